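# Grad-CAM and LIME representation images. Both consume the backend protocol
# (predict_probabilities, layer_activations_and_gradients) and emit an RGB
# raster of the source image's size, which the fractal engine then quantifies
# exactly like an ordinary image (116 features per representation).

#' Explanation configuration
#'
#' @param method `"gradcam"` or `"lime"`.
#' @param lime_num_perturbations Number of random superpixel on/off
#'   perturbations used to fit the local surrogate (default 1000).
#' @param lime_num_superpixels_kept Regions of interest retained in the
#'   rendered explanation (default 5).
#' @param gradcam_layer Identifier of the convolutional layer to read; `NULL`
#'   uses the backend's last (deepest) exposed layer.
#' @param heatmap_rendering `"heatmap_rgb"` renders the bare class-activation
#'   heatmap through a fixed perceptual colormap (inferno); `"overlay"`
#'   alpha-blends it over the input.
#' @param quickshift_ratio,quickshift_kernel_size,quickshift_max_dist
#'   Quick-shift segmentation parameters: color/space balance, Parzen kernel
#'   bandwidth (pixels) and maximum mode-seeking link length (pixels).
#' @param lime_kernel_width Exponential kernel width on the cosine distance
#'   between a perturbation mask and the full image (default 0.25).
#' @param lime_ridge_penalty Ridge penalty of the weighted linear surrogate.
#' @return An `explanation_config` object.
#' @export
explanation_config <- function(method = c("gradcam", "lime"),
                               lime_num_perturbations = 1000L,
                               lime_num_superpixels_kept = 5L,
                               gradcam_layer = NULL,
                               heatmap_rendering = c("heatmap_rgb", "overlay"),
                               quickshift_ratio = 1.0,
                               quickshift_kernel_size = 2,
                               quickshift_max_dist = 6,
                               lime_kernel_width = 0.25,
                               lime_ridge_penalty = 1.0) {
  if (lime_num_superpixels_kept < 1L)
    stop("lime_num_superpixels_kept must be >= 1", call. = FALSE)
  structure(list(method = match.arg(method),
                 lime_num_perturbations = as.integer(lime_num_perturbations),
                 lime_num_superpixels_kept = as.integer(lime_num_superpixels_kept),
                 gradcam_layer = gradcam_layer,
                 heatmap_rendering = match.arg(heatmap_rendering),
                 quickshift_ratio = quickshift_ratio,
                 quickshift_kernel_size = quickshift_kernel_size,
                 quickshift_max_dist = quickshift_max_dist,
                 lime_kernel_width = lime_kernel_width,
                 lime_ridge_penalty = lime_ridge_penalty),
            class = "explanation_config")
}

# Bilinear upsampling of a small map to H x W.
upsample_bilinear <- function(map, H, W) {
  h <- nrow(map); w <- ncol(map)
  yi <- pmin(pmax((seq_len(H) - 0.5) * h / H + 0.5, 1), h)
  xi <- pmin(pmax((seq_len(W) - 0.5) * w / W + 0.5, 1), w)
  y0 <- pmin(floor(yi), h - 1L); x0 <- pmin(floor(xi), w - 1L)
  fy <- yi - y0; fx <- xi - x0
  a <- map[cbind(rep(y0, W), rep(x0, each = H))]
  b <- map[cbind(rep(y0 + 1, W), rep(x0, each = H))]
  cc <- map[cbind(rep(y0, W), rep(x0 + 1, each = H))]
  d <- map[cbind(rep(y0 + 1, W), rep(x0 + 1, each = H))]
  fym <- rep(fy, W); fxm <- rep(fx, each = H)
  matrix(a * (1 - fym) * (1 - fxm) + b * fym * (1 - fxm) +
           cc * (1 - fym) * fxm + d * fym * fxm, H, W)
}

# Fixed perceptual colormap LUT (256 x 3, 0-255).
heatmap_lut <- function() {
  cols <- grDevices::hcl.colors(256, "Inferno")
  t(grDevices::col2rgb(cols))
}

render_heatmap <- function(values01, image, rendering) {
  H <- nrow(values01); W <- ncol(values01)
  lut <- heatmap_lut()
  idx <- pmin(255L, pmax(0L, as.integer(floor(values01 * 255)))) + 1L
  heat <- array(0, c(H, W, 3))
  for (ch in 1:3) heat[, , ch] <- matrix(lut[idx, ch], H, W)
  if (rendering == "overlay") heat <- 0.5 * heat + 0.5 * image
  array(pmin(pmax(heat, 0), 255), c(H, W, 3))
}

#' Grad-CAM representation of an image
#'
#' Reads activations and gradients of the named convolutional layer for the
#' backend's predicted class, weights each channel map by its mean gradient,
#' sums, applies ReLU, upsamples bilinearly to the image size and min-max
#' scales to \[0, 1\]. A constant map yields a valid uniform-color output (an
#' everywhere-nonpositive weighted sum maps to colormap(0)). The map is
#' rendered as a bare heatmap or as an overlay per the configuration.
#'
#' @param backend A `classification_backend`.
#' @param image RGB raster.
#' @param config An [explanation_config()].
#' @return A `representation_image`: `pixels` (H x W x 3, 0-255, the source
#'   image's dimensions) and `provenance`.
#' @export
grad_cam_representation <- function(backend, image,
                                    config = explanation_config("gradcam")) {
  image <- as_rgb_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  layer <- config$gradcam_layer
  if (is.null(layer)) layer <- backend$layers[length(backend$layers)]
  probs <- backend$predict_probabilities(list(image))
  cls <- which.max(probs[1, ])

  ag <- backend$layer_activations_and_gradients(image, layer, cls)
  K <- dim(ag$activations)[3]
  cam <- matrix(0, dim(ag$activations)[1], dim(ag$activations)[2])
  for (k in seq_len(K)) {
    alpha <- mean(ag$gradients[, , k])
    cam <- cam + alpha * ag$activations[, , k]
  }
  cam <- pmax(cam, 0)
  cam <- upsample_bilinear(cam, H, W)
  rng <- range(cam)
  values01 <- if (rng[2] > rng[1]) (cam - rng[1]) / (rng[2] - rng[1])
              else matrix(as.numeric(rng[2] > 0), H, W)

  structure(list(
    pixels = render_heatmap(values01, image, config$heatmap_rendering),
    provenance = list(method = "gradcam", layer = layer,
                      predicted_class = colnames(probs)[cls],
                      rendering = config$heatmap_rendering)),
    class = "representation_image")
}

#' Quick-shift superpixel segmentation
#'
#' Mode-seeking segmentation on joint (color, position) features: each pixel
#' links to its nearest higher-density neighbor within `max_dist`; trees of
#' links form the segments.
#'
#' @inheritParams grad_cam_representation
#' @param config An [explanation_config()] carrying the quick-shift
#'   parameters.
#' @return Integer matrix of segment labels 1..S.
#' @export
quickshift_segments <- function(image, config = explanation_config("lime")) {
  image <- as_rgb_image(image) / 255
  quickshift_cpp(image, config$quickshift_ratio,
                 config$quickshift_kernel_size, config$quickshift_max_dist)
}

#' LIME representation of an image
#'
#' Segments the image with quick-shift, draws seeded random on/off
#' perturbations of the superpixels (hidden superpixels are fudged to their
#' mean color for model input), queries the backend's probability for the
#' predicted class, and fits a ridge-regularized linear surrogate weighted by
#' an exponential kernel on the cosine distance from the unperturbed mask.
#' The top-scoring `min(kept, S)` superpixels retain their original pixels;
#' all other pixels are set to black.
#'
#' @inheritParams grad_cam_representation
#' @param seed Integer seed for the perturbation design (mandatory: the
#'   representation is part of a reproducible feature pipeline).
#' @return A `representation_image` with `pixels` and `provenance`
#'   (including the surrogate scores per superpixel).
#' @export
lime_representation <- function(backend, image,
                                config = explanation_config("lime"),
                                seed) {
  if (missing(seed) || is.null(seed))
    stop("lime_representation requires an explicit seed", call. = FALSE)
  image <- as_rgb_image(image)
  H <- dim(image)[1]; W <- dim(image)[2]

  seg <- quickshift_segments(image, config)
  S <- max(seg)
  kept_n <- min(config$lime_num_superpixels_kept, S)
  if (S < config$lime_num_superpixels_kept)
    message(sprintf("only %d superpixels; keeping all", S))

  # fudged image: every superpixel replaced by its mean color
  fudged <- image
  seg_means <- matrix(0, S, 3)
  for (ch in 1:3) {
    mu <- tapply(image[, , ch], seg, mean)
    seg_means[, ch] <- mu
    fudged[, , ch] <- mu[seg]
  }

  probs0 <- backend$predict_probabilities(list(image))
  cls <- which.max(probs0[1, ])

  Z <- withr::with_seed(seed, matrix(stats::rbinom(
    config$lime_num_perturbations * S, 1L, 0.5),
    config$lime_num_perturbations, S))
  Z[1, ] <- 1L # anchor: the unperturbed image

  perturbed <- lapply(seq_len(nrow(Z)), function(i) {
    on <- Z[i, ] == 1L
    img <- fudged
    keep <- on[seg]
    for (ch in 1:3) {
      plane <- img[, , ch]
      orig <- image[, , ch]
      plane[keep] <- orig[keep]
      img[, , ch] <- plane
    }
    img
  })
  y <- backend$predict_probabilities(perturbed)[, cls]

  # exponential kernel on cosine distance between mask and the full mask
  frac <- rowSums(Z) / S
  d <- 1 - sqrt(pmax(frac, 0))
  w <- exp(-d^2 / config$lime_kernel_width^2)

  # weighted ridge with unpenalized intercept
  X <- cbind(1, Z)
  pen <- diag(c(0, rep(config$lime_ridge_penalty, S)))
  beta <- solve(t(X * w) %*% X + pen, t(X * w) %*% y)
  scores <- as.numeric(beta[-1])

  keep_ids <- order(-scores, seq_len(S))[seq_len(kept_n)]
  mask <- seg %in% keep_ids
  out <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    plane <- matrix(0, H, W)
    orig <- image[, , ch]
    plane[mask] <- orig[mask]
    out[, , ch] <- plane
  }

  structure(list(
    pixels = out,
    provenance = list(method = "lime", predicted_class = colnames(probs0)[cls],
                      n_superpixels = S, kept = keep_ids, scores = scores,
                      seed = seed,
                      quickshift = list(ratio = config$quickshift_ratio,
                                        kernel_size = config$quickshift_kernel_size,
                                        max_dist = config$quickshift_max_dist))),
    class = "representation_image")
}

#' Quantify an xAI representation with the fractal engine
#'
#' Convenience wrapper: generates the requested representation and extracts
#' the 116-value handcrafted vector from it.
#'
#' @inheritParams grad_cam_representation
#' @param seed Seed forwarded to [lime_representation()].
#' @param multiscale A [multiscale_config()].
#' @return Named numeric feature vector of the representation image.
#' @export
xai_feature_vector <- function(backend, image, config, seed = NULL,
                               multiscale = multiscale_config()) {
  rep_img <- switch(config$method,
    gradcam = grad_cam_representation(backend, image, config),
    lime = lime_representation(backend, image, config, seed))
  extract_handcrafted_vector(rep_img$pixels, multiscale)
}
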