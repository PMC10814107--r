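# Seeded synthetic fixtures: two-class RGB texture datasets and a
# deterministic mock classification backend. These stand in for external
# histology collections and GPU-trained CNNs so every pipeline stage runs
# self-contained; they are synthetic by construction and documented as such.

#' Specification of a synthetic two-class texture dataset
#'
#' Each class is a thresholded, Gaussian-smoothed noise field ("blob field"):
#' pixels inside blobs take the class's blob color, the rest the base color,
#' plus i.i.d. Gaussian channel noise. Classes with different correlation
#' lengths produce blob textures whose lacunarity and percolation curves
#' differ systematically, so the fractal features are class-informative by
#' construction.
#'
#' @param n_per_class Images per class.
#' @param width,height Image size in pixels (must cover the largest box side,
#'   41 at the default ladder).
#' @param class_params Named list (one entry per class) of lists with
#'   `base_color`, `blob_color` (RGB in 0-255), `blob_density` (area fraction
#'   of blobs), `correlation_length` (Gaussian smoothing sigma, pixels) and
#'   `noise_sd` (channel noise, 0-255 units).
#' @param seed Integer seed; the dataset is a pure function of the spec.
#' @return A `texture_spec` object.
#' @export
texture_spec <- function(n_per_class = 30L, width = 64L, height = 64L,
                         class_params = NULL, seed = 1L) {
  if (is.null(class_params)) {
    # H&E-like palette: bluish-purple nuclei blobs on pinkish stroma.
    # The two classes differ in blob scale (correlation length 1.5 vs 4 px)
    # and density, mimicking fine- vs coarse-grained chromatin texture.
    class_params <- list(
      fine = list(base_color = c(225, 170, 190), blob_color = c(120, 70, 150),
                  blob_density = 0.35, correlation_length = 1.5, noise_sd = 12),
      coarse = list(base_color = c(225, 170, 190), blob_color = c(120, 70, 150),
                    blob_density = 0.45, correlation_length = 4, noise_sd = 12))
  }
  if (width < 41L || height < 41L)
    stop("width and height must be at least 41 (largest box side r_max)",
         call. = FALSE)
  if (n_per_class < 1L) stop("n_per_class must be positive", call. = FALSE)
  structure(list(n_per_class = as.integer(n_per_class),
                 width = as.integer(width), height = as.integer(height),
                 class_params = class_params, seed = as.integer(seed)),
            class = "texture_spec")
}

# Separable Gaussian blur with edge replication; sigma in pixels.
gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  k <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-k:k, sd = sigma)
  w <- w / sum(w)
  blur_dim <- function(m) { # along rows
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (o in -k:k) {
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      out <- out + w[o + k + 1L] * m[idx, , drop = FALSE]
    }
    out
  }
  t(blur_dim(t(blur_dim(mat))))
}

make_texture_image <- function(width, height, params) {
  field <- gaussian_blur(matrix(stats::rnorm(height * width), height, width),
                         params$correlation_length)
  cut <- stats::quantile(field, 1 - params$blob_density)
  blob <- field >= cut
  img <- array(0, c(height, width, 3))
  for (ch in 1:3) {
    img[, , ch] <- ifelse(blob, params$blob_color[ch], params$base_color[ch]) +
      stats::rnorm(height * width, sd = params$noise_sd)
  }
  array(pmin(pmax(img, 0), 255), dim(img))
}

#' Generate a seeded labeled texture dataset
#'
#' @param spec A [texture_spec()].
#' @return List with `images` (named list of H x W x 3 arrays, 0-255),
#'   `labels` (factor named by image id) and `spec`.
#' @examples
#' ds <- generate_texture_dataset(texture_spec(n_per_class = 2, seed = 7))
#' length(ds$images) # 4
#' @export
generate_texture_dataset <- function(spec = texture_spec()) {
  stopifnot(inherits(spec, "texture_spec"))
  classes <- names(spec$class_params)
  withr::with_seed(spec$seed, {
    images <- list()
    labels <- character(0)
    for (cl in classes) {
      for (i in seq_len(spec$n_per_class)) {
        id <- sprintf("%s_%03d", cl, i)
        images[[id]] <- make_texture_image(spec$width, spec$height,
                                           spec$class_params[[cl]])
        labels[id] <- cl
      }
    }
    list(images = images, labels = factor(labels, levels = classes),
         spec = spec)
  })
}

#' Write a generated dataset as class-named PNG subfolders
#'
#' Produces the directory convention consumed by [load_labeled_images()], so
#' synthetic fixtures double as end-to-end test data.
#'
#' @param dataset Result of [generate_texture_dataset()].
#' @param root Output directory (created if needed).
#' @return `root`, invisibly.
#' @export
write_texture_dataset <- function(dataset, root) {
  for (cl in levels(dataset$labels)) dir.create(file.path(root, cl),
                                                recursive = TRUE,
                                                showWarnings = FALSE)
  for (id in names(dataset$images)) {
    cl <- as.character(dataset$labels[[id]])
    png::writePNG(dataset$images[[id]] / 255,
                  file.path(root, cl, paste0(id, ".png")))
  }
  invisible(root)
}

# Deterministic integer derived from image content; keyed with the backend
# seed so pseudo-noise is a pure function of (image, seed).
image_content_key <- function(image, seed) {
  v <- as.numeric(image)
  h <- sum(v * (seq_along(v) %% 97 + 1)) + sum(v)
  (floor(abs(h)) + as.numeric(seed) * 7919) %% 2147483646 + 1
}

# Pooled image summary: 4x4 grid of channel means plus channel sds, in [0,1].
image_summary <- function(image) {
  image <- as_rgb_image(image)
  d <- dim(image)
  gi <- ceiling(seq_len(d[1]) / d[1] * 4)
  gj <- ceiling(seq_len(d[2]) / d[2] * 4)
  pooled <- vapply(1:3, function(ch) {
    as.vector(tapply(image[, , ch], list(gi[row(image[, , ch])],
                                         gj[col(image[, , ch])]), mean))
  }, numeric(16))
  sds <- vapply(1:3, function(ch) stats::sd(image[, , ch]), numeric(1))
  c(as.vector(pooled), sds) / 255
}

#' Deterministic mock classification backend
#'
#' Emulates a fine-tuned CNN for testing: embeddings are a seeded random
#' projection of a pooled image summary, scaled by `separation`, plus
#' image-keyed pseudo-noise; at `separation = 0` the embeddings carry no
#' class signal and downstream accuracy is at chance. The backend exposes the
#' full protocol needed downstream: `embed`, `predict_probabilities` and
#' `layer_activations_and_gradients` (an 8 x 8 mock convolutional layer named
#' `"mock_conv"` for Grad-CAM).
#'
#' @param arch An [architecture_spec()] or architecture name.
#' @param separation Effect size scaling the image-dependent embedding
#'   component (default 2).
#' @param seed Integer seed; all backend behavior is a pure function of
#'   (inputs, seed).
#' @param classes Class labels the head predicts over.
#' @return A `classification_backend` list.
#' @export
mock_backend <- function(arch, separation = 2, seed = 1L,
                         classes = c("fine", "coarse")) {
  if (is.character(arch)) arch <- architecture_spec(arch)
  stopifnot(inherits(arch, "architecture_spec"))
  dim_e <- arch$embedding_dim
  n_classes <- length(classes)
  n_phi <- 51L
  proj <- withr::with_seed(seed, matrix(stats::rnorm(dim_e * n_phi), dim_e))
  head_w <- withr::with_seed(seed + 1L,
                             matrix(stats::rnorm(n_classes * dim_e, sd = 1),
                                    n_classes))
  conv_w <- withr::with_seed(seed + 2L, matrix(stats::rnorm(8 * 3), 8))
  conv_b <- withr::with_seed(seed + 3L, stats::rnorm(8, sd = 0.1))
  grad_c <- withr::with_seed(seed + 4L,
                             matrix(stats::rnorm(n_classes * 8), n_classes))

  embed_one <- function(image) {
    phi <- image_summary(image)
    noise <- withr::with_seed(image_content_key(image, seed),
                              stats::rnorm(dim_e))
    as.numeric(separation * (proj %*% phi) / sqrt(n_phi) + noise)
  }

  backend <- list(
    arch = arch,
    pretrained = TRUE,
    classes = classes,
    layers = "mock_conv",
    head = head_w,
    separation = separation,
    seed = as.integer(seed))

  backend$embed <- function(images) {
    if (is.null(names(images))) names(images) <- seq_along(images)
    t(vapply(images, embed_one, numeric(dim_e)))
  }

  backend$predict_probabilities <- function(images, head = backend$head) {
    emb <- backend$embed(images)
    z <- emb %*% t(head) / sqrt(dim_e)
    z <- z - apply(z, 1, max)
    p <- exp(z)
    p <- p / rowSums(p)
    colnames(p) <- classes
    p
  }

  backend$layer_activations_and_gradients <- function(image, layer,
                                                      class_index) {
    if (!identical(layer, "mock_conv"))
      stop("unknown activation layer: ", layer, call. = FALSE)
    image <- as_rgb_image(image)
    d <- dim(image)
    gi <- ceiling(seq_len(d[1]) / d[1] * 8)
    gj <- ceiling(seq_len(d[2]) / d[2] * 8)
    ds <- vapply(1:3, function(ch) {
      tapply(image[, , ch], list(gi[row(image[, , ch])],
                                 gj[col(image[, , ch])]), mean)
    }, matrix(0, 8, 8)) / 255
    activations <- array(0, c(8, 8, 8))
    gradients <- array(0, c(8, 8, 8))
    for (k in 1:8) {
      a <- conv_w[k, 1] * ds[, , 1] + conv_w[k, 2] * ds[, , 2] +
        conv_w[k, 3] * ds[, , 3] + conv_b[k]
      activations[, , k] <- pmax(a, 0)
      gradients[, , k] <- grad_c[class_index, k]
    }
    list(activations = activations, gradients = gradients)
  }

  class(backend) <- "classification_backend"
  backend
}
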