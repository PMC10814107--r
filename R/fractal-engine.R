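#' @useDynLib fractalens, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Single gliding-box pass at one scale: frequency table plus percolation
# summaries. All public per-scale operations wrap this.
box_scan <- function(image, r, config = multiscale_config()) {
  image <- as_rgb_image(image)
  r <- as.integer(r)
  if (r %% 2L == 0L) stop("box side must be odd", call. = FALSE)
  if (dim(image)[1] < r || dim(image)[2] < r)
    stop(sprintf("image too small for scale r=%d", r), call. = FALSE)
  box_scan_cpp(image, r, config$percolation_threshold, config$connectivity)
}

#' Gliding-box probability matrix at one scale
#'
#' Slides an r x r box one pixel at a time over an RGB image. For each box
#' position with central pixel `pc`, `m` counts the pixels `p` in the box whose
#' 5-D Chebyshev distance over (x, y, R, G, B) to `pc` is at most `r`. Spatial
#' offsets inside the box never exceed (r-1)/2, so the criterion reduces to
#' max(|dR|, |dG|, |dB|) <= r with channels in native 0-255 units. The
#' frequency table N(m, r) over all n_r = (width-r+1)(height-r+1) box
#' positions is normalized to the probability matrix P(m, r).
#'
#' @param image RGB raster (H x W x 3 array, 0-255; grayscale is promoted).
#' @param r Odd box side in pixels.
#' @param config A [multiscale_config()] (supplies the percolation rule for
#'   the shared scan; the probabilities themselves do not depend on it).
#' @return A `box_statistics` object: `r`, `n_r`, `frequency` (N(m,r) indexed
#'   by m = 1..r^2) and `probability` (P(m,r)).
#' @examples
#' img <- array(128, c(10, 10, 3))
#' s <- gliding_box_probability(img, 3)
#' s$n_r            # 64
#' s$probability[9] # 1: every box fully counted on a uniform image
#' @export
gliding_box_probability <- function(image, r, config = multiscale_config()) {
  scan <- box_scan(image, r, config)
  structure(
    list(r = as.integer(r), n_r = scan$n_boxes,
         frequency = scan$frequency,
         probability = scan$frequency / scan$n_boxes),
    class = "box_statistics")
}

check_normalized <- function(stats) {
  for (s in stats) {
    if (abs(sum(s$probability) - 1) > 1e-9)
      stop("probability mass != 1", call. = FALSE)
  }
  invisible(stats)
}

#' Fractal dimension curve from gliding-box probabilities
#'
#' For each scale, FD(r) estimates the number of boxes of side r needed to
#' overlay the image: FD(r) = sum_m P(m, r) / m (the Voss box-count
#' estimator). Because every box contains at least its central pixel (m >= 1),
#' FD(r) lies in (0, 1].
#'
#' @param stats List of `box_statistics`, one per scale.
#' @param config A [multiscale_config()]; `fd_variant = "mass"` switches to
#'   the mass-moment form sum_m P(m, r) * m.
#' @return Numeric vector of FD values, one per scale.
#' @export
fractal_dimension_curve <- function(stats, config = multiscale_config()) {
  if (inherits(stats, "box_statistics")) stats <- list(stats)
  check_normalized(stats)
  vapply(stats, function(s) {
    m <- seq_along(s$probability)
    if (config$fd_variant == "box_count") sum(s$probability / m)
    else sum(s$probability * m)
  }, numeric(1))
}

#' Lacunarity curve from gliding-box probabilities
#'
#' Lacunarity at scale r is the normalized variance of the box-mass
#' distribution: with first moment mu = sum m P(m,r) and second moment
#' mu2 = sum m^2 P(m,r), L(r) = (mu2 - mu^2) / mu^2. L is zero exactly when
#' the mass distribution at that scale is degenerate (e.g. uniform images).
#'
#' @inheritParams fractal_dimension_curve
#' @return Numeric vector of lacunarity values, one per scale.
#' @export
lacunarity_curve <- function(stats, config = multiscale_config()) {
  if (inherits(stats, "box_statistics")) stats <- list(stats)
  check_normalized(stats)
  vapply(stats, function(s) {
    m <- seq_along(s$probability)
    mu <- sum(m * s$probability)
    mu2 <- sum(m^2 * s$probability)
    if (mu == 0) stop("internal error: zero first moment", call. = FALSE)
    (mu2 - mu^2) / mu^2
  }, numeric(1))
}

#' Hoshen-Kopelman cluster labeling of a pore mask
#'
#' Labels connected pore clusters of a binary grid with a single-pass
#' union-find (Hoshen-Kopelman). Pores sharing a label belong to the same
#' cluster; labels are contiguous integers 1..K in raster order of first
#' occurrence and 0 marks background.
#'
#' @param pore_mask Logical matrix (TRUE = pore).
#' @param connectivity 4 (default, edge-sharing neighbors) or 8 (plus
#'   diagonals).
#' @return List with `labels` (integer matrix), `sizes` (pixels per cluster,
#'   indexed by label) and `n_clusters`.
#' @examples
#' x <- matrix(c(1, 0, 1, 0, 1, 0, 1, 0, 1) == 1, 3, 3)
#' label_pore_clusters(x, 4)$n_clusters # 5 isolated pores
#' @export
label_pore_clusters <- function(pore_mask, connectivity = 4L) {
  if (!is.matrix(pore_mask)) stop("pore_mask must be a matrix", call. = FALSE)
  storage.mode(pore_mask) <- "logical"
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  out <- hk_label_cpp(pore_mask, as.integer(connectivity))
  out$n_clusters <- length(out$sizes)
  out
}

#' Percolation curves over the scale ladder
#'
#' For every box position at every scale, the pixels satisfying the 5-D
#' Chebyshev criterion are the box's pores; pore clusters are labeled with
#' Hoshen-Kopelman. Three curves summarize the scan: C(r), the mean number of
#' clusters per box; Q(r), the mean coverage ratio |c_max|/r^2 of the largest
#' cluster (or mean absolute size with `q_normalization = "absolute"`); and
#' P(r), the fraction of boxes whose pore fraction reaches the percolation
#' threshold.
#'
#' @inheritParams gliding_box_probability
#' @param config A [multiscale_config()].
#' @return List with `scales`, `C`, `Q`, `P` (each one value per scale).
#' @export
percolation_curves <- function(image, config = multiscale_config()) {
  image <- as_rgb_image(image)
  rs <- box_scales(config)
  scans <- lapply(rs, function(r) box_scan(image, r, config))
  qv <- vapply(scans, `[[`, numeric(1), "mean_largest_ratio")
  if (config$q_normalization == "absolute") qv <- qv * rs^2
  list(scales = rs,
       C = vapply(scans, `[[`, numeric(1), "mean_clusters"),
       Q = qv,
       P = vapply(scans, `[[`, numeric(1), "percolating_fraction"))
}

#' Scalar descriptors of a multiscale curve
#'
#' Reduces a discrete curve f(x_1..x_N) on an index interval (a, b) to four
#' scalars: the trapezoid area A(a,b) = (b-a)/(2N) * sum_{n=a}^{b-1}
#' (f(x_n) + f(x_{n+1})); the moment skewness S of the values (0/0 on a
#' constant curve is defined as 0); the area ratio R = A(floor(b/2)+1, b) /
#' A(a, floor(b/2)) between the right and left half-areas (undefined
#' denominators are encoded as 0 with `r_defined = FALSE`); and the curve
#' maximum.
#'
#' @param curve Numeric vector (20 points for the default scale ladder).
#' @param interval Integer pair (a, b) of point indices, default the full
#'   curve.
#' @return A `curve_descriptors` list: `area`, `skewness`, `area_ratio`,
#'   `max_value`, `interval`, `n_points`, `mean`, `r_defined`.
#' @examples
#' d <- curve_descriptors(c(1, 2, 3))
#' d$area     # 8/3
#' d$skewness # 0
#' @export
curve_descriptors <- function(curve, interval = c(1L, length(curve))) {
  n <- length(curve)
  a <- as.integer(interval[1]); b <- as.integer(interval[2])
  if (!(b > a)) stop("interval must satisfy b > a", call. = FALSE)
  if (a < 1L || b > n) stop("interval outside the curve", call. = FALSE)

  trap_area <- function(a1, b1) {
    if (b1 <= a1) return(0)
    idx <- a1:(b1 - 1L)
    (b1 - a1) / (2 * n) * sum(curve[idx] + curve[idx + 1L])
  }

  vals <- curve[a:b]
  xbar <- mean(vals)
  m2 <- sum((vals - xbar)^2) / n
  m3 <- sum((vals - xbar)^3) / n
  skew <- if (m2 == 0) 0 else m3 / m2^1.5

  half <- b %/% 2L
  left <- trap_area(a, half)
  right <- trap_area(half + 1L, b)
  r_defined <- left != 0
  area_ratio <- if (r_defined) right / left else 0

  structure(
    list(area = trap_area(a, b), skewness = skew, area_ratio = area_ratio,
         max_value = max(vals), interval = c(a, b), n_points = n,
         mean = xbar, r_defined = r_defined),
    class = "curve_descriptors")
}

#' Names of the 116 handcrafted features
#'
#' Fixed layout: 20 fractal dimensions, 20 lacunarities, 20 mean cluster
#' counts, 20 largest-cluster coverage ratios, 20 percolating-box fractions
#' (each ordered by ascending scale), then 16 curve descriptors, four for each
#' of the curves L, C, Q, P in the order area, skewness, area ratio, maximum.
#'
#' @param config A [multiscale_config()].
#' @return Character vector of length 116 at the default configuration.
#' @export
handcrafted_feature_names <- function(config = multiscale_config()) {
  rs <- box_scales(config)
  c(paste0("FD_r", rs), paste0("L_r", rs), paste0("C_r", rs),
    paste0("Q_r", rs), paste0("P_r", rs),
    as.vector(t(outer(c("L", "C", "Q", "P"),
                      c("area", "skewness", "area_ratio", "max"),
                      paste, sep = "_"))))
}

#' Extract the full multiscale fractal feature vector from one image
#'
#' Runs the gliding-box scan at every scale of the ladder and assembles the
#' 116-value handcrafted descriptor: the FD, lacunarity and percolation
#' curves (5 x 20 values) plus the four scalar descriptors of each of the L,
#' C, Q and P curves (16 values). The fractal dimension curve contributes no
#' scalar descriptors.
#'
#' @inheritParams percolation_curves
#' @return Named numeric vector (length 116 at the defaults), with the layout
#'   of [handcrafted_feature_names()].
#' @export
extract_handcrafted_vector <- function(image, config = multiscale_config()) {
  image <- as_rgb_image(image)
  rs <- box_scales(config)
  d <- dim(image)
  if (d[1] < config$r_max || d[2] < config$r_max)
    stop(sprintf("image (%dx%d) smaller than the largest scale r=%d",
                 d[2], d[1], config$r_max), call. = FALSE)

  scans <- lapply(rs, function(r) box_scan(image, r, config))
  stats <- lapply(seq_along(rs), function(i) {
    structure(list(r = rs[i], n_r = scans[[i]]$n_boxes,
                   frequency = scans[[i]]$frequency,
                   probability = scans[[i]]$frequency / scans[[i]]$n_boxes),
              class = "box_statistics")
  })

  fd <- fractal_dimension_curve(stats, config)
  lac <- lacunarity_curve(stats, config)
  cc <- vapply(scans, `[[`, numeric(1), "mean_clusters")
  qq <- vapply(scans, `[[`, numeric(1), "mean_largest_ratio")
  if (config$q_normalization == "absolute") qq <- qq * rs^2
  pp <- vapply(scans, `[[`, numeric(1), "percolating_fraction")

  desc <- unlist(lapply(list(lac, cc, qq, pp), function(curve) {
    d <- curve_descriptors(curve)
    c(d$area, d$skewness, d$area_ratio, d$max_value)
  }))

  stats::setNames(c(fd, lac, cc, qq, pp, desc),
                  handcrafted_feature_names(config))
}

#' Handcrafted feature table for a set of images
#'
#' Applies [extract_handcrafted_vector()] to each image and stacks the rows
#' into a feature table keyed by image id.
#'
#' @param images Named list of RGB rasters (names become image ids).
#' @param config A [multiscale_config()].
#' @return Data frame with `image_id` plus one column per feature.
#' @export
extract_feature_table <- function(images, config = multiscale_config()) {
  if (is.null(names(images)) || anyDuplicated(names(images)))
    stop("images must be a uniquely named list", call. = FALSE)
  rows <- t(vapply(images, extract_handcrafted_vector,
                   numeric(length(handcrafted_feature_names(config))),
                   config = config))
  out <- data.frame(image_id = names(images), rows,
                    row.names = NULL, check.names = FALSE)
  out
}
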