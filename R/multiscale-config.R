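#' Multiscale quantification configuration
#'
#' Defines the ladder of gliding-box sides and the percolation rule used by the
#' fractal engine. Box sides must be odd so every box has a central pixel; the
#' default ladder r = 3, 5, ..., 41 quantifies an image on 20 scales. The
#' percolation threshold is the site-percolation critical occupation
#' probability 0.59275: a box "percolates" when its pore fraction reaches it.
#'
#' @param r_min Smallest box side in pixels (odd, default 3).
#' @param r_max Largest box side in pixels (odd, default 41).
#' @param r_step Increment between consecutive box sides (default 2).
#' @param percolation_threshold Pore fraction at or above which a box counts
#'   as percolating (default 0.59275).
#' @param connectivity Pore adjacency rule for cluster labeling: 4 or 8.
#' @param fd_variant `"box_count"` (default) computes the fractal dimension
#'   curve as the box-count estimate sum(P(m,r)/m); `"mass"` uses the mass
#'   moment sum(P(m,r)*m) instead.
#' @param q_normalization `"ratio"` (default) reports the largest-cluster
#'   curve as mean coverage |c_max|/r^2; `"absolute"` reports mean pixel
#'   counts.
#'
#' @return An object of class `multiscale_config`.
#' @examples
#' cfg <- multiscale_config()
#' box_scales(cfg) # 3 5 ... 41
#' @export
multiscale_config <- function(r_min = 3L, r_max = 41L, r_step = 2L,
                              percolation_threshold = 0.59275,
                              connectivity = 4L,
                              fd_variant = c("box_count", "mass"),
                              q_normalization = c("ratio", "absolute")) {
  r_min <- as.integer(r_min); r_max <- as.integer(r_max)
  r_step <- as.integer(r_step)
  if (r_min %% 2L == 0L || r_max %% 2L == 0L)
    stop("box sides must be odd", call. = FALSE)
  if (r_min > r_max) stop("r_min must not exceed r_max", call. = FALSE)
  if (r_step < 1L) stop("r_step must be positive", call. = FALSE)
  if (!(percolation_threshold > 0 && percolation_threshold < 1))
    stop("percolation_threshold must lie in (0, 1)", call. = FALSE)
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  structure(
    list(r_min = r_min, r_max = r_max, r_step = r_step,
         percolation_threshold = percolation_threshold,
         connectivity = as.integer(connectivity),
         fd_variant = match.arg(fd_variant),
         q_normalization = match.arg(q_normalization)),
    class = "multiscale_config")
}

#' Box-side ladder of a configuration
#'
#' @param config A [multiscale_config()].
#' @return Integer vector of box sides (20 values at the defaults).
#' @export
box_scales <- function(config = multiscale_config()) {
  seq.int(config$r_min, config$r_max, by = config$r_step)
}

#' @export
print.multiscale_config <- function(x, ...) {
  cat("Multiscale config: r =", x$r_min, "..", x$r_max, "step", x$r_step,
      sprintf("(%d scales)", length(box_scales(x))), "\n")
  cat("  percolation threshold:", x$percolation_threshold,
      " connectivity:", x$connectivity, "\n")
  cat("  FD variant:", x$fd_variant, " Q normalization:", x$q_normalization, "\n")
  invisible(x)
}

#' Coerce an image to an RGB array in 0-255
#'
#' Accepts an H x W x 3 numeric array (values 0-255 or 0-1, the latter is
#' rescaled), or a grayscale matrix / H x W x 1 array which is promoted to RGB
#' by channel replication.
#'
#' @param image Numeric matrix or array.
#' @return H x W x 3 numeric array with values in 0-255.
#' @export
as_rgb_image <- function(image) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  if (!is.array(image) || length(dim(image)) != 3L)
    stop("image must be a matrix or an H x W x C array", call. = FALSE)
  d <- dim(image)
  if (d[3] == 1L) image <- array(rep(image, 3L), c(d[1], d[2], 3L))
  else if (d[3] == 4L) image <- image[, , 1:3, drop = FALSE] # drop alpha
  else if (d[3] != 3L) stop("image must have 1, 3 or 4 channels", call. = FALSE)
  if (max(image) <= 1 && min(image) >= 0) image <- image * 255
  if (min(image) < 0 || max(image) > 255)
    stop("channel values must lie in 0-255", call. = FALSE)
  image
}
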