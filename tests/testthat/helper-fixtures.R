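# Image fixtures built in code.

uniform_image <- function(h = 44, w = 44, value = 128) {
  array(value, c(h, w, 3))
}

# 1-pixel checkerboard with values 0/255 on all channels
checkerboard_image <- function(h = 64, w = 64) {
  m <- 255 * ((row(matrix(0, h, w)) + col(matrix(0, h, w))) %% 2)
  array(rep(m, 3), c(h, w, 3))
}

random_image <- function(h = 48, w = 48, seed = 1) {
  withr::with_seed(seed, array(runif(h * w * 3, 0, 255), c(h, w, 3)))
}

small_texture_dataset <- function(n_per_class = 4, seed = 42) {
  generate_texture_dataset(texture_spec(n_per_class = n_per_class,
                                        seed = seed))
}
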