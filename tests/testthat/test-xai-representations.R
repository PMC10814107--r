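# Hand-built backends exercising the explanation operations without any
# trained model.
fake_backend <- function(activations, gradients,
                         probs = matrix(c(0.6, 0.4), 1)) {
  list(
    layers = "conv",
    predict_probabilities = function(images, ...) {
      matrix(rep(probs, length(images)), length(images), byrow = TRUE)
    },
    layer_activations_and_gradients = function(image, layer, class_index) {
      if (!identical(layer, "conv"))
        stop("unknown activation layer: ", layer, call. = FALSE)
      list(activations = activations, gradients = gradients)
    })
}

inferno0 <- function() {
  as.numeric(grDevices::col2rgb(grDevices::hcl.colors(256, "Inferno")[1]))
}

test_that("uniform positive activation maps render a uniform color", {
  b <- fake_backend(array(1, c(4, 4, 2)), array(1, c(4, 4, 2)))
  img <- random_image(32, 32, 2)
  rep_img <- grad_cam_representation(b, img)
  px <- rep_img$pixels
  expect_equal(dim(px), c(32, 32, 3))
  for (ch in 1:3) expect_equal(max(px[, , ch]) - min(px[, , ch]), 0)
})

test_that("an everywhere-negative weighted sum maps to colormap(0)", {
  b <- fake_backend(array(1, c(4, 4, 2)), array(-1, c(4, 4, 2)))
  rep_img <- grad_cam_representation(b, random_image(32, 32, 3))
  base <- inferno0()
  for (ch in 1:3)
    expect_true(all(rep_img$pixels[, , ch] == base[ch]))
})

test_that("a single hot activation cell dominates its upsampled footprint", {
  act <- array(0, c(4, 4, 1))
  act[2, 3, 1] <- 1
  b <- fake_backend(act, array(1, c(4, 4, 1)))
  img <- uniform_image(64, 64)
  rep_img <- grad_cam_representation(b, img,
                                     explanation_config("gradcam"))
  # brightest rendered color = top of the colormap = scaled value 1
  lut_top <- as.numeric(grDevices::col2rgb(
    grDevices::hcl.colors(256, "Inferno")[256]))
  hot <- which(rep_img$pixels[, , 1] == lut_top[1] &
                 rep_img$pixels[, , 2] == lut_top[2] &
                 rep_img$pixels[, , 3] == lut_top[3], arr.ind = TRUE)
  expect_gt(nrow(hot), 0)
  # footprint of cell (2, 3) on a 64x64 canvas: rows 17..32, cols 33..48
  expect_true(all(hot[, 1] >= 17 & hot[, 1] <= 32))
  expect_true(all(hot[, 2] >= 33 & hot[, 2] <= 48))
})

test_that("overlay rendering blends the heatmap with the input", {
  b <- fake_backend(array(1, c(4, 4, 1)), array(1, c(4, 4, 1)))
  img <- uniform_image(32, 32, 100)
  bare <- grad_cam_representation(b, img, explanation_config("gradcam"))
  over <- grad_cam_representation(
    b, img, explanation_config("gradcam", heatmap_rendering = "overlay"))
  expect_equal(over$pixels, 0.5 * bare$pixels + 0.5 * img)
})

test_that("representations keep the source image's dimensions", {
  b <- fake_backend(array(1, c(4, 4, 2)), array(1, c(4, 4, 2)))
  img <- random_image(41, 53, 4)
  expect_equal(dim(grad_cam_representation(b, img)$pixels), c(41, 53, 3))
  l <- lime_representation(b, img, explanation_config("lime",
                                                      lime_num_perturbations = 50),
                           seed = 1)
  expect_equal(dim(l$pixels), c(41, 53, 3))
})

test_that("lime is bit-reproducible under a fixed seed and refuses none", {
  b <- fake_backend(array(1, c(4, 4, 1)), array(1, c(4, 4, 1)))
  img <- random_image(32, 32, 9)
  cfg <- explanation_config("lime", lime_num_perturbations = 100)
  r1 <- lime_representation(b, img, cfg, seed = 42)
  r2 <- lime_representation(b, img, cfg, seed = 42)
  expect_identical(r1$pixels, r2$pixels)
  r3 <- lime_representation(b, img, cfg, seed = 43)
  expect_false(identical(r1$provenance$scores, r3$provenance$scores))
  expect_error(lime_representation(b, img, cfg), "seed")
})

test_that("fewer than five superpixels keeps all of them", {
  b <- fake_backend(array(1, c(4, 4, 1)), array(1, c(4, 4, 1)))
  img <- random_image(20, 20, 5)
  cfg <- explanation_config("lime", lime_num_perturbations = 50,
                            quickshift_kernel_size = 10,
                            quickshift_max_dist = 100)
  seg <- quickshift_segments(img, cfg)
  expect_lt(max(seg), 5)
  expect_message(l <- lime_representation(b, img, cfg, seed = 3),
                 "keeping all")
  expect_equal(sort(l$provenance$kept), seq_len(max(seg)))
  # nothing masked: the representation is the original image
  expect_equal(l$pixels, as_rgb_image(img))
})

test_that("the surrogate ranks a probability-driving superpixel first", {
  img <- random_image(24, 24, 12)
  cfg <- explanation_config("lime", lime_num_perturbations = 300)
  seg <- quickshift_segments(img, cfg)
  target <- as.integer(names(which.max(table(seg))))
  orig <- as_rgb_image(img)
  # probability of class 1 = 1 iff the designated superpixel is unperturbed
  b <- list(predict_probabilities = function(images, ...) {
    p <- vapply(images, function(im) {
      as.numeric(all(im[, , 1][seg == target] == orig[, , 1][seg == target]))
    }, numeric(1))
    cbind(0.5 + p / 2, 0.5 - p / 2)
  })
  l <- lime_representation(b, img, cfg, seed = 21)
  expect_equal(l$provenance$kept[1], target)
  # retained pixels keep their values, everything else is black
  mask <- seg %in% l$provenance$kept
  for (ch in 1:3) {
    expect_equal(l$pixels[, , ch][mask], orig[, , ch][mask])
    expect_true(all(l$pixels[, , ch][!mask] == 0))
  }
})

test_that("explanation feature vectors reuse the 116-feature layout", {
  ds <- small_texture_dataset(n_per_class = 1, seed = 8)
  b <- mock_backend("densenet121", seed = 2)
  v_cam <- xai_feature_vector(b, ds$images[[1]],
                              explanation_config("gradcam"))
  expect_length(v_cam, 116)
  cfg <- explanation_config("lime", lime_num_perturbations = 100)
  v1 <- xai_feature_vector(b, ds$images[[1]], cfg, seed = 4)
  v2 <- xai_feature_vector(b, ds$images[[1]], cfg, seed = 4)
  expect_identical(v1, v2)
  expect_length(v1, 116)
})
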