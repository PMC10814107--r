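test_that("fold plans are stratified, seeded and cover every sample", {
  y <- factor(rep(c("a", "b"), c(30, 24)))
  plan <- fold_plan(y, k = 10, seed = 3)
  expect_length(plan$assignment, 54)
  expect_true(all(plan$assignment %in% 1:10))
  sizes <- table(plan$assignment)
  expect_lte(max(sizes) - min(sizes), 2)
  # per-class balance within one image
  for (cl in levels(y)) {
    per <- table(factor(plan$assignment[y == cl], levels = 1:10))
    expect_lte(max(per) - min(per), 1)
  }
  expect_identical(plan$assignment, fold_plan(y, k = 10, seed = 3)$assignment)
  expect_false(identical(plan$assignment,
                         fold_plan(y, k = 10, seed = 4)$assignment))
})

test_that("relieff rewards label-aligned features and zeroes constants", {
  withr::with_seed(21, {
    y <- factor(rep(c("a", "b"), each = 20))
    X <- cbind(as.integer(y) + rnorm(40, sd = 0.01), matrix(rnorm(40 * 5), 40))
    w <- relieff_weights(X, y, 10)
    expect_equal(which.max(w), 1L)

    Xc <- cbind(rep(2, 40), rnorm(40))
    expect_identical(relieff_weights(Xc, y)[[1]], 0)
  })
  expect_error(relieff_weights(matrix(1:4, 2), factor(c("a", "a"))),
               "two classes")
  expect_error(relieff_weights(matrix(1, 1, 1), factor("a")), "two samples")
})

test_that("relieff weights match a hand-computed 4-sample case", {
  # 2 features, neighbors = 1; feature 1 separates the classes, feature 2
  # is identical within pairs across classes
  X <- matrix(c(0, 0.1, 1, 0.9,
                0, 1, 0, 1), 4)
  y <- factor(c("a", "a", "b", "b"))
  got <- relieff_weights(X, y, neighbors = 1)
  want <- relieff_brute(X, y, 1)
  expect_equal(unname(got), want)
  # nearest hit differs by 0.1 in f1, nearest miss by 0.8 (after range
  # normalization); f1 must dominate f2
  expect_gt(got[[1]], got[[2]])
})

test_that("relieff matches the brute-force oracle on random instance sets", {
  withr::with_seed(17, {
    for (i in 1:50) {
      n <- 12
      y <- factor(sample(c("a", "b"), n, replace = TRUE))
      while (min(table(y)) < 2) y <- factor(sample(c("a", "b"), n,
                                                   replace = TRUE))
      X <- matrix(rnorm(n * 4), n)
      k <- sample(1:4, 1)
      expect_equal(unname(relieff_weights(X, y, k)), relieff_brute(X, y, k),
                   tolerance = 1e-12)
    }
  })
})

test_that("top-k selection is deterministic with lower-index tie-breaking", {
  expect_equal(sort(select_top_k(c(3, 1, 2), 2)), c(1, 3))
  expect_equal(select_top_k(c(1, 1, 1), 2), c(1, 2))
  expect_setequal(select_top_k(1:5, 5), 1:5)
  expect_error(select_top_k(1:3, 4), "exceeds")
})

test_that("probability averaging picks the highest-mean class", {
  r <- average_probability_predict(list(c(0.6, 0.4), c(0.2, 0.8)))
  expect_equal(r$probabilities, c(0.4, 0.6))
  expect_equal(r$class, 2)

  r2 <- average_probability_predict(list(c(0.5, 0.5), c(0.5, 0.5)))
  expect_equal(r2$class, 1) # tie -> lowest index

  r4 <- average_probability_predict(list(c(0.9, 0.1), c(0.6, 0.4),
                                         c(0.4, 0.6), c(0.2, 0.8)))
  expect_equal(r4$probabilities, c(0.525, 0.475))
  expect_equal(r4$class, 1)

  expect_error(average_probability_predict(list()), "empty")
  expect_error(average_probability_predict(list(c(0.7, 0.6))), "sum to 1")
})

test_that("accuracy follows (TP+TN)/(TP+TN+FP+FN)", {
  expect_equal(accuracy_from_confusion(list(TP = 5, TN = 5, FP = 0, FN = 0)), 1)
  expect_equal(accuracy_from_confusion(list(TP = 3, TN = 2, FP = 1, FN = 2)),
               0.625)
  expect_equal(accuracy_from_confusion(list(TP = 0, TN = 0, FP = 4, FN = 4)), 0)
  expect_error(accuracy_from_confusion(list(TP = 0, TN = 0, FP = 0, FN = 0)),
               "zero")
})

test_that("ensemble probabilities sum to one and separable data is perfect", {
  withr::with_seed(8, {
    X <- rbind(matrix(rnorm(16 * 20, 4), 16), matrix(rnorm(16 * 20, -4), 16))
    y <- factor(rep(c("a", "b"), each = 16))
    pred <- fractalens:::ensemble_predict(X[c(1:12, 17:28), ], y[c(1:12, 17:28)],
                                          X[c(13:16, 29:32), ], seed = 1)
    expect_true(all(abs(rowSums(pred$probabilities) - 1) < 1e-9))
    expect_equal(as.character(pred$class), as.character(y[c(13:16, 29:32)]))
    expect_length(pred$per_classifier, 4)
  })
})

test_that("an all-constant feature subset degenerates to class priors", {
  # permuted-label folds can select only zero-variance features (ReliefF
  # weight 0 outranks negative weights); the ensemble must stay well-defined
  Xtr <- matrix(0, 54, 5)
  Xte <- matrix(0, 6, 5)
  y <- factor(rep(c("a", "b"), each = 27))
  p <- fractalens:::ensemble_predict(Xtr, y, Xte, seed = 15)
  expect_true(all(p$probabilities == 0.5))
  expect_equal(as.character(p$class), rep("a", 6)) # tie -> lowest index
})

test_that("cross-validated evaluation is exact on separable data", {
  withr::with_seed(14, {
    X <- rbind(matrix(rnorm(20 * 30, 5), 20), matrix(rnorm(20 * 30, -5), 20))
    y <- factor(rep(c("a", "b"), each = 20))
    plan <- fold_plan(y, k = 10, seed = 2)
    ev <- evaluate_composition(X, y, plan, sizes = c(5, 10), seed = 1)
    expect_equal(ev$records$mean_accuracy, c(1, 1))
    expect_equal(ev$records$mean_f1, c(1, 1))
    expect_length(ev$folds, 10)
    # contract arithmetic: every fold selects once per size
    expect_true(all(vapply(ev$folds, function(f) length(f$selected),
                           integer(1)) == 2))
  })
})

test_that("oversized subset sizes are skipped with a warning", {
  withr::with_seed(14, {
    X <- matrix(rnorm(24 * 8), 24)
    y <- factor(rep(c("a", "b"), each = 12))
    plan <- fold_plan(y, k = 3, seed = 2)
    expect_warning(ev <- evaluate_composition(X, y, plan, sizes = c(5, 25),
                                              seed = 1), "skipping")
    expect_equal(ev$records$subset_size, 5)
  })
})

test_that("feature selection never sees test-fold labels", {
  withr::with_seed(30, {
    X <- matrix(rnorm(30 * 15), 30)
    y <- factor(rep(c("a", "b"), each = 15))
    plan <- fold_plan(y, k = 5, seed = 9)
    base <- evaluate_composition(X, y, plan, sizes = c(5, 10), seed = 4)
    for (f in c(1, 3)) {
      y2 <- y
      test_rows <- which(plan$assignment == f)
      y2[test_rows] <- rev(y[test_rows]) # corrupt only the held-out labels
      alt <- evaluate_composition(X, y2, plan, sizes = c(5, 10), seed = 4)
      expect_identical(alt$folds[[f]]$selected, base$folds[[f]]$selected)
    }
  })
})

test_that("informative features are recovered from a 500-feature haystack", {
  withr::with_seed(55, {
    n <- 60
    y <- factor(rep(c("a", "b"), each = n / 2))
    signal <- matrix(rnorm(n * 5, mean = ifelse(y == "a", 1.5, -1.5)), n)
    X <- cbind(signal, matrix(rnorm(n * 495), n))
    plan <- fold_plan(y, k = 10, seed = 5)
    hits <- 0
    for (f in 1:10) {
      tr <- plan$assignment != f
      w <- relieff_weights(X[tr, ], y[tr], 10)
      if (all(1:5 %in% select_top_k(w, 5))) hits <- hits + 1
    }
    expect_gte(hits, 9)
  })
})

test_that("solutions rank by accuracy then parsimony then name", {
  rec <- data.frame(
    composition = c("B", "A", "C"),
    subset_size = c(25, 10, 10),
    mean_accuracy = c(0.9, 0.9, 0.8))
  top <- rank_top_solutions(rec, 10)
  expect_equal(top$composition, c("A", "B", "C"))

  one <- rank_top_solutions(rec[1, , drop = FALSE])
  expect_equal(nrow(one), 1)

  withr::with_seed(2, {
    rec12 <- data.frame(composition = sprintf("c%02d", 1:12),
                        subset_size = sample(c(5, 10, 15, 20, 25), 12, TRUE),
                        mean_accuracy = round(runif(12), 2))
    top10 <- rank_top_solutions(rec12, 10)
    ord <- order(-rec12$mean_accuracy, rec12$subset_size, rec12$composition)
    expect_equal(top10$composition, rec12$composition[ord][1:10])
    expect_equal(nrow(top10), 10)
  })
})

test_that("friedman comparison ranks categories and is exact on ties", {
  m <- matrix(rep(c(90, 90, 90, 90), 3), 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  fm <- friedman_comparison(m)
  expect_true(all(fm$average_ranking == 2))
  expect_equal(fm$statistic, 0)
  expect_equal(fm$p_value, 1)

  # rank sums total k(k+1)/2 per dataset
  withr::with_seed(6, {
    m2 <- matrix(runif(5 * 4, 70, 100), 5, 4,
                 dimnames = list(letters[1:5], NULL))
    fm2 <- friedman_comparison(m2)
    expect_true(all(abs(colSums(fm2$ranks) - 5 * 6 / 2) < 1e-12))
    # cross-check the omnibus statistic against stats::friedman.test
    ref <- stats::friedman.test(t(m2))
    expect_equal(fm2$statistic, unname(ref$statistic))
    expect_equal(fm2$p_value, unname(ref$p.value))
  })

  m3 <- m; m3[1, 1] <- NA
  expect_error(friedman_comparison(m3), "missing")
  expect_error(friedman_comparison(m[1, , drop = FALSE]), "at least 2")
})

test_that("the published 6x4 category matrix reproduces the printed ranking", {
  fm <- friedman_comparison(category_mean_accuracy())
  expect_equal(unname(fm$average_ranking),
               c(1, 2.25, 2.75, 4.75, 4.75, 5.5))
  expect_equal(names(fm$average_ranking)[1], "ens_deep")
  expect_equal(fm$p_value, 0.0033, tolerance = 0.01)
})
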