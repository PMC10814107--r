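# Leakage-safe evaluation: per-fold ReliefF feature selection at subset
# sizes 5..25, a four-algorithm probability-averaging classifier ensemble,
# 10-fold cross-validation, solution ranking and Friedman comparison of
# feature-vector categories.

#' Stratified cross-validation fold plan
#'
#' Assigns every sample to one of `k` folds of approximately equal size,
#' stratified by class so each fold mirrors the label balance; seeded.
#'
#' @param labels Factor of class labels (names, if present, become ids).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return A `fold_plan`: `k`, `assignment` (integer fold per sample) and
#'   `seed`.
#' @export
fold_plan <- function(labels, k = 10L, seed = 1L) {
  y <- as.factor(labels)
  if (length(y) < k) stop("fewer samples than folds", call. = FALSE)
  assignment <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  names(assignment) <- names(labels)
  structure(list(k = as.integer(k), assignment = assignment,
                 seed = as.integer(seed)), class = "fold_plan")
}

#' ReliefF feature weights
#'
#' Standard ReliefF: every instance is used; for each, the `neighbors`
#' nearest hits (same class) and nearest misses per other class update the
#' feature weights with range-normalized value differences, miss
#' contributions weighted by the class prior ratio P(c)/(1 - P(class(i))).
#' Nearest neighbors are found under the Manhattan distance on the
#' range-normalized features. Constant features receive weight exactly 0.
#'
#' @param features Numeric matrix or data frame (rows = instances).
#' @param labels Factor of class labels, one per row.
#' @param neighbors Hits/misses per class considered (default 10, clamped to
#'   the available class size).
#' @return Numeric weight per feature; higher means more relevant. Rank with
#'   [select_top_k()].
#' @export
relieff_weights <- function(features, labels, neighbors = 10L) {
  X <- as.matrix(features)
  y <- droplevels(as.factor(labels))
  n <- nrow(X)
  if (n < 2L) stop("at least two samples required", call. = FALSE)
  if (nlevels(y) < 2L) stop("labels must contain at least two classes",
                            call. = FALSE)

  rng <- apply(X, 2, function(col) diff(range(col)))
  scale <- ifelse(rng > 0, rng, 1)
  Xn <- sweep(sweep(X, 2, apply(X, 2, min)), 2, scale, "/")
  Xn[, rng == 0] <- 0 # constant features contribute no diff anywhere

  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  priors <- table(y) / n
  W <- numeric(ncol(X))

  for (i in seq_len(n)) {
    cl <- y[i]
    for (c2 in levels(y)) {
      pool <- setdiff(which(y == c2), i)
      if (!length(pool)) next
      k_i <- min(neighbors, length(pool))
      nn <- pool[order(D[i, pool])[seq_len(k_i)]]
      diffsum <- colSums(abs(Xn[nn, , drop = FALSE] -
                               matrix(Xn[i, ], k_i, ncol(Xn), byrow = TRUE)))
      if (c2 == cl) {
        W <- W - diffsum / (n * k_i)
      } else {
        W <- W + (priors[[c2]] / (1 - priors[[as.character(cl)]])) *
          diffsum / (n * k_i)
      }
    }
  }
  stats::setNames(W, colnames(X))
}

#' Indices of the k largest feature weights
#'
#' Deterministic under ties: the lower index wins.
#'
#' @param weights Numeric vector of feature weights.
#' @param k Subset size.
#' @return Integer indices in descending-weight order.
#' @export
select_top_k <- function(weights, k) {
  if (k > length(weights)) stop("k exceeds the number of features",
                                call. = FALSE)
  order(-weights, seq_along(weights))[seq_len(k)]
}

#' Soft-voting combination of classifier probabilities
#'
#' Averages the per-class probability vectors of the individual classifiers
#' and assigns the class with the highest mean; ties go to the lowest class
#' index.
#'
#' @param per_classifier_probabilities List of numeric class-probability
#'   vectors (same length, each summing to 1 within 1e-6).
#' @return List with `class` (index of the assigned class) and
#'   `probabilities` (the averaged vector).
#' @examples
#' average_probability_predict(list(c(0.6, 0.4), c(0.2, 0.8)))$class # 2
#' @export
average_probability_predict <- function(per_classifier_probabilities) {
  ps <- per_classifier_probabilities
  if (!length(ps)) stop("empty classifier list", call. = FALSE)
  len <- unique(vapply(ps, length, integer(1)))
  if (length(len) != 1L) stop("probability vectors differ in length",
                              call. = FALSE)
  for (p in ps) {
    if (abs(sum(p) - 1) > 1e-6)
      stop("probability vector does not sum to 1", call. = FALSE)
  }
  avg <- Reduce(`+`, ps) / length(ps)
  list(class = which.max(avg), probabilities = avg)
}

#' Accuracy from confusion counts
#'
#' (TP + TN) / (TP + TN + FP + FN).
#'
#' @param counts Named list or vector with `TP`, `TN`, `FP`, `FN`.
#' @return Fraction correct.
#' @export
accuracy_from_confusion <- function(counts) {
  counts <- as.list(counts)
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total <= 0) stop("confusion counts sum to zero", call. = FALSE)
  (counts$TP + counts$TN) / total
}

# Macro-averaged F1 over classes; empty denominators contribute 0.
macro_f1 <- function(truth, predicted, levels) {
  f1 <- vapply(levels, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

# Train the four-algorithm ensemble and predict class probabilities for the
# test rows. Probabilities are re-normalized per classifier before averaging.
# Zero-variance training columns are dropped before fitting (they carry no
# information and destabilize some fitters); if every column is constant the
# ensemble degenerates to the training class priors.
ensemble_predict <- function(X_train, y_train, X_test, seed = 1L) {
  lv <- levels(y_train)
  X_train <- as.matrix(X_train)
  X_test <- as.matrix(X_test, ncol = ncol(X_train))

  keep <- apply(X_train, 2, function(col) diff(range(col)) > 0)
  if (!any(keep)) {
    prior <- as.numeric(table(y_train)) / length(y_train)
    avg <- matrix(prior, nrow(X_test), length(lv), byrow = TRUE,
                  dimnames = list(NULL, lv))
    probs <- stats::setNames(rep(list(avg), 4),
                             c("svm", "naive_bayes", "random_forest", "knn"))
    return(list(class = factor(lv[max.col(avg, ties.method = "first")],
                               levels = lv),
                probabilities = avg, per_classifier = probs))
  }
  X_train <- X_train[, keep, drop = FALSE]
  X_test <- X_test[, keep, drop = FALSE]
  dfr <- as.data.frame(X_train)
  dte <- as.data.frame(X_test)
  names(dte) <- names(dfr)

  probs <- withr::with_seed(seed, {
    svm_fit <- e1071::svm(X_train, y_train, probability = TRUE)
    svm_p <- attr(stats::predict(svm_fit, X_test, probability = TRUE),
                  "probabilities")[, lv, drop = FALSE]
    nb_fit <- e1071::naiveBayes(dfr, y_train)
    nb_p <- stats::predict(nb_fit, dte, type = "raw")[, lv, drop = FALSE]
    rf_fit <- randomForest::randomForest(X_train, y_train, ntree = 100)
    rf_p <- stats::predict(rf_fit, X_test, type = "prob")[, lv, drop = FALSE]
    knn_fit <- caret::knn3(X_train, y_train, k = min(5L, nrow(X_train)))
    knn_p <- stats::predict(knn_fit, X_test, type = "prob")[, lv, drop = FALSE]
    list(svm = svm_p, naive_bayes = nb_p, random_forest = rf_p, knn = knn_p)
  })
  probs <- lapply(probs, function(p) p / rowSums(p))

  avg <- Reduce(`+`, probs) / length(probs)
  list(class = factor(lv[max.col(avg, ties.method = "first")], levels = lv),
       probabilities = avg, per_classifier = probs)
}

#' Cross-validated evaluation of one feature composition
#'
#' For every fold: ReliefF is fitted on the training rows only (leakage-safe);
#' for each requested subset size the top-k features are selected, the four
#' classifiers (SVM, naive Bayes, random forest, K-nearest neighbors) are
#' trained on the training rows' subset, and the probability-averaging
#' ensemble classifies the held-out rows. Accuracy and macro F1 are averaged
#' over folds. Sizes exceeding the table dimension are skipped with a
#' warning.
#'
#' @param table Data frame with `image_id` plus feature columns (or a plain
#'   feature matrix).
#' @param labels Factor of class labels, one per row of `table`.
#' @param plan A [fold_plan()] covering all rows.
#' @param sizes Feature subset sizes (default 5, 10, 15, 20, 25).
#' @param neighbors ReliefF neighbor count.
#' @param seed Seed for the stochastic classifiers.
#' @param composition_name Label stored in the records.
#' @return A `solution_records` list: `records` (data frame with
#'   `composition`, `subset_size`, `mean_accuracy`, `mean_f1`) and `folds`
#'   (per-fold accuracies and selected feature indices per size).
#' @export
evaluate_composition <- function(table, labels, plan,
                                 sizes = c(5L, 10L, 15L, 20L, 25L),
                                 neighbors = 10L, seed = 1L,
                                 composition_name = "composition") {
  X <- if (is.data.frame(table) && "image_id" %in% names(table))
    as.matrix(table[, setdiff(names(table), "image_id"), drop = FALSE])
  else as.matrix(table)
  y <- droplevels(as.factor(labels))
  if (nrow(X) != length(plan$assignment))
    stop("fold plan does not cover all rows", call. = FALSE)

  usable <- sizes[sizes <= ncol(X)]
  if (length(usable) < length(sizes))
    warning(sprintf("skipping subset size(s) > %d features", ncol(X)),
            call. = FALSE)

  fold_detail <- vector("list", plan$k)
  acc <- matrix(NA_real_, plan$k, length(usable),
                dimnames = list(NULL, usable))
  f1 <- acc
  for (f in seq_len(plan$k)) {
    tr <- plan$assignment != f
    w <- relieff_weights(X[tr, , drop = FALSE], y[tr], neighbors)
    selected <- list()
    for (si in seq_along(usable)) {
      k <- usable[si]
      sel <- select_top_k(w, k)
      selected[[as.character(k)]] <- sel
      pred <- ensemble_predict(X[tr, sel, drop = FALSE], droplevels(y[tr]),
                               X[!tr, sel, drop = FALSE],
                               seed = seed + f)
      acc[f, si] <- mean(pred$class == y[!tr])
      f1[f, si] <- macro_f1(y[!tr], pred$class, levels(y))
    }
    fold_detail[[f]] <- list(selected = selected, accuracy = acc[f, ],
                             f1 = f1[f, ])
  }

  records <- data.frame(
    composition = composition_name,
    subset_size = usable,
    mean_accuracy = colMeans(acc),
    mean_f1 = colMeans(f1),
    row.names = NULL)
  structure(list(records = records, folds = fold_detail,
                 fold_accuracy = acc), class = "solution_records")
}

#' Rank solutions: highest accuracy with the fewest descriptors
#'
#' Sorts records by mean accuracy (descending), then subset size
#' (ascending), then composition name, and returns the first `n`.
#'
#' @param records Data frame with `composition`, `subset_size`,
#'   `mean_accuracy` (and usually `mean_f1`), e.g. row-bound `records` from
#'   [evaluate_composition()].
#' @param n Number of top solutions (default 10).
#' @return The top `n` rows in rank order.
#' @export
rank_top_solutions <- function(records, n = 10L) {
  if (!nrow(records)) stop("no records to rank", call. = FALSE)
  ord <- order(-records$mean_accuracy, records$subset_size,
               records$composition)
  utils::head(records[ord, , drop = FALSE], n)
}

#' Friedman comparison of feature-vector categories across datasets
#'
#' Ranks the categories within each dataset (rank 1 = highest mean accuracy,
#' mid-ranks on ties), averages the ranks per category, and computes the
#' Friedman chi-square statistic with `categories - 1` degrees of freedom
#' and its p-value.
#'
#' @param matrix Numeric matrix of mean accuracies, categories in rows,
#'   datasets in columns; no missing cells.
#' @return A `comparison_matrix` list: `mean_accuracy`, `ranks`,
#'   `average_ranking` (named, sorted best first), `statistic`, `df`,
#'   `p_value`.
#' @export
friedman_comparison <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 categories and 2 datasets", call. = FALSE)
  if (anyNA(m)) stop("missing cells in the comparison matrix", call. = FALSE)
  k <- nrow(m) # categories (treatments)
  b <- ncol(m) # datasets (blocks)
  ranks <- apply(m, 2, function(col) rank(-col, ties.method = "average"))
  avg <- rowMeans(ranks)
  rank_sums <- rowSums(ranks)
  statistic <- 12 / (b * k * (k + 1)) * sum(rank_sums^2) - 3 * b * (k + 1)
  # no tie correction applied: at most mid-rank ties occur in practice and
  # the uncorrected statistic matches the classical formulation
  p <- stats::pchisq(statistic, df = k - 1, lower.tail = FALSE)
  structure(list(mean_accuracy = m, ranks = ranks,
                 average_ranking = sort(stats::setNames(avg, rownames(m))),
                 statistic = statistic, df = k - 1, p_value = p),
            class = "comparison_matrix")
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat("Friedman comparison:", nrow(x$mean_accuracy), "categories x",
      ncol(x$mean_accuracy), "datasets\n")
  cat("  chi-square =", format(x$statistic, digits = 5), " df =", x$df,
      " p =", format(x$p_value, digits = 3), "\n")
  cat("  average ranking (best first):\n")
  print(round(x$average_ranking, 3))
  invisible(x)
}

#' Published category-mean accuracy matrix
#'
#' Mean accuracies (%) of the six feature-vector categories (handcrafted,
#' deep-learned, xAI, and their three ensemble groups) over four H&E
#' histology datasets (colorectal, liver, oral dysplasia, breast), as
#' reported in the literature the package's design follows. Shipped as a
#' plain-text table for the Friedman comparison example.
#'
#' @return 6 x 4 numeric matrix (categories x datasets).
#' @export
category_mean_accuracy <- function() {
  path <- system.file("extdata", "category_mean_accuracy.csv",
                      package = "fractalens")
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(tab)
}
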