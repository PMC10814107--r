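# Independent brute-force oracles kept deliberately naive: these re-derive
# expected results by direct enumeration and never share code with the
# package implementation.

# Recursive flood fill connected-component labeling.
flood_fill_labels <- function(mask, connectivity = 4) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  if (connectivity == 4) {
    offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  lab <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j] || labels[i, j] > 0L) next
    lab <- lab + 1L
    stack <- list(c(i, j))
    labels[i, j] <- lab
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in offs) {
        ni <- cur[1] + o[1]; nj <- cur[2] + o[2]
        if (ni >= 1 && ni <= h && nj >= 1 && nj <= w &&
            mask[ni, nj] && labels[ni, nj] == 0L) {
          labels[ni, nj] <- lab
          stack[[length(stack) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  sizes <- if (lab > 0) tabulate(labels[labels > 0], lab) else integer(0)
  list(labels = labels, sizes = sizes, n_clusters = lab)
}

# Plain-loop ReliefF update rule: all instances, k nearest hits/misses per
# class under Manhattan distance on range-normalized features, miss terms
# weighted by P(c)/(1 - P(class_i)).
relieff_brute <- function(X, y, k) {
  X <- as.matrix(X)
  y <- as.factor(y)
  n <- nrow(X); p <- ncol(X)
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  span <- hi - lo
  nd <- function(f, a, b) {
    if (span[f] == 0) return(0)
    abs(X[a, f] - X[b, f]) / span[f]
  }
  manh <- function(a, b) {
    s <- 0
    for (f in seq_len(p)) s <- s + nd(f, a, b)
    s
  }
  prior <- table(y) / n
  W <- numeric(p)
  for (i in seq_len(n)) {
    for (cl in levels(y)) {
      pool <- setdiff(which(y == cl), i)
      if (length(pool) == 0) next
      dists <- vapply(pool, function(j) manh(i, j), numeric(1))
      ki <- min(k, length(pool))
      nn <- pool[order(dists)[seq_len(ki)]]
      for (f in seq_len(p)) {
        contrib <- sum(vapply(nn, function(j) nd(f, i, j), numeric(1)))
        if (cl == as.character(y[i])) {
          W[f] <- W[f] - contrib / (n * ki)
        } else {
          W[f] <- W[f] + (prior[[cl]] / (1 - prior[[as.character(y[i])]])) *
            contrib / (n * ki)
        }
      }
    }
  }
  W
}

# Trapezoid area by direct summation (independent of the package helper).
trapezoid_area_brute <- function(f, a, b, n = length(f)) {
  s <- 0
  for (i in a:(b - 1)) s <- s + f[i] + f[i + 1]
  (b - a) / (2 * n) * s
}
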