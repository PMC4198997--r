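# Independent naive implementations used as oracles, deliberately written
# element-by-element and kept separate from the package internals.

naive_entropy <- function(x, k) {
  # x: raw matrix, cost orientation; frequencies from normalized values
  n <- nrow(x); m <- ncol(x)
  e <- numeric(m)
  for (j in seq_len(m)) {
    r <- numeric(n)
    for (i in seq_len(n))
      r[i] <- (max(x[, j]) - x[i, j]) / (max(x[, j]) - min(x[, j]))
    f <- r / sum(r)
    s <- 0
    for (i in seq_len(n)) if (f[i] > 0) s <- s + f[i] * log(f[i])
    e[j] <- -k * s
  }
  e
}

naive_argmin_level <- function(day, centers, weights = NULL) {
  # brute force over centers; ties -> worst (largest index)
  bestd <- Inf; best <- 0L
  for (l in seq_len(nrow(centers))) {
    s <- 0
    for (j in seq_len(ncol(centers))) {
      w <- if (is.null(weights)) 1 else weights[j]
      s <- s + w * (day[j] - centers[l, j])^2
    }
    d <- sqrt(s)
    if (d < bestd || d == bestd) { bestd <- d; best <- l }
  }
  best
}

random_obs_matrix <- function(n, m, max = 300) {
  mat <- matrix(stats::runif(n * m, 0, max), n, m)
  colnames(mat) <- paste0("X", seq_len(m))
  mat
}
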