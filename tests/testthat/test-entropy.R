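test_that("min-max normalization maps cost indicators onto [0, 1]", {
  obs <- beijing_feb2014()
  r <- normalize_minmax(as_observation_matrix(obs))
  expect_true(all(r >= 0 & r <= 1))
  # PM2.5: min 5 (02-03) -> 1, max 387 (02-15) -> 0, midpoint symmetry
  expect_equal(r["02-03", "PM2.5"], 1)
  expect_equal(r["02-15", "PM2.5"], 0)
  expect_equal((387 - 196) / 382, 0.5)
  x <- matrix(c(5, 196, 387), dimnames = list(NULL, "PM2.5"))
  expect_equal(unname(normalize_minmax(x)[2, 1]), 0.5)
  # benefit orientation flips the ends
  b <- normalize_minmax(x, orientation = "benefit")
  expect_equal(b[, 1], c(0, 0.5, 1))
  expect_error(normalize_minmax(matrix(c(3, 3, 3))), "constant column")
  expect_error(normalize_minmax(matrix(c(-1, 2))), "negative")
})

test_that("relative frequencies sum to one per indicator", {
  expect_equal(relative_frequencies(cbind(c(0.2, 0.2, 0.6)))[, 1],
               c(0.2, 0.2, 0.6))
  expect_equal(relative_frequencies(cbind(rep(1, 4)))[, 1], rep(0.25, 4))
  expect_error(relative_frequencies(cbind(c(0, 0, 0))), "all-zero")
  f <- relative_frequencies(normalize_minmax(
    as_observation_matrix(beijing_feb2014())))
  expect_equal(unname(colSums(f)), rep(1, 5), tolerance = 1e-12)
  expect_true(all(f >= 0))
})

test_that("entropy closed forms hold", {
  # uniform distribution over n objects with k = 1/ln n has entropy 1
  f <- cbind(rep(1 / 7, 7))
  expect_equal(unname(entropy_values(f, "objects")$entropy), 1)
  # a point mass has entropy 0 under the 0 ln 0 convention, any k
  f0 <- cbind(c(1, 0, 0, 0))
  expect_equal(unname(entropy_values(f0, "objects")$entropy), 0)
  expect_equal(unname(entropy_values(f0, "custom", k = 3)$entropy), 0)
  # two-object normalized column (1, 0) is a point mass
  r2 <- normalize_minmax(matrix(c(10, 40)))
  expect_equal(unname(relative_frequencies(r2)[, 1]), c(1, 0))
  expect_error(entropy_values(f, "custom", k = -1), "invalid entropy")
})

test_that("weights follow (1 - e) / sum(1 - e) and sum to one", {
  # equal entropies share weight equally; maximum entropy gets zero
  expect_equal(entropy_weights(c(0.5, 0.5))$weights, c(0.5, 0.5))
  expect_equal(entropy_weights(c(0.5, 1.0))$weights, c(1, 0))
  expect_error(entropy_weights(c(1, 1)), "zero")
  w <- entropy_weights(c(0.2, 0.9, 1.4))
  expect_equal(sum(w$weights), 1, tolerance = 1e-10)
  expect_match(paste(w$notes, collapse = " "), "outside")
})

test_that("entropy pipeline matches a naive per-element oracle", {
  set.seed(101)
  for (rep in 1:5) {
    x <- random_obs_matrix(10, 4)
    w <- aq_entropy_weights(x)
    expect_equal(unname(w$entropy), naive_entropy(x, 1 / log(nrow(x))),
                 tolerance = 1e-12)
  }
})

test_that("weights are permutation-equivariant and scale-invariant", {
  set.seed(7)
  x <- random_obs_matrix(12, 5)
  w <- aq_entropy_weights(x)$weights
  perm <- c(3, 1, 5, 2, 4)
  wp <- aq_entropy_weights(x[, perm])$weights
  expect_equal(unname(wp), unname(w[perm]), tolerance = 1e-12)
  # multiplying one raw column by a positive constant changes nothing
  x2 <- x; x2[, 2] <- x2[, 2] * 37.5
  expect_equal(aq_entropy_weights(x2)$weights, w, tolerance = 1e-12)
  expect_equal(sum(w), 1, tolerance = 1e-10)
})
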