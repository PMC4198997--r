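test_that("euclidean distance computes plain and weighted forms", {
  expect_equal(euclidean_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(0, 0), c(3, 4), c(0.5, 0.5)),
               sqrt(12.5))
  expect_error(euclidean_distance(1:3, 1:2), "length mismatch")
})

test_that("euclidean distance satisfies the metric axioms", {
  set.seed(11)
  for (rep in 1:120) {
    a <- runif(4); b <- runif(4); c <- runif(4)
    dab <- euclidean_distance(a, b)
    expect_gte(dab, 0)
    expect_equal(dab, euclidean_distance(b, a))
    expect_equal(euclidean_distance(a, a), 0)
    expect_lte(dab, euclidean_distance(a, c) + euclidean_distance(c, b) + 1e-12)
  }
  # cross-check against stats::dist on a batch of random pairs
  set.seed(12)
  m <- matrix(runif(20), 10, 2)
  expect_equal(euclidean_distance(m[1, ], m[2, ]),
               as.numeric(stats::dist(m[1:2, ])))
})

test_that("joint normalization pools observations with centers", {
  cen <- build_centers("GB3095-2012", c("PM2.5", "PM10", "SO2"))
  obs <- beijing_feb2014()
  jn <- joint_normalize(obs[c("date", "PM2.5", "PM10", "SO2")], cen)
  # PM2.5 pool is 5..387 (centers 35, 75 interior): Level I -> 0.9215
  expect_equal(unname(jn$centers["I", "PM2.5"]), (387 - 35) / 382,
               tolerance = 1e-12)
  expect_equal(round(unname(jn$centers["I", "PM2.5"]), 4), 0.9215)
  # SO2 pool max is the Level II threshold itself
  expect_equal(unname(jn$max["SO2"]), 150)
  expect_true(all(jn$observations >= 0 & jn$observations <= 1))
  expect_true(all(jn$centers >= 0 & jn$centers <= 1))

  # a day lying exactly on a center row lands on its coordinates
  one <- matrix(c(35, 50, 50, 387, 443, 102), 2, 3, byrow = TRUE,
                dimnames = list(NULL, c("PM2.5", "PM10", "SO2")))
  jn2 <- joint_normalize(one, cen)
  expect_equal(unname(jn2$observations[1, ]), unname(jn2$centers["I", ]))

  # single indicator midpoint case
  o <- matrix(c(0, 10), dimnames = list(NULL, "X"))
  cenX <- matrix(5, dimnames = list("I", "X"))
  jn3 <- joint_normalize(o, cenX)
  expect_equal(unname(jn3$observations[, 1]), c(1, 0))
  expect_equal(unname(jn3$centers[1, 1]), 0.5)
})

test_that("unit mismatches between observations and centers are errors", {
  cen <- build_centers("GB3095-1996", c("PM10", "CO", "SO2"))
  obs <- beijing_feb2014()
  attr(obs, "units")["CO"] <- "ug/m3"
  expect_error(joint_normalize(obs, cen), "unit mismatch")
})

test_that("classification is an argmin with a worst-level tie rule", {
  cen <- rbind(I = c(0, 0), II = c(1, 1))
  got <- classify_nearest(c(0.1, 0.1), cen)
  expect_equal(got$level, 1L)
  # exact tie goes to the more polluted level by default
  tied <- classify_nearest(c(0.5, 0.5), cen)
  expect_equal(tied$level, 2L)
  expect_equal(classify_nearest(c(0.5, 0.5), cen, tie = "best")$level, 1L)
  expect_error(classify_nearest(c(0.5, 0.5), cen[0, , drop = FALSE]),
               "no centers")
})

test_that("classification agrees with a brute-force oracle", {
  set.seed(21)
  for (rep in 1:120) {
    nlev <- sample(2:4, 1); m <- sample(1:5, 1)
    cen <- matrix(runif(nlev * m), nlev, m)
    day <- runif(m)
    w <- if (rep %% 2) NULL else runif(m)
    got <- classify_nearest(day, cen, w)
    expect_equal(got$level, naive_argmin_level(day, cen, w))
  }
})

test_that("evaluation is invariant to indicator order and unit rescaling", {
  obs <- beijing_feb2014()
  f1 <- aq_evaluate(obs, "GB3095-2012")
  f2 <- aq_evaluate(obs[c("date", "SO2", "PM10", "CO", "NO2", "PM2.5")],
                    "GB3095-2012")
  expect_equal(as.character(f1$level), as.character(f2$level))

  # rescale SO2 consistently in observations and in a custom standard
  std <- aq_standard("GB3095-2012")
  std$thresholds$value[std$thresholds$code == "SO2"] <-
    std$thresholds$value[std$thresholds$code == "SO2"] * 1000
  obs2 <- obs; obs2$SO2 <- obs2$SO2 * 1000
  attr(obs2, "units") <- NULL
  f3 <- aq_evaluate(obs2, std)
  expect_equal(as.character(f3$level), as.character(f1$level))
  expect_equal(f3$distances, f1$distances, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("raising a cost indicator pulls a day toward worse levels", {
  cen <- build_centers("GB3095-2012", c("PM2.5", "PM10"))
  obs <- beijing_feb2014()
  grid <- seq(10, 380, by = 10)
  gap <- sapply(grid, function(v) {
    newd <- rbind(as_observation_matrix(obs)[, c("PM2.5", "PM10")],
                  c(v, 100))
    jn <- joint_normalize(newd, cen)
    d <- classify_nearest(jn$observations[nrow(newd), ], jn$centers)$distances
    d[1, 2] - d[1, 1]   # distance to II minus distance to I
  })
  expect_true(all(diff(gap) <= 1e-9))
})

test_that("full evaluation returns labelled days and provenance", {
  obs <- beijing_feb2014()
  fit <- aq_evaluate(obs, "GB3095-2012")
  expect_s3_class(fit, "aq_eval")
  expect_length(fit$level, 28)
  expect_true(all(fit$level %in% c("I", "II")))
  expect_setequal(fit$dropped, c("CO", "NO2"))
  expect_setequal(fit$retained, c("PM2.5", "PM10", "SO2"))

  old <- aq_evaluate(obs, "GB3095-1996")
  expect_true(all(old$level %in% c("I", "II", "III")))
  expect_length(old$retained, 4)

  expect_error(aq_evaluate(obs[0, ], "GB3095-2012"), "empty observation")
})

test_that("predict applies the fitted normalization to new days", {
  obs <- beijing_feb2014()
  fit <- aq_evaluate(obs, "GB3095-2012")
  pred <- predict(fit, obs)
  expect_equal(pred$rank, as.character(fit$level))
  expect_equal(as.matrix(pred[paste0("d", 1:2)]), fit$distances,
               ignore_attr = TRUE)
  clean <- data.frame(PM2.5 = 5, PM10 = 20, SO2 = 5)
  expect_equal(predict(fit, clean)$rank, "I")
})

test_that("standard comparison flags per-day concordance", {
  obs <- beijing_feb2014()
  cmp <- compare_standards(obs)
  expect_equal(nrow(cmp$table), 28)
  expect_type(cmp$table$concordant, "logical")
  one <- compare_standards(obs[obs$date == "02-15", ])
  expect_equal(nrow(one$table), 1)
  # comparing a standard against itself is fully concordant
  self <- compare_standards(obs, c("GB3095-2012", "GB3095-2012"),
                            config = "default")
  expect_true(all(self$table$concordant))
})
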