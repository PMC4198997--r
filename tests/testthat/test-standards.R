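test_that("built-in threshold tables hold the regulatory values", {
  new <- aq_standard("GB3095-2012")
  old <- aq_standard("GB3095-1996")
  expect_equal(new$levels, c("I", "II"))
  expect_equal(old$levels, c("I", "II", "III"))

  get <- function(std, want, time) {
    rows <- std$thresholds[std$thresholds$code == want &
                           std$thresholds$averaging_time == time, ]
    rows$value[order(rows$level)]
  }
  expect_equal(get(new, "PM2.5", "24h"), c(35, 75))
  expect_equal(get(new, "PM10", "24h"), c(50, 150))
  expect_equal(get(new, "SO2", "24h"), c(50, 150))
  expect_equal(get(new, "NO2", "24h"), c(80, 80))
  expect_equal(get(new, "CO", "24h"), c(4, 4))
  expect_equal(get(new, "O3", "8h"), c(100, 160))
  expect_equal(get(old, "SO2", "24h"), c(50, 150, 250))
  expect_equal(get(old, "PM10", "24h"), c(50, 150, 250))
  expect_equal(get(old, "NO2", "24h"), c(80, 80, 120))
  expect_equal(get(old, "CO", "24h"), c(4, 4, 6))
  expect_equal(get(old, "O3", "1h"), c(120, 160, 200))
  # the 2012 revision has no PM2.5 in the 1996 standard
  expect_false("PM2.5" %in% old$thresholds$code)
})

test_that("unknown standards and malformed configs are rejected", {
  expect_error(aq_standard("GB3095-2099"), "unknown standard")
  bad <- aq_standard("GB3095-2012")
  bad$thresholds$value[bad$thresholds$code == "PM2.5" &
                       bad$thresholds$averaging_time == "24h"] <- c(75, 35)
  expect_error(aqeval:::validate_standard(bad), "non-monotone")
})

test_that("standards round-trip through the YAML config format", {
  std <- aq_standard("GB3095-1996")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_standard(std, path)
  back <- read_standard(path)
  expect_equal(back$id, std$id)
  expect_equal(back$levels, std$levels)
  key <- function(th) th[order(th$code, th$averaging_time, th$level), ]
  expect_equal(key(back$thresholds), key(std$thresholds),
               ignore_attr = TRUE)
})

test_that("center construction drops only all-level-degenerate indicators", {
  cen <- build_centers("GB3095-2012", c("PM2.5", "PM10", "CO", "NO2", "SO2"))
  expect_setequal(attr(cen, "dropped"), c("CO", "NO2"))
  expect_equal(sort(colnames(cen)), c("PM10", "PM2.5", "SO2"))
  expect_equal(cen[, "SO2"], c(I = 50, II = 150))
  expect_equal(cen[, "PM2.5"], c(I = 35, II = 75))

  # 1996: CO and NO2 coincide at I/II but differ at III, so all are kept
  cen96 <- build_centers("GB3095-1996", c("PM10", "CO", "NO2", "SO2"))
  expect_length(attr(cen96, "dropped"), 0)
  expect_equal(nrow(cen96), 3)
  expect_equal(cen96[, "CO"], c(I = 4, II = 4, III = 6))
})

test_that("retained center coordinates strictly increase with level", {
  for (sid in standard_ids()) {
    cen <- build_centers(sid)
    for (j in seq_len(ncol(cen)))
      expect_true(all(diff(cen[, j]) >= 0) && cen[1, j] < cen[nrow(cen), j],
                  label = paste(sid, colnames(cen)[j]))
  }
})

test_that("dropping is invariant to indicator order and errors when empty", {
  a <- build_centers("GB3095-2012", c("PM2.5", "CO", "SO2", "NO2", "PM10"))
  b <- build_centers("GB3095-2012", c("NO2", "PM10", "SO2", "PM2.5", "CO"))
  expect_setequal(attr(a, "dropped"), attr(b, "dropped"))
  expect_equal(a[, sort(colnames(a))], b[, sort(colnames(b))])
  expect_error(build_centers("GB3095-2012", c("CO", "NO2")), "degenerate")
  expect_error(build_centers("GB3095-2012", c("PM2.5", "O3")),
               "without 24h thresholds")
})
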