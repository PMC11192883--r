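test_that("per-scene lake mean and coverage follow the pixel counts", {
  vals <- matrix(NA_real_, 5, 5)
  vals[1, 1:3] <- c(40, 50, 60)
  tsi <- structure(list(values = vals, valid_count = 3L, lake_total = 10L,
                        n_clamped = 0L), class = "tsi_raster")
  m <- lake_scene_mean(tsi)
  expect_equal(m$tsi_mean, 50)
  expect_equal(m$coverage_pct, 30)
  # empty raster
  tsi$values[] <- NA; tsi$valid_count <- 0L
  m2 <- lake_scene_mean(tsi)
  expect_true(is.na(m2$tsi_mean))
  expect_equal(m2$coverage_pct, 0)
  tsi$lake_total <- 0L
  expect_error(lake_scene_mean(tsi), "positive")
})

test_that("annual records average per-scene means with equal weight", {
  d <- as.Date(c("2005-04-01", "2005-09-10", "2006-06-01"))
  r <- annualize(d, c(48, 52, 61.2), c(100, 140, 90), 2005, "L1")
  expect_equal(r$tsi_mean, 50)
  expect_equal(r$pixel_count, 120L)
  expect_equal(r$n_scenes, 2L)
  r6 <- annualize(d, c(48, 52, 61.2), c(100, 140, 90), 2006, "L1")
  expect_equal(r6$tsi_mean, 61.2)
  empty <- annualize(d, c(48, 52, 61.2), c(100, 140, 90), 2007, "L1")
  expect_true(is.na(empty$tsi_mean))
  expect_equal(empty$n_scenes, 0L)
})

test_that("long-term average and trophic level", {
  expect_equal(forty_year_average(rep(55, 10))$average_tsi, 55)
  expect_equal(as.character(forty_year_average(rep(55, 10))$level), "light eutrophic")
  avg <- forty_year_average(c(40, 60))
  expect_equal(avg$average_tsi, 50)
  expect_equal(as.character(avg$level), "light eutrophic")  # boundary -> upper bin
  expect_equal(as.character(forty_year_average(rep(25, 40))$level), "oligotrophic")
  # order invariance, NA dropped
  x <- c(30, NA, 50, 40)
  expect_equal(forty_year_average(x)$average_tsi,
               forty_year_average(rev(x))$average_tsi)
  expect_error(forty_year_average(c(NA, NA)), "non-missing")
})

test_that("Mann-Kendall statistics match the closed-form cases", {
  mk <- mann_kendall(1:10)
  expect_equal(mk$s, 45)
  expect_equal(mk$var_s, 10 * 9 * 25 / 18)
  expect_equal(mk$z, 44 / sqrt(125), tolerance = 1e-12)
  expect_equal(mk$p_value, 2 * pnorm(-44 / sqrt(125)), tolerance = 1e-12)
  expect_equal(mk$p_value, 8.5e-5, tolerance = 1e-2)
  expect_equal(mk$trend, "increase")

  const <- suppressWarnings(mann_kendall(rep(5, 8)))
  expect_equal(const$s, 0)
  expect_equal(const$trend, "no trend")

  # antisymmetry under reversal
  set.seed(3)
  x <- cumsum(rnorm(12))
  a <- mann_kendall(x); b <- mann_kendall(rev(x))
  expect_equal(b$s, -a$s)
  expect_equal(b$sen_slope, -a$sen_slope)

  # exact linear series: Sen slope exact, for any n >= 4
  for (n in c(4, 9, 40)) {
    t <- seq_len(n)
    mk2 <- mann_kendall(2 * t + 7, t)
    expect_equal(mk2$sen_slope, 2)
    expect_equal(mk2$s, choose(n, 2))
  }
  expect_error(mann_kendall(c(3)), "at least 2")
  expect_warning(mann_kendall(c(1, 2, 3)), "fewer than 4")
})

test_that("Mann-Kendall equals the brute-force oracle on random series", {
  set.seed(77)
  for (i in 1:150) {
    n <- sample(5:30, 1)
    x <- round(rnorm(n, 50, 5), sample(c(0, 1, 3), 1))   # ties at low precision
    yrs <- sort(sample(1984:2023, n))
    if (runif(1) < 0.3) x[sample(n, 2)] <- NA            # gaps
    if (sum(!is.na(x)) < 4) next
    o <- oracle_mk(x, yrs)
    mk <- suppressWarnings(mann_kendall(x, yrs))
    expect_identical(mk$s, o$s)
    expect_equal(mk$sen_slope, o$sen, tolerance = 1e-12)
  }
})

test_that("trend statistics are invariant to constant shifts", {
  set.seed(12)
  x <- 50 + 0.2 * (1:25) + rnorm(25, 0, 2)
  a <- mann_kendall(x); b <- mann_kendall(x + 13.7)
  expect_equal(b$s, a$s)
  expect_equal(b$z, a$z)
  expect_equal(b$p_value, a$p_value)
  expect_equal(b$sen_slope, a$sen_slope)
})

test_that("tie correction reduces the variance", {
  x <- c(1, 2, 2, 2, 3, 4, 4, 5)
  mk <- mann_kendall(x)
  n <- 8
  v0 <- n * (n - 1) * (2 * n + 5) / 18
  expect_lt(mk$var_s, v0)
  expect_equal(mk$var_s, v0 - (3 * 2 * 11 + 2 * 1 * 9) / 18)
})

test_that("aggregation table builder covers lakes x years", {
  df <- data.frame(
    lake_id = rep(c("A", "B"), each = 4),
    date = rep(c("2001-05-01", "2001-08-01", "2002-06-01", "2003-06-01"), 2),
    tsi_mean = c(40, 44, 50, NA, 60, 62, 61, 65),
    valid_count = c(10, 12, 9, 0, 30, 32, 31, 29))
  ann <- aggregate_annual(df, 2001:2003)
  expect_equal(nrow(ann), 6)
  expect_equal(ann$tsi_mean[ann$lake_id == "A" & ann$year == 2001], 42)
  expect_true(is.na(ann$tsi_mean[ann$lake_id == "A" & ann$year == 2003]))
  expect_equal(ann$tsi_mean[ann$lake_id == "B" & ann$year == 2003], 65)
})
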