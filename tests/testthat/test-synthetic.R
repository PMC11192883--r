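test_that("band solver hits the ABI target exactly and respects type constraints", {
  sens <- sensor_spec("OLI")
  th <- pipeline_thresholds()
  set.seed(1)
  targets <- list(`1` = runif(40, -0.028, 0.085),
                  `2` = runif(40, -0.05, 0.10),
                  `3` = runif(40, -0.15, -0.034))
  for (wt in 1:3) {
    a <- targets[[as.character(wt)]]
    sp <- solve_bands_for_abi(a, wt, sens, seed = wt * 11)
    expect_true(all(abs(abi(sp$B, sp$R, sp$NIR, sens) - a) < 1e-9))
    expect_true(all(sp >= 0 & sp <= 0.6))
    for (i in seq_along(a)) {
      got <- oracle_classify_pixel(sp$B[i], sp$G[i], sp$R[i], sp$NIR[i],
                                   sp$SWIR[i], sens, th)
      expect_equal(got, paste0("type", wt))
    }
  }
  # flat-feasible zero target
  s0 <- solve_bands_for_abi(0, 1, sens)
  expect_equal(abi(s0$B, s0$R, s0$NIR, sens), 0, tolerance = 1e-12)
  # unreachable target names the failure
  expect_error(solve_bands_for_abi(10, 3, sens), "infeasible")
  expect_error(solve_bands_for_abi(-0.5, 2, sens), "infeasible")
})

test_that("simulated scenes are reproducible and honour the seed contract", {
  rec <- scene_recipe(nrow = 64, ncol = 64, seed = 42, noise_sd = 0.005,
                      lakes = list(lake_spec("A", c(32, 32), c(20, 16))))
  s1 <- simulate_scene(rec)
  s2 <- simulate_scene(rec)
  expect_identical(s1$scene$bands, s2$scene$bands)
  expect_identical(s1$truth, s2$truth)
  # same recipe, different seed: same truth geometry, different reflectance
  rec3 <- scene_recipe(nrow = 64, ncol = 64, seed = 43, noise_sd = 0.005,
                       lakes = list(lake_spec("A", c(32, 32), c(20, 16))))
  s3 <- simulate_scene(rec3)
  expect_false(identical(s1$scene$bands$G, s3$scene$bands$G))
  # RNG state of the session is untouched
  set.seed(9); before <- .Random.seed
  invisible(simulate_scene(rec))
  expect_identical(before, .Random.seed)
})

test_that("recipe class fractions are realized to within rounding", {
  fr <- list(type1 = 0.45, type2 = 0.25, type3 = 0.2, scum = 0.06, vegetation = 0.04)
  rec <- scene_recipe(nrow = 96, ncol = 96, seed = 2,
                      lakes = list(lake_spec("A", c(48, 48), c(30, 26), fractions = fr)))
  sim <- simulate_scene(rec)
  # classify the noise-free scene over the full lake ellipse (before the
  # boundary buffer): realized pixel counts must match the recipe within
  # the integer-allocation rounding of one pixel per class
  wmask <- lakeTSI:::ellipse_mask(96, 96, c(48, 48), c(30, 26))
  cm <- classify_pixels(sim$scene, wmask)
  lbl <- class_map_labels(cm)[wmask]
  counted <- table(factor(lbl, levels = class_labels()))
  n_lake <- sum(wmask)
  for (cls in names(fr))
    expect_lt(abs(counted[[cls]] - n_lake * fr[[cls]]), 1)
  # the allocation rule itself is exact
  n <- 977
  cnt <- lakeTSI:::allocate_counts(n, unlist(fr))
  expect_equal(sum(cnt), n)
  expect_true(all(abs(cnt - n * unlist(fr)) < 1))
})

test_that("invalid recipes are rejected with all failures listed", {
  expect_error(scene_recipe(noise_sd = -1), "noise_sd")
  expect_error(scene_recipe(cloud_fraction = 2), "cloud_fraction")
  expect_error(scene_recipe(lakes = list(lake_spec(fractions = list(
    type1 = 0.9, type2 = 0.9, type3 = 0, scum = 0, vegetation = 0)))),
    "sum <= 1")
})

test_that("fully clouded scenes yield no retrievable pixels", {
  rec <- scene_recipe(nrow = 48, ncol = 48, seed = 4, cloud_fraction = 1,
                      lakes = list(lake_spec("A", c(24, 24), c(15, 12))))
  sim <- simulate_scene(rec)
  expect_true(all(sim$scene$qa %in% c("medium", "high")))
  res <- suppressWarnings(process_scene(sim$scene, sim$outlines[[1]]))
  expect_equal(res$tsi$valid_count, 0)
})

test_that("matchup generator reproduces the model exactly at zero noise", {
  for (wt in 1:3) {
    m <- simulate_matchups(50, wt, tsi_noise_sd = 0, seed = 21)
    expect_true(all(m$tsi_measured >= 20 & m$tsi_measured <= 90))
    fit <- suppressWarnings(fit_type_model(m, wt))
    cf <- default_tsi_coefficients()
    expect_equal(fit$slope, cf$slope[wt], tolerance = 1e-6)
    expect_equal(fit$intercept, cf$intercept[wt], tolerance = 1e-6)
  }
  expect_error(simulate_matchups(0, 1), ">= 1")
  # reproducible under seed
  expect_identical(simulate_matchups(30, 1, tsi_noise_sd = 2, seed = 5),
                   simulate_matchups(30, 1, tsi_noise_sd = 2, seed = 5))
})

test_that("matchup noise calibrated for R2 ~ 0.66 lands in (0.56, 0.76)", {
  r2s <- sapply(1:100, function(s) {
    sig <- simulate_matchups(310, 1, tsi_noise_sd = 0, seed = 3000 + s)$tsi_measured
    m <- simulate_matchups(310, 1, tsi_noise_sd = noise_sd_for_r2(sig, 0.66),
                           seed = 3000 + s)
    fit_type_model(m, 1)$r2
  })
  expect_gt(mean(r2s > 0.56 & r2s < 0.76), 0.95)
  expect_equal(mean(r2s), 0.66, tolerance = 0.03)
})

test_that("annual series generator honours trend, gaps and determinism", {
  x <- simulate_annual_series(40, base = 50, slope = 0.3, noise_sd = 0, seed = 1)
  expect_equal(x, 50 + 0.3 * (0:39))
  expect_equal(suppressWarnings(mann_kendall(x))$sen_slope, 0.3)
  const <- simulate_annual_series(10, base = 55, slope = 0, noise_sd = 0, seed = 2)
  expect_equal(mann_kendall(const)$trend, "no trend")
  gappy <- simulate_annual_series(20, missing_fraction = 0.25, seed = 3)
  expect_equal(sum(is.na(gappy)), 5)
  all_missing <- simulate_annual_series(10, missing_fraction = 1, seed = 4)
  expect_true(all(is.na(all_missing)))
  expect_error(mann_kendall(all_missing), "at least 2")
  expect_error(simulate_annual_series(3), "n_years")
  expect_identical(simulate_annual_series(15, noise_sd = 2, seed = 9),
                   simulate_annual_series(15, noise_sd = 2, seed = 9))
})

test_that("forward-inverse consistency holds pixelwise at zero noise", {
  rec <- scene_recipe(nrow = 80, ncol = 80, seed = 17,
    lakes = list(lake_spec("A", c(40, 40), c(26, 22),
      fractions = list(type1 = 0.4, type2 = 0.3, type3 = 0.3,
                       scum = 0, vegetation = 0))))
  sim <- simulate_scene(rec)
  res <- process_scene(sim$scene, sim$outlines[[1]])
  tc <- unclass(sim$truth$classes); pc <- unclass(res$classes)
  expect_identical(pc, tc)
  expect_lt(max(abs(res$tsi$values - sim$truth$tsi), na.rm = TRUE), 1e-6)
  expect_identical(is.na(res$tsi$values), is.na(sim$truth$tsi))
})
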