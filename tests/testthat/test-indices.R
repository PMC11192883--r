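test_that("TSI from chlorophyll-a follows the Carlson form", {
  expect_equal(tsi_from_chla(1), 25)
  expect_equal(tsi_from_chla(10), 10 * (2.5 + 1.086 * log(10)), tolerance = 1e-12)
  expect_equal(tsi_from_chla(10), 50.006, tolerance = 1e-4)
  expect_equal(tsi_from_chla(100), 75.012, tolerance = 1e-4)
  expect_error(tsi_from_chla(0), "positive")
  expect_error(tsi_from_chla(-3), "positive")
  expect_error(tsi_from_chla(NaN))
  # strictly increasing
  c <- sort(exp(runif(50, -3, 5)))
  expect_true(all(diff(tsi_from_chla(c)) > 0))
})

test_that("trophic levels partition the 0-100 scale", {
  expect_equal(as.character(trophic_level(25)), "oligotrophic")
  expect_equal(as.character(trophic_level(55)), "light eutrophic")
  # shared boundaries belong to the upper level
  expect_equal(as.character(trophic_level(30)), "mesotrophic")
  expect_equal(as.character(trophic_level(50)), "light eutrophic")
  expect_equal(as.character(trophic_level(70)), "hyper eutrophic")
  expect_equal(as.character(trophic_level(0)), "oligotrophic")
  expect_equal(as.character(trophic_level(100)), "hyper eutrophic")
  expect_error(trophic_level(101), "0, 100")
  expect_error(trophic_level(-1), "0, 100")
  # every value maps to exactly one non-missing level
  tsi <- seq(0, 100, by = 0.25)
  lv <- trophic_level(tsi)
  expect_false(any(is.na(lv)))
  # monotone non-decreasing along increasing chlorophyll
  chla <- exp(seq(log(0.1), log(400), length.out = 200))
  lv2 <- trophic_level(pmin(pmax(tsi_from_chla(chla), 0), 100))
  expect_true(all(diff(as.integer(lv2)) >= 0))
})

test_that("sensor registry carries the operational band centres", {
  oli <- sensor_spec("OLI")
  expect_equal(unname(oli$wavelengths[c("G", "R", "NIR", "SWIR")]),
               c(563, 665, 865, 1609))
  tm <- sensor_spec("TM")
  expect_equal(unname(tm$wavelengths[c("G", "R", "NIR", "SWIR")]),
               c(560, 660, 835, 1650))
  expect_equal(sensor_spec("ETM+")$wavelengths, tm$wavelengths)
  expect_true(all(diff(oli$wavelengths) > 0))
  custom <- sensor_spec("OLI", lambda_B = 480)
  expect_equal(unname(custom$wavelengths["B"]), 480)
  expect_error(sensor_spec("OLI", lambda_B = 600), "increasing")
})

test_that("NDWI, FAI, TWI, ABI evaluate the printed formulas", {
  expect_equal(ndwi(0.10, 0.04), 0.06)
  expect_equal(ndwi(0.02, 0.09), -0.07)
  expect_equal(ndwi(0.2, 0.1, form = "normalized"), 0.1 / 0.3)
  expect_equal(twi(0.10, 0.02), 0.08)
  expect_equal(twi(0.03, 0.08), -0.05)
  # FAI derived values (baseline ratio 200/944 for OLI, 175/990 for TM)
  expect_equal(fai(0.10, 0.20, 0.05, "OLI"),
               0.20 - 0.10 - (0.05 - 0.10) * 200 / 944, tolerance = 1e-12)
  expect_equal(fai(0.10, 0.20, 0.05, "OLI"), 0.110593, tolerance = 1e-5)
  expect_equal(fai(0.10, 0.20, 0.05, "TM"), 0.108838, tolerance = 1e-5)
  # ABI derived values (c1 = 81/183, c2 = 81/383 at lambda_B = 482)
  expect_equal(abi(0.05, 0.10, 0.05, "OLI"),
               0.05 * 81 / 183, tolerance = 1e-12)
  expect_equal(abi(0.05, 0.10, 0.05, "OLI"), 0.0221311, tolerance = 1e-5)
  expect_equal(abi(0.05, 0.05, 0.15, "OLI"), -0.0211488, tolerance = 1e-5)
})

test_that("flat spectra give zero for every index and sensor", {
  set.seed(42)
  for (sid in c("OLI", "TM", "ETM+")) {
    for (lvl in runif(5, 0.01, 0.5)) {
      expect_equal(ndwi(lvl, lvl), 0)
      expect_equal(twi(lvl, lvl), 0)
      expect_equal(fai(lvl, lvl, lvl, sid), 0, tolerance = 1e-15)
      expect_equal(abi(lvl, lvl, lvl, sid), 0, tolerance = 1e-15)
    }
  }
})

test_that("ABI and FAI are affine in the spectrum", {
  set.seed(7)
  s <- sensor_spec("OLI")
  for (i in 1:20) {
    s1 <- runif(5, 0, 0.5); s2 <- runif(5, 0, 0.5); a <- runif(1)
    mix <- a * s1 + (1 - a) * s2
    expect_equal(abi(mix[1], mix[3], mix[4], s),
                 a * abi(s1[1], s1[3], s1[4], s) + (1 - a) * abi(s2[1], s2[3], s2[4], s),
                 tolerance = 1e-12)
    expect_equal(fai(mix[3], mix[4], mix[5], s),
                 a * fai(s1[3], s1[4], s1[5], s) + (1 - a) * fai(s2[3], s2[4], s2[5], s),
                 tolerance = 1e-12)
  }
})

test_that("per-type TSI inversion applies the model line and clamps", {
  expect_equal(as.numeric(tsi_from_abi(0, 1)), 72.47)
  expect_equal(as.numeric(tsi_from_abi(0, 2)), 55.39)
  expect_equal(as.numeric(tsi_from_abi(0, 3)), 16.04)
  expect_equal(as.numeric(tsi_from_abi(0.05, 1)), -601.94 * 0.05 + 72.47)
  expect_equal(as.numeric(tsi_from_abi(0.05, 1)), 42.373, tolerance = 1e-10)
  # clamping
  clamped <- tsi_from_abi(-0.2, 1)
  expect_equal(as.numeric(clamped), 100)
  expect_equal(attr(clamped, "n_clamped"), 1L)
  expect_equal(as.numeric(tsi_from_abi(-0.2, 1, clamp = FALSE)),
               -601.94 * -0.2 + 72.47)
  expect_error(tsi_from_abi(0, 4), "unknown water type")
  # monotone decreasing in ABI for every type
  a <- seq(-0.05, 0.05, length.out = 30)
  for (t in 1:3)
    expect_true(all(diff(tsi_from_abi(a, t, clamp = FALSE)) < 0))
})
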