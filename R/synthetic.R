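# Run code under a seeded RNG without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' ABI value implied by a TSI under a type model
#'
#' Inverts TSI = slope x ABI + intercept: abi = (tsi - intercept) / slope.
#'
#' @param tsi TSI values.
#' @param water_type Water type(s) in 1:3.
#' @param coeffs Coefficient table.
#' @return Numeric ABI.
#' @export
abi_from_tsi <- function(tsi, water_type, coeffs = default_tsi_coefficients()) {
  if (length(water_type) == 1) water_type <- rep_len(water_type, length(tsi))
  row <- coef_row(coeffs, water_type)
  (tsi - row$intercept) / row$slope
}

# Candidate anchors (B, G, fai0, twi0) per water type for the band solver.
# fai0 is the target FAI (<= -0.004 keeps the pixel out of the scum and
# vegetation branches), twi0 the target TWI (< 0.076 for type 1, >= for
# type 2, free for type 3). G/B are chosen to satisfy the clear-water test
# for the requested type.
solver_anchors <- function(water_type) {
  g <- function(B, G, f0, t0) c(B = B, G = G, f0 = f0, t0 = t0)
  switch(as.character(water_type),
    "1" = list(g(0.10, 0.15, -0.02, 0.040), g(0.15, 0.15, -0.004, 0.000),
               g(0.05, 0.12, -0.02, 0.060), g(0.25, 0.30, -0.004, 0.000),
               g(0.40, 0.45, -0.004, 0.000), g(0.59, 0.60, -0.004, 0.000)),
    "2" = list(g(0.10, 0.15, -0.02, 0.090), g(0.15, 0.15, -0.004, 0.076),
               g(0.30, 0.30, -0.004, 0.076), g(0.45, 0.45, -0.004, 0.076),
               g(0.59, 0.60, -0.004, 0.076), g(0.10, 0.15, -0.05, 0.150)),
    "3" = list(g(0.06, 0.08, -0.01, 0.000), g(0.03, 0.05, -0.004, 0.020),
               g(0.30, 0.10, -0.01, 0.000), g(0.45, 0.10, -0.01, -0.100),
               g(0.60, 0.11, -0.004, -0.250), g(0.60, 0.11, -0.004, -0.450)),
    stop("water_type must be 1, 2 or 3"))
}

# Classification constraints for a candidate spectrum of a given type.
type_constraints_ok <- function(water_type, B, G, R, NIR, SWIR, sensor,
                                thresholds = pipeline_thresholds(), rmax = 0.6) {
  f <- fai(R, NIR, SWIR, sensor)
  tw <- twi(R, SWIR)
  bands_ok <- B >= 0 & G >= 0 & R >= 0 & NIR >= 0 & SWIR >= 0 &
    B <= rmax & G <= rmax & R <= rmax & NIR <= rmax & SWIR <= rmax
  not_scum_veg <- f <= thresholds$fai_vegetation
  clear <- G < thresholds$clear_g | B > G
  ok <- ifelse(water_type == 1, !clear & tw < thresholds$twi_turbid,
        ifelse(water_type == 2, !clear & tw >= thresholds$twi_turbid, clear))
  bands_ok & not_scum_veg & ok
}

# Solve R, SWIR, NIR for target (abi, fai0, twi0) given B and the sensor.
solve_rns <- function(a, B, f0, t0, sensor) {
  wl <- sensor$wavelengths
  c1 <- (wl[["G"]] - wl[["B"]]) / (wl[["R"]] - wl[["B"]])
  c2 <- (wl[["G"]] - wl[["B"]]) / (wl[["NIR"]] - wl[["B"]])
  k  <- (wl[["NIR"]] - wl[["R"]]) / (wl[["SWIR"]] - wl[["R"]])
  R <- B + (a + (f0 - t0 * k) * c2) / (c1 - c2)
  list(R = R, SWIR = R - t0, NIR = f0 + R - t0 * k)
}

#' Solve a band spectrum realizing a target ABI for a water type
#'
#' Constructs surface-reflectance spectra that (a) evaluate to the requested
#' ABI exactly (closed form, to machine precision) and (b) satisfy the
#' decision-tree constraints of the requested water type, so that the full
#' pipeline classifies them back to that type. Blue and green anchors (and
#' the FAI/TWI operating points) are selected from a feasibility ladder; when
#' a seed is given, the free bands are jittered and re-solved, falling back
#' to the unjittered solution where the jitter would break feasibility.
#' Spectra are constrained to \[0, 0.6\] reflectance.
#'
#' @param target_abi Numeric vector of ABI targets.
#' @param water_type Water type, 1, 2 or 3 (scalar or vector).
#' @param sensor A [sensor_spec()] or sensor id.
#' @param seed Optional seed for the band jitter; NULL = no jitter.
#' @param jitter_sd Jitter standard deviation on the free bands (default
#'   0.005 reflectance).
#' @return Data frame with columns B, G, R, NIR, SWIR (one row per target).
#' @examples
#' s <- solve_bands_for_abi(0.02, 1)
#' abi(s$B, s$R, s$NIR, "OLI")  # 0.02
#' @export
solve_bands_for_abi <- function(target_abi, water_type, sensor = "OLI",
                                seed = NULL, jitter_sd = 0.005) {
  sensor <- as_sensor(sensor)
  n <- length(target_abi)
  if (any(!is.finite(target_abi))) stop("`target_abi` must be finite")
  if (length(water_type) == 1) water_type <- rep_len(water_type, n)
  stopifnot(length(water_type) == n, all(water_type %in% 1:3))

  out <- data.frame(B = rep(NA_real_, n), G = NA_real_, R = NA_real_,
                    NIR = NA_real_, SWIR = NA_real_, f0 = NA_real_, t0 = NA_real_)
  for (wt in unique(water_type)) {
    idx <- which(water_type == wt)
    unresolved <- idx
    for (anc in solver_anchors(wt)) {
      if (!length(unresolved)) break
      a <- target_abi[unresolved]
      sol <- solve_rns(a, anc[["B"]], anc[["f0"]], anc[["t0"]], sensor)
      ok <- type_constraints_ok(wt, anc[["B"]], anc[["G"]], sol$R, sol$NIR,
                                sol$SWIR, sensor)
      hit <- unresolved[ok]
      out$B[hit] <- anc[["B"]]; out$G[hit] <- anc[["G"]]
      out$R[hit] <- sol$R[ok]; out$NIR[hit] <- sol$NIR[ok]
      out$SWIR[hit] <- sol$SWIR[ok]
      out$f0[hit] <- anc[["f0"]]; out$t0[hit] <- anc[["t0"]]
      unresolved <- unresolved[!ok]
    }
    if (length(unresolved))
      stop(sprintf(paste0("infeasible ABI target(s) for water type %d ",
                          "(e.g. %.4g): no spectrum within the [0, 0.6] ",
                          "reflectance bounds satisfies the type's ",
                          "classification constraints"),
                   wt, target_abi[unresolved[1]]))
  }

  if (!is.null(seed)) {
    out <- with_seed(seed, {
      jB <- out$B + stats::rnorm(n, 0, jitter_sd)
      jG <- out$G + stats::rnorm(n, 0, jitter_sd)
      jB <- pmin(pmax(jB, 0), 0.6)
      jG <- pmin(pmax(jG, 0), 0.6)
      sol <- solve_rns(target_abi, jB, out$f0, out$t0, sensor)
      ok <- type_constraints_ok(water_type, jB, jG, sol$R, sol$NIR, sol$SWIR, sensor)
      out$B[ok] <- jB[ok]; out$G[ok] <- jG[ok]
      out$R[ok] <- sol$R[ok]; out$NIR[ok] <- sol$NIR[ok]
      out$SWIR[ok] <- sol$SWIR[ok]
      out
    })
  }
  out$f0 <- NULL; out$t0 <- NULL
  out
}

#' Scene recipe for the synthetic generator
#'
#' Describes a synthetic acquisition: grid shape, sensor, band noise, cloud
#' fraction and a list of elliptical lakes, each with per-class pixel
#' fractions and a per-type true-TSI range (TSI varies as a smooth
#' left-to-right gradient between the range endpoints; equal endpoints give
#' a constant field). Defaults emulate the three optical water types at
#' limnologically plausible trophic states: algae-dominated pixels
#' (moderate/hyper eutrophic), turbid pixels (meso/light eutrophic) and clear
#' pixels (oligo/mesotrophic; the spectral constraint set caps clear-water
#' TSI near 35).
#'
#' @param nrow,ncol Grid shape in pixels.
#' @param sensor Sensor id or [sensor_spec()].
#' @param noise_sd Gaussian noise sd added to every band, reflectance units.
#' @param cloud_fraction Fraction of scene pixels covered by cloud blobs.
#' @param lakes List of lake specs; see [lake_spec()].
#' @param seed Seed making the scene bit-reproducible.
#' @param date Acquisition date.
#' @return Object of class `scene_recipe`.
#' @export
scene_recipe <- function(nrow = 128, ncol = 128, sensor = "OLI",
                         noise_sd = 0, cloud_fraction = 0,
                         lakes = list(lake_spec()), seed = 1,
                         date = as.Date("2010-07-01")) {
  problems <- character()
  if (noise_sd < 0) problems <- c(problems, "noise_sd must be >= 0")
  if (cloud_fraction < 0 || cloud_fraction > 1)
    problems <- c(problems, "cloud_fraction must be in [0, 1]")
  for (lk in lakes) {
    fr <- unlist(lk$fractions)
    if (any(fr < 0) || any(fr > 1) || sum(fr) > 1 + 1e-9)
      problems <- c(problems, paste0("lake ", lk$lake_id,
                                     ": fractions must be in [0,1] and sum <= 1"))
  }
  if (length(problems)) stop("invalid recipe: ", paste(problems, collapse = "; "))
  structure(list(nrow = nrow, ncol = ncol, sensor = as_sensor(sensor),
                 noise_sd = noise_sd, cloud_fraction = cloud_fraction,
                 lakes = lakes, seed = seed, date = as.Date(date)),
            class = "scene_recipe")
}

#' @rdname scene_recipe
#' @param lake_id Lake identifier.
#' @param centre,radii Ellipse centre and radii in pixel units (x, y).
#' @param fractions Named list of per-class pixel fractions over
#'   `type1`, `type2`, `type3`, `scum`, `vegetation` (sum <= 1; any
#'   remainder is allocated to the largest class by the rounding rule).
#' @param tsi_by_type Named list `"1"`, `"2"`, `"3"` of length-2 TSI ranges.
#' @export
lake_spec <- function(lake_id = "L1", centre = c(64, 64), radii = c(40, 30),
                      fractions = list(type1 = 0.5, type2 = 0.3, type3 = 0.2,
                                       scum = 0, vegetation = 0),
                      tsi_by_type = list(`1` = c(58, 72), `2` = c(45, 60),
                                         `3` = c(22, 33))) {
  list(lake_id = as.character(lake_id), centre = centre, radii = radii,
       fractions = fractions, tsi_by_type = tsi_by_type)
}

# Largest-remainder integer allocation of n pixels to class fractions.
allocate_counts <- function(n, fractions) {
  raw <- n * fractions
  cnt <- floor(raw)
  left <- n - sum(cnt)
  if (left > 0) {
    pick <- order(raw - cnt, decreasing = TRUE)[seq_len(left)]
    cnt[pick] <- cnt[pick] + 1
  }
  cnt
}

# Seeded random-walk cloud blobs covering ~fraction of the grid.
cloud_blobs <- function(nrow, ncol, fraction) {
  mask <- matrix(FALSE, nrow, ncol)
  target <- round(fraction * nrow * ncol)
  if (target <= 0) return(mask)
  while (sum(mask) < target) {
    r <- sample.int(nrow, 1); c <- sample.int(ncol, 1)
    steps <- min(target - sum(mask), 400)
    for (s in seq_len(steps)) {
      mask[max(1, min(nrow, r)), max(1, min(ncol, c))] <- TRUE
      mv <- sample.int(4, 1)
      r <- r + c(1, -1, 0, 0)[mv]; c <- c + c(0, 0, 1, -1)[mv]
      r <- max(1, min(nrow, r)); c <- max(1, min(ncol, c))
    }
  }
  mask
}

# Pixel-centre coordinates for the synthetic scene geotransform
# c(0, 1, 0, 0, 0, 1): x = col - 0.5, y = row - 0.5.
syn_geotransform <- function() c(0, 1, 0, 0, 0, 1)

ellipse_mask <- function(nrow, ncol, centre, radii) {
  x <- matrix(rep(seq_len(ncol), each = nrow), nrow) - 0.5
  y <- matrix(rep(seq_len(nrow), times = ncol), nrow) - 0.5
  ((x - centre[1]) / radii[1])^2 + ((y - centre[2]) / radii[2])^2 <= 1
}

ellipse_polygon <- function(centre, radii, n = 180) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(centre[1] + radii[1] * cos(th), centre[2] + radii[2] * sin(th))
}

#' Simulate a scene with known ground truth
#'
#' Forward model for the retrieval pipeline: a land background (NDWI well
#' below zero), elliptical lakes whose water pixels are built by
#' [solve_bands_for_abi()] from a known TSI field through the inverse of the
#' per-type models, floating-scum and vegetation pixels with diagnostic FAI
#' signatures, cloud blobs carried in the QA layer, and optional Gaussian
#' band noise added after construction. The returned truth accounts for the
#' pipeline's own 3-pixel boundary erosion and cloud exclusion, so that on a
#' noise-free scene the pipeline reproduces the truth exactly.
#'
#' @param recipe A [scene_recipe()].
#' @param coeffs Coefficient table used for the TSI-to-ABI forward step.
#' @return List with `scene` (a [scene()]), `truth` (list: `classes` a
#'   `class_map`, `tsi` and `abi` matrices with NA outside retrievable
#'   water), and `outlines` (list of [lake_outline()]).
#' @export
simulate_scene <- function(recipe, coeffs = default_tsi_coefficients()) {
  stopifnot(inherits(recipe, "scene_recipe"))
  nr <- recipe$nrow; nc <- recipe$ncol
  with_seed(recipe$seed, {
    land <- c(B = 0.06, G = 0.08, R = 0.12, NIR = 0.45, SWIR = 0.30)
    bands <- lapply(land, function(v) matrix(v, nr, nc))
    names(bands) <- names(land)
    truth_codes <- matrix(1L, nr, nc)
    truth_tsi <- matrix(NA_real_, nr, nc)
    truth_abi <- matrix(NA_real_, nr, nc)

    cloud <- cloud_blobs(nr, nc, recipe$cloud_fraction)
    qa <- matrix("clear", nr, nc)
    qa[matrix(stats::runif(nr * nc) < 0.05, nr, nc) & !cloud] <- "low"
    qa[cloud] <- sample(c("high", "medium"), sum(cloud), replace = TRUE,
                        prob = c(0.8, 0.2))

    outlines <- list()
    ctr <- pixel_centres(syn_geotransform(), nr, nc)
    margin <- 4  # outline ring of land pixels kept inside the vector outline
    class_order <- c("type1", "type2", "type3", "scum", "vegetation")
    for (lk in recipe$lakes) {
      lmask <- ellipse_mask(nr, nc, lk$centre, lk$radii)
      pix <- which(lmask)
      fr <- unlist(lk$fractions[class_order])
      fr[is.na(fr)] <- 0
      if (sum(fr) < 1) {  # remainder joins the largest class
        fr[which.max(fr)] <- fr[which.max(fr)] + (1 - sum(fr))
      }
      cnt <- allocate_counts(length(pix), fr)
      # contiguous left-to-right blocks per class: order pixels by column
      ord <- pix[order(col(lmask)[pix], row(lmask)[pix])]
      assign_cls <- rep(class_order, times = cnt)
      cls <- stats::setNames(assign_cls, NULL)

      for (ci in seq_along(class_order)) {
        cname <- class_order[ci]
        sel <- ord[cls == cname]
        if (!length(sel)) next
        if (cname %in% c("type1", "type2", "type3")) {
          wt <- as.integer(substring(cname, 5))
          rng <- lk$tsi_by_type[[as.character(wt)]]
          xpos <- (col(lmask)[sel] - 0.5) / nc
          tsi <- rng[1] + (rng[2] - rng[1]) * xpos
          a <- abi_from_tsi(tsi, wt, coeffs)
          sp <- solve_bands_for_abi(a, wt, recipe$sensor,
                                    seed = recipe$seed + wt, jitter_sd = 0.004)
          for (b in names(bands)) bands[[b]][sel] <- sp[[b]]
          truth_codes[sel] <- 4L + wt
          truth_tsi[sel] <- tsi
          truth_abi[sel] <- a
        } else if (cname == "scum") {
          jit <- stats::rnorm(length(sel), 0, 0.01)
          bands$B[sel] <- 0.10; bands$G[sel] <- 0.30 + jit
          bands$R[sel] <- 0.05; bands$NIR[sel] <- 0.25 + abs(jit)
          bands$SWIR[sel] <- 0.05
          truth_codes[sel] <- 3L
        } else {  # vegetation
          jit <- stats::rnorm(length(sel), 0, 0.005)
          bands$B[sel] <- 0.10; bands$G[sel] <- 0.16 + jit
          bands$R[sel] <- 0.10; bands$NIR[sel] <- 0.11
          bands$SWIR[sel] <- 0.10
          truth_codes[sel] <- 4L
        }
      }
      poly <- ellipse_polygon(lk$centre, lk$radii + margin)
      outlines[[lk$lake_id]] <- lake_outline(
        lk$lake_id, poly,
        area_km2 = max(1, length(pix) * 0.0009),  # 30 m pixels
        name = lk$lake_id)

      # pipeline-visible truth: cloud overrides, the in-outline land collar
      # and the 3-pixel boundary buffer are not retrievable
      omask <- matrix(point_in_polygon(ctr$x, ctr$y, poly), nr)
      survives <- erode3(lmask & !cloud)
      ring <- (omask & !lmask & !cloud) | (lmask & !cloud & !survives)
      truth_codes[ring] <- 8L
      truth_tsi[ring] <- NA_real_; truth_abi[ring] <- NA_real_
    }
    truth_codes[cloud] <- 2L
    truth_tsi[cloud] <- NA_real_; truth_abi[cloud] <- NA_real_

    if (recipe$noise_sd > 0)
      for (b in names(bands))
        bands[[b]] <- bands[[b]] + matrix(stats::rnorm(nr * nc, 0, recipe$noise_sd), nr, nc)

    sc <- scene(bands, qa, sensor = recipe$sensor,
                geotransform = syn_geotransform(), date = recipe$date)
    list(scene = sc,
         truth = list(classes = new_class_map(truth_codes),
                      tsi = truth_tsi, abi = truth_abi),
         outlines = outlines)
  })
}

#' Noise level giving a target coefficient of determination
#'
#' For a response with signal standard deviation `sd(signal)`, additive
#' Gaussian noise with sd `sd(signal) * sqrt(1/r2 - 1)` yields an expected
#' OLS R2 of `r2`.
#'
#' @param signal Numeric vector of noise-free response values.
#' @param r2 Target R2 in (0, 1).
#' @return Noise standard deviation.
#' @export
noise_sd_for_r2 <- function(signal, r2) {
  stopifnot(r2 > 0, r2 < 1)
  stats::sd(signal) * sqrt(1 / r2 - 1)
}

#' Simulate in-situ/satellite matchups
#'
#' Generates matchup records for one water type: chlorophyll-a is drawn
#' lognormal, the trophic signal is TSI(Chla) clipped to the observed
#' \[20, 90\] range, ABI follows exactly from the type model
#' (abi = (tsi - intercept)/slope), and measured TSI is the signal plus
#' Gaussian observation noise (standard OLS error model, so refitting the
#' model to the matchups recovers the generating coefficients without
#' attenuation).
#'
#' @param n Number of matchups (>= 1).
#' @param water_type Water type 1, 2 or 3.
#' @param coeffs Coefficient table.
#' @param chla_meanlog,chla_sdlog Lognormal parameters of Chla on the log
#'   scale (defaults 2 and 1 spread TSI across all five trophic levels).
#' @param tsi_noise_sd Gaussian sd of the TSI measurement noise.
#' @param seed Seed for reproducibility.
#' @return Data frame with columns `lake_id`, `date`, `water_type`, `abi`,
#'   `chla`, `tsi_measured`.
#' @export
simulate_matchups <- function(n, water_type, coeffs = default_tsi_coefficients(),
                              chla_meanlog = 2, chla_sdlog = 1,
                              tsi_noise_sd = 0, seed = NULL) {
  if (n < 1) stop("`n` must be >= 1")
  stopifnot(water_type %in% 1:3, tsi_noise_sd >= 0)
  with_seed(seed, {
    chla <- stats::rlnorm(n, chla_meanlog, chla_sdlog)
    signal <- pmin(pmax(tsi_from_chla(chla), 20), 90)
    a <- abi_from_tsi(signal, water_type, coeffs)
    measured <- signal + stats::rnorm(n, 0, tsi_noise_sd)
    measured <- pmin(pmax(measured, 0), 100)
    data.frame(
      lake_id = sprintf("SYN%03d", seq_len(n) %% 37 + 1),
      date = as.Date("2015-06-01") + (seq_len(n) * 11) %% 2200,
      water_type = water_type, abi = a, chla = chla, tsi_measured = measured)
  })
}

#' Simulate an annual TSI series with trend, noise and gaps
#'
#' x_t = base + slope * t + N(0, noise_sd^2), t = 0 .. n_years - 1, with a
#' seeded random subset of years set missing.
#'
#' @param n_years Series length (>= 4).
#' @param base Intercept TSI at the first year.
#' @param slope Linear trend, TSI per year.
#' @param noise_sd Gaussian noise sd, TSI units.
#' @param missing_fraction Fraction of years set to NA.
#' @param seed Seed.
#' @return Numeric vector of length `n_years` (with NAs for missing years).
#' @export
simulate_annual_series <- function(n_years, base = 50, slope = 0, noise_sd = 0,
                                   missing_fraction = 0, seed = NULL) {
  if (n_years < 4) stop("`n_years` must be >= 4")
  stopifnot(noise_sd >= 0, missing_fraction >= 0, missing_fraction <= 1)
  with_seed(seed, {
    t <- seq_len(n_years) - 1
    x <- base + slope * t + stats::rnorm(n_years, 0, noise_sd)
    n_miss <- round(missing_fraction * n_years)
    if (n_miss > 0) x[sample.int(n_years, n_miss)] <- NA_real_
    x
  })
}
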