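#' Sensor band specification
#'
#' Band-centre wavelengths for the three Landsat-class instruments the
#' retrieval supports. The green/red/NIR/SWIR centres are the operational
#' values used by the index formulas (OLI: 563/665/865/1609 nm; TM and ETM+:
#' 560/660/835/1650 nm). Blue-band centres are nominal (482 nm OLI, 485 nm
#' TM/ETM+) and can be overridden.
#'
#' @param sensor_id One of `"TM"`, `"ETM+"`, `"OLI"`.
#' @param lambda_B Optional blue band-centre override, nm.
#' @return An object of class `sensor_spec`: a list with `sensor_id` and a
#'   named numeric vector `wavelengths` over bands B, G, R, NIR, SWIR (nm),
#'   strictly increasing.
#' @examples
#' sensor_spec("OLI")$wavelengths
#' @export
sensor_spec <- function(sensor_id = c("OLI", "TM", "ETM+"), lambda_B = NULL) {
  sensor_id <- match.arg(sensor_id)
  wl <- switch(sensor_id,
    "OLI"  = c(B = 482, G = 563, R = 665, NIR = 865, SWIR = 1609),
    "TM"   = c(B = 485, G = 560, R = 660, NIR = 835, SWIR = 1650),
    "ETM+" = c(B = 485, G = 560, R = 660, NIR = 835, SWIR = 1650))
  if (!is.null(lambda_B)) {
    stopifnot(is.numeric(lambda_B), length(lambda_B) == 1, is.finite(lambda_B))
    wl["B"] <- lambda_B
  }
  if (any(wl <= 0) || any(diff(wl) <= 0))
    stop("sensor wavelengths must be positive and strictly increasing B < G < R < NIR < SWIR")
  structure(list(sensor_id = sensor_id, wavelengths = wl), class = "sensor_spec")
}

#' @export
print.sensor_spec <- function(x, ...) {
  cat("<sensor_spec>", x$sensor_id, "\n")
  print(x$wavelengths)
  invisible(x)
}

as_sensor <- function(sensor) {
  if (inherits(sensor, "sensor_spec")) return(sensor)
  if (is.character(sensor) && length(sensor) == 1) return(sensor_spec(sensor))
  stop("`sensor` must be a sensor_spec or a sensor id string")
}

check_finite <- function(..., .names = NULL) {
  args <- list(...)
  nm <- if (is.null(.names)) paste0("arg", seq_along(args)) else .names
  for (i in seq_along(args)) {
    if (any(!is.finite(args[[i]]) & !is.na(args[[i]])))
      stop("non-finite values in `", nm[i], "`")
  }
  invisible(TRUE)
}

#' Carlson trophic state index from chlorophyll-a
#'
#' TSI(Chla) = 10 (2.5 + 1.086 ln Chla), the chlorophyll-a form of Carlson's
#' 0-100 trophic state scale. The value is returned unclamped; values outside
#' \[0, 100\] are possible for extreme concentrations and are left to the
#' caller to handle.
#'
#' @param chla Chlorophyll-a concentration, ug/L; must be finite and > 0.
#' @return Numeric TSI, same length as `chla`.
#' @examples
#' tsi_from_chla(1)    # 25
#' tsi_from_chla(10)   # ~50.01
#' @export
tsi_from_chla <- function(chla) {
  if (!is.numeric(chla) || any(!is.finite(chla)) || any(chla <= 0))
    stop("`chla` must be finite and strictly positive (ug/L)")
  10 * (2.5 + 1.086 * log(chla))
}

#' Trophic level classification
#'
#' Bins a TSI value on the 0-100 scale into the five standard trophic levels:
#' oligotrophic \[0, 30), mesotrophic \[30, 50), light eutrophic \[50, 60),
#' moderate eutrophic \[60, 70), hyper eutrophic \[70, 100\]. Interval
#' endpoints are half-open with shared boundaries assigned to the upper level;
#' the final bin is closed at 100.
#'
#' @param tsi Numeric TSI values in \[0, 100\]; NA allowed and propagated.
#' @return Factor with levels `oligotrophic`, `mesotrophic`,
#'   `light eutrophic`, `moderate eutrophic`, `hyper eutrophic`.
#' @export
trophic_level <- function(tsi) {
  ok <- is.na(tsi) | (is.finite(tsi) & tsi >= 0 & tsi <= 100)
  if (!all(ok)) stop("`tsi` must lie in [0, 100]")
  cut(tsi, breaks = c(0, 30, 50, 60, 70, 100),
      labels = trophic_levels(), right = FALSE,
      include.lowest = TRUE) -> lev
  # cut(right = FALSE) leaves 100 outside the last half-open bin; close it.
  lev[!is.na(tsi) & tsi == 100] <- "hyper eutrophic"
  lev
}

#' @rdname trophic_level
#' @return `trophic_levels()`: character vector of the five level labels in
#'   increasing trophic order.
#' @export
trophic_levels <- function() {
  c("oligotrophic", "mesotrophic", "light eutrophic",
    "moderate eutrophic", "hyper eutrophic")
}

#' Water index (NDWI, difference form)
#'
#' The water-detection index used for lake extraction, in the printed
#' difference form G - NIR. The conventional normalized ratio
#' (G - NIR)/(G + NIR) is available via `form = "normalized"`; the default is
#' the difference form the operational pipeline uses.
#'
#' @param g,nir Green and near-infrared surface reflectance (dimensionless).
#' @param form `"difference"` (default) or `"normalized"`.
#' @return Numeric index, same shape as the inputs.
#' @export
ndwi <- function(g, nir, form = c("difference", "normalized")) {
  form <- match.arg(form)
  check_finite(g, nir, .names = c("g", "nir"))
  if (form == "difference") g - nir else (g - nir) / (g + nir)
}

#' Floating algae index (FAI)
#'
#' NIR peak height above a linear baseline between the red and SWIR bands:
#' FAI = NIR - R - (SWIR - R) (lambda_NIR - lambda_R)/(lambda_SWIR - lambda_R).
#' Positive values flag floating algal scums and emergent vegetation.
#'
#' @param r,nir,swir Red, NIR and SWIR surface reflectance.
#' @param sensor A [sensor_spec()] or sensor id; supplies the wavelengths.
#' @return Numeric index, same shape as the inputs.
#' @export
fai <- function(r, nir, swir, sensor = "OLI") {
  sensor <- as_sensor(sensor)
  wl <- sensor$wavelengths
  if (wl["SWIR"] == wl["R"]) stop("degenerate sensor: lambda_SWIR == lambda_R")
  check_finite(r, nir, swir, .names = c("r", "nir", "swir"))
  k <- (wl[["NIR"]] - wl[["R"]]) / (wl[["SWIR"]] - wl[["R"]])
  nir - r - (swir - r) * k
}

#' Turbid water index (TWI)
#'
#' TWI = R - SWIR. High values indicate sediment-dominated (turbid) water;
#' the operational turbid/algal split uses the threshold 0.076.
#'
#' @param r,swir Red and SWIR surface reflectance.
#' @return Numeric index.
#' @export
twi <- function(r, swir) {
  check_finite(r, swir, .names = c("r", "swir"))
  r - swir
}

#' Algal biomass index (ABI)
#'
#' The difference of two linear spectral baselines evaluated at the green
#' wavelength: one baseline through (lambda_B, B) and (lambda_R, R), the other
#' through (lambda_B, B) and (lambda_NIR, NIR):
#' ABI = (R - B)(lambda_G - lambda_B)/(lambda_R - lambda_B)
#'     - (NIR - B)(lambda_G - lambda_B)/(lambda_NIR - lambda_B).
#' Note the green reflectance itself cancels out of this form: ABI is the
#' difference of the two baseline heights at lambda_G.
#'
#' @param b,r,nir Blue, red and NIR surface reflectance.
#' @param sensor A [sensor_spec()] or sensor id.
#' @return Numeric index.
#' @export
abi <- function(b, r, nir, sensor = "OLI") {
  sensor <- as_sensor(sensor)
  wl <- sensor$wavelengths
  if (wl["R"] == wl["B"] || wl["NIR"] == wl["B"])
    stop("degenerate sensor wavelengths for ABI baselines")
  check_finite(b, r, nir, .names = c("b", "r", "nir"))
  c1 <- (wl[["G"]] - wl[["B"]]) / (wl[["R"]] - wl[["B"]])
  c2 <- (wl[["G"]] - wl[["B"]]) / (wl[["NIR"]] - wl[["B"]])
  (r - b) * c1 - (nir - b) * c2
}

#' Default per-type ABI-to-TSI inversion coefficients
#'
#' The operational linear inversion models fitted per optical water type
#' (1 algae-dominated, 2 turbid, 3 clear): TSI = slope x ABI + intercept.
#'
#' @return A data.frame with columns `water_type`, `slope`, `intercept`,
#'   `r2`, `p_value`, `n`.
#' @export
default_tsi_coefficients <- function() {
  data.frame(
    water_type = 1:3,
    slope      = c(-601.94, -325.78, -118.28),
    intercept  = c(72.47, 55.39, 16.04),
    r2         = c(0.66, 0.67, 0.66),
    p_value    = c(0.01, 0.01, 0.01),   # reported as p < 0.01
    n          = c(310L, 272L, 71L))
}

coef_row <- function(coeffs, water_type) {
  i <- match(water_type, coeffs$water_type)
  if (any(is.na(i))) stop("no coefficients for water type ",
                          paste(water_type[is.na(i)], collapse = ", "))
  coeffs[i, , drop = FALSE]
}

#' TSI from the algal biomass index
#'
#' Applies the per-type linear inversion TSI = slope x ABI + intercept and
#' clamps the result to the 0-100 Carlson scale (clamping can be disabled).
#' The number of clamped values is attached as attribute `n_clamped` so
#' callers can log out-of-scale retrievals.
#'
#' @param abi Numeric ABI values.
#' @param water_type Integer water type(s) in 1:3, scalar or same length as
#'   `abi`.
#' @param coeffs Coefficient table as from [default_tsi_coefficients()] or
#'   [fit_type_model()] results bound together.
#' @param clamp Clamp to \[0, 100\] (default TRUE).
#' @return Numeric TSI, with attribute `n_clamped`.
#' @examples
#' tsi_from_abi(0, 1)      # 72.47, the type-1 intercept
#' tsi_from_abi(0.05, 1)   # 42.373
#' @export
tsi_from_abi <- function(abi, water_type, coeffs = default_tsi_coefficients(),
                         clamp = TRUE) {
  if (!all(water_type %in% coeffs$water_type))
    stop("unknown water type: ", paste(setdiff(water_type, coeffs$water_type), collapse = ", "))
  if (length(water_type) == 1) water_type <- rep_len(water_type, length(abi))
  stopifnot(length(water_type) == length(abi))
  row <- coef_row(coeffs, water_type)
  out <- row$slope * abi + row$intercept
  n_clamped <- 0L
  if (clamp) {
    n_clamped <- sum(out < 0 | out > 100, na.rm = TRUE)
    out <- pmin(pmax(out, 0), 100)
  }
  attr(out, "n_clamped") <- n_clamped
  out
}
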