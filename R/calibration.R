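#' Fit a per-type ABI-to-TSI inversion model
#'
#' Ordinary least squares of measured TSI on ABI for the matchups of one
#' optical water type: TSI = slope x ABI + intercept. The slope p-value is
#' the two-sided t test on n - 2 degrees of freedom.
#'
#' @param matchups Data frame with at least columns `water_type`, `abi`,
#'   `tsi_measured` (see [simulate_matchups()] for the full matchup schema).
#' @param water_type Water type (1, 2 or 3) to fit; rows of other types are
#'   dropped. Use `NULL` to fit all rows as given.
#' @return Object of class `tsi_model`: list with `water_type`, `slope`,
#'   `intercept`, `r2`, `p_value`, `n`, confidence-interval helper data and
#'   the underlying `lm` fit.
#' @examples
#' m <- simulate_matchups(50, water_type = 1, tsi_noise_sd = 3, seed = 1)
#' fit <- fit_type_model(m, 1)
#' coef(fit)
#' @export
fit_type_model <- function(matchups, water_type = NULL) {
  d <- as.data.frame(matchups)
  if (!all(c("abi", "tsi_measured") %in% names(d)))
    stop("matchups need columns `abi` and `tsi_measured`")
  if (!is.null(water_type)) d <- d[d$water_type == water_type, , drop = FALSE]
  d <- d[is.finite(d$abi) & is.finite(d$tsi_measured), , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 matchups to fit a type model")
  if (diff(range(d$abi)) == 0) stop("singular fit: all ABI values identical")
  fit <- stats::lm(tsi_measured ~ abi, data = d)
  sm <- summary(fit)
  structure(list(
    water_type = if (is.null(water_type)) NA_integer_ else as.integer(water_type),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = sm$r.squared,
    p_value = sm$coefficients["abi", "Pr(>|t|)"],
    n = nrow(d),
    conf_int = stats::confint(fit, level = 0.95),
    fit = fit), class = "tsi_model")
}

#' @export
print.tsi_model <- function(x, ...) {
  cat("<tsi_model> TSI = slope x ABI + intercept",
      if (!is.na(x$water_type)) sprintf("(water type %d)", x$water_type), "\n")
  cat(sprintf("  slope %.2f, intercept %.2f, R2 %.3f, p %.3g, n %d\n",
              x$slope, x$intercept, x$r2, x$p_value, x$n))
  invisible(x)
}

#' @export
coef.tsi_model <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
summary.tsi_model <- function(object, ...) summary(object$fit, ...)

#' @export
predict.tsi_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::fitted(object$fit))
  if (is.numeric(newdata)) newdata <- data.frame(abi = newdata)
  stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
residuals.tsi_model <- function(object, ...) stats::residuals(object$fit)

#' Coefficient table from fitted type models
#'
#' Binds [fit_type_model()] results into the coefficient-table schema used by
#' [tsi_from_abi()] and [invert_tsi()].
#'
#' @param ... `tsi_model` objects (one per water type).
#' @return Data frame with columns `water_type`, `slope`, `intercept`, `r2`,
#'   `p_value`, `n`.
#' @export
coefficients_table <- function(...) {
  fits <- list(...)
  do.call(rbind, lapply(fits, function(f) data.frame(
    water_type = f$water_type, slope = f$slope, intercept = f$intercept,
    r2 = f$r2, p_value = f$p_value, n = f$n)))
}

#' Clear-water reflectance threshold
#'
#' The clear-water green-band cutoff is mu + 2 sigma of the green reflectance
#' distribution of surveyed oligotrophic lakes (95% one-sided coverage under
#' normality). With the surveyed mu = 0.065 and sigma = 0.021 this gives
#' 0.107, reported operationally as 0.11.
#'
#' @param mu Mean green reflectance of clear-water pixels.
#' @param sigma Standard deviation (>= 0).
#' @param digits If non-NULL, round the reported threshold to this many
#'   decimals (the operational value uses 2).
#' @return The threshold reflectance.
#' @examples
#' clear_threshold(0.065, 0.021)              # 0.107
#' clear_threshold(0.065, 0.021, digits = 2)  # 0.11
#' @export
clear_threshold <- function(mu, sigma, digits = NULL) {
  if (!is.finite(mu) || !is.finite(sigma) || sigma < 0)
    stop("`sigma` must be finite and >= 0")
  out <- mu + 2 * sigma
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Validation metrics for estimated vs measured TSI
#'
#' Computes the report card used to validate retrievals against in-situ
#' measurements: R2 of the OLS regression of estimated on measured (primary),
#' squared Pearson correlation (also reported), RMSE, MAE, MRE (mean of
#' |e - m| / m, percent) and trophic-level agreement (percent of pairs whose
#' estimated and measured TSI fall in the same trophic level).
#'
#' @param estimated,measured Equal-length numeric vectors (>= 2 pairs);
#'   `measured` must be strictly positive for the MRE.
#' @return Object of class `tsi_metrics`: list with `r2`, `r2_pearson`,
#'   `rmse`, `mre`, `mae`, `n`, `level_accuracy`.
#' @examples
#' score(c(11, 21, 31), c(10, 20, 30))
#' @export
score <- function(estimated, measured) {
  if (length(estimated) != length(measured))
    stop("`estimated` and `measured` must have equal length")
  ok <- is.finite(estimated) & is.finite(measured)
  e <- estimated[ok]; m <- measured[ok]
  if (length(e) < 2) stop("need at least 2 finite pairs")
  if (any(m <= 0)) stop("`measured` must be > 0 for the relative error")
  fit <- stats::lm(e ~ m)
  # summary.lm warns on exact fits; a perfect retrieval is a legitimate input
  r2 <- suppressWarnings(summary(fit)$r.squared)
  lev_e <- trophic_level(pmin(pmax(e, 0), 100))
  lev_m <- trophic_level(pmin(pmax(m, 0), 100))
  structure(list(
    r2 = r2,
    r2_pearson = stats::cor(e, m)^2,
    rmse = sqrt(mean((e - m)^2)),
    mae = mean(abs(e - m)),
    mre = 100 * mean(abs(e - m) / m),
    n = length(e),
    level_accuracy = 100 * mean(lev_e == lev_m)), class = "tsi_metrics")
}

#' @export
print.tsi_metrics <- function(x, ...) {
  cat("<tsi_metrics>\n")
  cat(sprintf("  n %d  R2 %.3f (regression)  RMSE %.2f  MAE %.2f  MRE %.2f%%\n",
              x$n, x$r2, x$rmse, x$mae, x$mre))
  cat(sprintf("  trophic level agreement %.1f%%\n", x$level_accuracy))
  invisible(x)
}

#' Structural audit of an annual TSI table
#'
#' Summary statistics over a dataset in the published annual-record schema:
#' the share of lakes with long annual TSI series, the share of complete
#' series, the lake-area class shares and the per-zone row counts.
#'
#' @param annual_tsi Data frame in the `annual_TSI.csv` schema (one row per
#'   lake, `TSI_<year>` columns; see [write_tables()]).
#' @param lake_info Data frame in the `lake_info.csv` schema (columns
#'   `Lake Area`, `Lake Zone`; check.names-mangled equivalents accepted).
#' @param min_years Series-length cutoff for the long-series share
#'   (default 30).
#' @return List with `pct_series_ge_min` (percent of lakes with at least
#'   `min_years` non-missing annual values), `pct_series_complete` (percent
#'   with every year present), `pct_area_1_10` and `pct_area_gt_500`
#'   (percent of lakes in the 1-10 km2 and >500 km2 area classes) and
#'   `zone_counts` (named vector of rows per lake zone).
#' @export
dataset_audit <- function(annual_tsi, lake_info, min_years = 30) {
  tsi_cols <- grep("^TSI_", names(annual_tsi))
  if (!length(tsi_cols)) stop("no TSI_<year> columns found")
  nyr <- length(tsi_cols)
  n_present <- rowSums(!is.na(annual_tsi[, tsi_cols, drop = FALSE]))
  area_col <- grep("^Lake.Area$", names(lake_info))
  zone_col <- grep("^Lake.Zone$", names(lake_info))
  if (!length(area_col) || !length(zone_col))
    stop("lake_info needs `Lake Area` and `Lake Zone` columns")
  area <- lake_info[[area_col[1]]]
  zone <- lake_info[[zone_col[1]]]
  list(
    pct_series_ge_min = 100 * mean(n_present >= min_years),
    pct_series_complete = 100 * mean(n_present == nyr),
    pct_area_1_10 = 100 * mean(area >= 1 & area < 10, na.rm = TRUE),
    pct_area_gt_500 = 100 * mean(area > 500, na.rm = TRUE),
    zone_counts = table(factor(zone, levels = c("EPL", "NPML", "IMXL", "YGPL", "TPL"))))
}
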