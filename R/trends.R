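#' Per-scene lake summary
#'
#' Arithmetic mean TSI over retrieved pixels, the number of retrieved pixels
#' and the pixel coverage (retrieved / total lake pixels, percent).
#'
#' @param tsi A `tsi_raster` from [invert_tsi()] or [process_scene()] (its
#'   `lake_total` must be set).
#' @return List with `tsi_mean` (NA when nothing was retrieved),
#'   `valid_count`, `coverage_pct`.
#' @export
lake_scene_mean <- function(tsi) {
  if (is.na(tsi$lake_total) || tsi$lake_total <= 0)
    stop("`lake_total` must be a positive pixel count")
  m <- if (tsi$valid_count > 0) mean(tsi$values, na.rm = TRUE) else NA_real_
  list(tsi_mean = m, valid_count = tsi$valid_count,
       coverage_pct = 100 * tsi$valid_count / tsi$lake_total)
}

#' Annual record from dated per-scene means
#'
#' Collapses the per-scene lake means falling in one calendar year into the
#' annual record: the annual TSI is the unweighted mean of per-scene lake
#' means (equal weight per observation date), the annual pixel count is the
#' rounded mean of per-scene valid-pixel counts. A year with no scenes yields
#' a missing record.
#'
#' @param dates Scene acquisition dates (`Date` or coercible).
#' @param tsi_means Per-scene lake mean TSI (NA scenes are dropped).
#' @param valid_counts Per-scene retrieved-pixel counts.
#' @param year Calendar year of the record.
#' @param lake_id Lake identifier carried through.
#' @return One-row data.frame with columns `lake_id`, `year`, `tsi_mean`,
#'   `pixel_count`, `n_scenes`.
#' @export
annualize <- function(dates, tsi_means, valid_counts, year, lake_id = NA_character_) {
  dates <- as.Date(dates)
  stopifnot(length(dates) == length(tsi_means),
            length(dates) == length(valid_counts))
  in_year <- !is.na(dates) & as.integer(format(dates, "%Y")) == year & !is.na(tsi_means)
  if (!any(in_year))
    return(data.frame(lake_id = as.character(lake_id), year = as.integer(year),
                      tsi_mean = NA_real_, pixel_count = NA_integer_,
                      n_scenes = 0L))
  data.frame(lake_id = as.character(lake_id), year = as.integer(year),
             tsi_mean = mean(tsi_means[in_year]),
             pixel_count = as.integer(round(mean(valid_counts[in_year]))),
             n_scenes = sum(in_year))
}

#' Long-term average TSI and trophic level
#'
#' Unweighted mean over the non-missing annual TSI values of a lake's record
#' series, with the corresponding trophic level.
#'
#' @param records Data frame of annual records (needs column `tsi_mean`), or
#'   a numeric vector of annual values.
#' @return List with `average_tsi` and `level` (factor, see
#'   [trophic_level()]).
#' @export
forty_year_average <- function(records) {
  vals <- if (is.data.frame(records)) records$tsi_mean else as.numeric(records)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no non-missing annual values")
  avg <- mean(vals)
  list(average_tsi = avg, level = trophic_level(min(max(avg, 0), 100)))
}

#' Mann-Kendall trend test with Sen slope
#'
#' Non-parametric monotone trend test on an annual series with gaps. The
#' statistic is S = sum over pairs i < j of sign(x_j - x_i); its variance
#' uses the tie correction n(n-1)(2n+5)/18 - sum t(t-1)(2t+5)/18, the normal
#' deviate Z applies the continuity correction (|S| - 1 in the numerator),
#' and the p-value is two-sided normal. The Sen slope is the median of
#' pairwise slopes (x_j - x_i)/(t_j - t_i) over the actual year spacing.
#' Missing years are dropped. Series with fewer than 4 non-missing values
#' return "no trend" with a warning (the normal approximation is unreliable);
#' fewer than 2 values is an error.
#'
#' @param x Annual values (may contain NA).
#' @param years Time coordinates (defaults to the series index); used for
#'   the Sen slope denominator.
#' @param alpha Significance level for the trend call (default 0.05).
#' @return Object of class `mk_trend`: list with `s`, `var_s`, `z`,
#'   `p_value`, `sen_slope`, `trend` (`"increase"`, `"decrease"` or
#'   `"no trend"`), `n`, `alpha`.
#' @examples
#' mann_kendall(1:10)                        # strong increase, S = 45
#' mann_kendall(c(5, 5, 5, 5, 5))            # no trend
#' @export
mann_kendall <- function(x, years = seq_along(x), alpha = 0.05) {
  stopifnot(length(x) == length(years))
  keep <- !is.na(x) & !is.na(years)
  x <- as.numeric(x[keep]); t <- as.numeric(years[keep])
  o <- order(t); x <- x[o]; t <- t[o]
  n <- length(x)
  if (n < 2) stop("need at least 2 non-missing values")
  if (anyDuplicated(t)) stop("duplicate time coordinates")
  # pairwise differences, i < j
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dt <- t[ij[2, ]] - t[ij[1, ]]
  s <- sum(sign(dx))
  ties <- table(x)
  tt <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) - sum(tt * (tt - 1) * (2 * tt + 5))) / 18
  z <- if (var_s > 0) {
    if (s > 0) (s - 1) / sqrt(var_s) else if (s < 0) (s + 1) / sqrt(var_s) else 0
  } else 0
  p <- 2 * stats::pnorm(-abs(z))
  sen <- stats::median(dx / dt)
  small <- n < 4
  if (small) warning("fewer than 4 values: trend forced to 'no trend'")
  trend <- if (!small && p < alpha) {
    if (s > 0) "increase" else "decrease"
  } else "no trend"
  structure(list(s = s, var_s = var_s, z = z, p_value = p, sen_slope = sen,
                 trend = trend, n = n, alpha = alpha), class = "mk_trend")
}

#' @export
print.mk_trend <- function(x, ...) {
  cat("<mk_trend> Mann-Kendall test, n =", x$n, "\n")
  cat(sprintf("  S %.0f  Z %.3f  p %.4g  Sen slope %.4f / yr\n",
              x$s, x$z, x$p_value, x$sen_slope))
  cat(sprintf("  trend: %s (alpha = %g)\n", x$trend, x$alpha))
  invisible(x)
}

#' Build per-lake annual record tables from per-scene results
#'
#' Convenience aggregation: given a data.frame of per-scene lake means
#' (columns `lake_id`, `date`, `tsi_mean`, `valid_count`), produce the annual
#' records for a span of years for every lake.
#'
#' @param scene_results Data frame of per-scene results.
#' @param years Integer vector of calendar years to cover.
#' @return Data frame of annual records (one row per lake x year).
#' @export
aggregate_annual <- function(scene_results, years) {
  stopifnot(all(c("lake_id", "date", "tsi_mean", "valid_count") %in% names(scene_results)))
  out <- lapply(unique(scene_results$lake_id), function(id) {
    d <- scene_results[scene_results$lake_id == id, ]
    do.call(rbind, lapply(years, function(y)
      annualize(d$date, d$tsi_mean, d$valid_count, y, lake_id = id)))
  })
  do.call(rbind, out)
}
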