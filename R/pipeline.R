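#' Pipeline thresholds
#'
#' The operational decision-tree constants: FAI above `fai_scum` flags thick
#' floating algae, FAI in (`fai_vegetation`, `fai_scum`\] flags aquatic
#' vegetation, green reflectance below `clear_g` (or blue > green) flags clear
#' water, TWI at or above `twi_turbid` flags turbid water. `fai_suspended`
#' is only used when `strict_fai = TRUE`: water pixels with FAI below it are
#' additionally excluded as highly suspended.
#'
#' @param fai_scum Scum threshold on FAI (default 0.02).
#' @param fai_vegetation Vegetation threshold on FAI (default -0.004).
#' @param fai_suspended Strict-mode lower FAI cutoff (default -0.01).
#' @param twi_turbid Turbid-water threshold on TWI (default 0.076).
#' @param clear_g Clear-water threshold on green reflectance (default 0.11,
#'   i.e. mu + 2 sigma of surveyed oligotrophic lakes, see
#'   [clear_threshold()]).
#' @param ndwi_form NDWI form for water extraction, `"difference"` or
#'   `"normalized"`.
#' @param strict_fai Apply the `fai_suspended` exclusion (default FALSE).
#' @return Named list of thresholds.
#' @export
pipeline_thresholds <- function(fai_scum = 0.02, fai_vegetation = -0.004,
                                fai_suspended = -0.01, twi_turbid = 0.076,
                                clear_g = 0.11,
                                ndwi_form = c("difference", "normalized"),
                                strict_fai = FALSE) {
  ndwi_form <- match.arg(ndwi_form)
  th <- list(fai_scum = fai_scum, fai_vegetation = fai_vegetation,
             fai_suspended = fai_suspended, twi_turbid = twi_turbid,
             clear_g = clear_g, ndwi_form = ndwi_form, strict_fai = strict_fai)
  num <- unlist(th[1:5])
  if (any(!is.finite(num))) stop("all thresholds must be finite")
  th
}

#' Class-map label set
#'
#' Integer codes and labels used in classification maps: 1 land, 2 cloud,
#' 3 scum, 4 vegetation, 5 type1 (algae-dominated), 6 type2 (turbid),
#' 7 type3 (clear), 8 invalid.
#'
#' @return Character vector of the eight labels, in code order.
#' @export
class_labels <- function() {
  c("land", "cloud", "scum", "vegetation", "type1", "type2", "type3", "invalid")
}

new_class_map <- function(codes) {
  structure(codes, class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  cat("<class_map>", nrow(x), "x", ncol(x), "pixels\n")
  tab <- table(factor(class_labels()[x], levels = class_labels()))
  print(tab)
  invisible(x)
}

#' Convert a class map to a factor matrix of labels
#' @param classes A `class_map`.
#' @return Character matrix of labels.
#' @export
class_map_labels <- function(classes) {
  matrix(class_labels()[unclass(classes)], nrow = nrow(classes))
}

#' Cloud usability mask from the QA layer
#'
#' Pixels with medium or high cloud confidence are masked; clear and
#' low-confidence pixels are kept as cloud-free.
#'
#' @param sc A [scene()].
#' @return Logical matrix, TRUE = usable (cloud-free).
#' @export
mask_clouds <- function(sc) {
  matrix(sc$qa %in% c("clear", "low"), nrow = nrow(sc$qa))
}

#' Bimodal (between-class variance) threshold
#'
#' Threshold separating the two modes of a sample, chosen to maximize the
#' between-class variance over a 256-bin histogram (Otsu's criterion).
#' Deterministic for a fixed input.
#'
#' @param values Numeric vector with at least 2 distinct finite values.
#' @param levels Number of histogram bins (default 256).
#' @return The threshold, on the scale of `values`.
#' @export
bimodal_threshold <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  if (length(values) < 2 || diff(range(values)) == 0)
    stop("degenerate histogram: need >= 2 distinct values for a bimodal threshold")
  EBImage::otsu(matrix(values, ncol = 1), range = range(values), levels = levels)
}

# 3-pixel morphological erosion with a square structuring element (7x7 box).
erode3 <- function(mask) {
  out <- EBImage::erode(mask * 1, EBImage::makeBrush(7, shape = "box"))
  matrix(out > 0.5, nrow = nrow(mask))
}

#' Extract water pixels for one lake
#'
#' Water extraction: (1) rasterize the outline; (2) compute NDWI; (3) take a
#' per-lake bimodal threshold on NDWI over cloud-free in-lake pixels; water =
#' NDWI above the threshold; (4) erode the water mask by 3 pixels (~100 m at
#' 30 m resolution, square structuring element) to suppress mixed
#' land/water boundary pixels. Cloud-masked pixels are excluded before
#' thresholding.
#'
#' @param sc A [scene()].
#' @param outline A [lake_outline()] in the scene CRS.
#' @param thresholds [pipeline_thresholds()] (supplies the NDWI form).
#' @return Logical water mask with attributes `threshold` (the NDWI cut, NA
#'   when no water was found), `lake_mask` (rasterized outline) and
#'   `pre_erosion` (water mask before the boundary buffer).
#' @export
extract_water <- function(sc, outline, thresholds = pipeline_thresholds()) {
  lake <- rasterize_outline(outline, sc)
  usable <- mask_clouds(sc)
  empty <- function(msg) {
    warning(msg)
    structure(matrix(FALSE, nrow(lake), ncol(lake)), threshold = NA_real_,
              lake_mask = lake, pre_erosion = matrix(FALSE, nrow(lake), ncol(lake)))
  }
  if (!any(lake)) return(empty("lake outline does not intersect the scene"))
  nd <- ndwi(sc$bands$G, sc$bands$NIR, form = thresholds$ndwi_form)
  sample <- nd[lake & usable]
  if (length(sample) < 2 || diff(range(sample)) == 0)
    return(empty("no usable in-lake pixels for NDWI thresholding"))
  thr <- bimodal_threshold(sample)
  water <- lake & usable & nd > thr
  structure(erode3(water), threshold = thr, lake_mask = lake,
            pre_erosion = water)
}

#' Decision-tree water-pixel classification
#'
#' Classifies each water pixel, in this order: (1) FAI > 0.02: floating-algae
#' scum (excluded from retrieval); (2) -0.004 < FAI <= 0.02: aquatic
#' vegetation (excluded); (3) green reflectance < 0.11 OR blue > green: clear
#' water (type 3); (4) TWI >= 0.076: turbid water (type 2); (5) otherwise:
#' algae-dominated water (type 1). Exclusions precede typing, and the clear
#' test precedes the TWI split (clear pixels also have small TWI and would
#' otherwise fall into type 1). With `strict_fai` enabled in the thresholds,
#' water pixels with FAI < -0.01 are flagged invalid (highly suspended)
#' before typing.
#'
#' Non-water pixels are labelled from the masks: cloud where the QA layer is
#' medium/high confidence, invalid for in-lake pixels that failed water
#' extraction, land elsewhere.
#'
#' @param sc A [scene()].
#' @param water Water mask from [extract_water()].
#' @param thresholds [pipeline_thresholds()].
#' @return A `class_map` (integer matrix of codes, see [class_labels()]).
#' @export
classify_pixels <- function(sc, water, thresholds = pipeline_thresholds()) {
  b <- sc$bands; sens <- sc$sensor
  fai_v <- fai(b$R, b$NIR, b$SWIR, sens)
  twi_v <- twi(b$R, b$SWIR)
  usable <- mask_clouds(sc)
  lake <- attr(water, "lake_mask")
  if (is.null(lake)) lake <- water

  codes <- matrix(1L, nrow(b$G), ncol(b$G))             # land
  codes[!usable] <- 2L                                   # cloud
  codes[lake & usable & !water] <- 8L                    # failed extraction
  w <- water & usable

  is_scum <- w & fai_v > thresholds$fai_scum
  is_veg  <- w & !is_scum & fai_v > thresholds$fai_vegetation
  rest <- w & !is_scum & !is_veg
  if (isTRUE(thresholds$strict_fai)) {
    suspended <- rest & fai_v < thresholds$fai_suspended
    codes[suspended] <- 8L
    rest <- rest & !suspended
  }
  is_clear <- rest & (b$G < thresholds$clear_g | b$B > b$G)
  is_turb  <- rest & !is_clear & twi_v >= thresholds$twi_turbid
  is_alg   <- rest & !is_clear & !is_turb

  codes[is_scum] <- 3L
  codes[is_veg]  <- 4L
  codes[is_alg]  <- 5L
  codes[is_turb] <- 6L
  codes[is_clear] <- 7L
  new_class_map(codes)
}

#' Per-pixel TSI inversion
#'
#' Applies the per-type linear ABI-to-TSI models to every pixel classified as
#' water type 1-3; all other pixels are missing. Retrieved values are clamped
#' to the 0-100 scale and clamping events counted.
#'
#' @param sc A [scene()].
#' @param classes A `class_map` from [classify_pixels()].
#' @param coeffs Coefficient table (default [default_tsi_coefficients()]).
#' @return Object of class `tsi_raster`: list with `values` (matrix, NA where
#'   not retrieved), `valid_count`, `lake_total` (pixels inside the outline,
#'   when known), `n_clamped`.
#' @export
invert_tsi <- function(sc, classes, coeffs = default_tsi_coefficients()) {
  codes <- unclass(classes)
  vals <- matrix(NA_real_, nrow(codes), ncol(codes))
  n_clamped <- 0L
  abi_v <- abi(sc$bands$B, sc$bands$R, sc$bands$NIR, sc$sensor)
  for (t in 1:3) {
    sel <- codes == (4L + t)
    if (any(sel)) {
      tv <- tsi_from_abi(abi_v[sel], t, coeffs)
      n_clamped <- n_clamped + attr(tv, "n_clamped")
      vals[sel] <- tv
    }
  }
  lake_total <- NA_integer_
  structure(list(values = vals, valid_count = sum(!is.na(vals)),
                 lake_total = lake_total, n_clamped = n_clamped),
            class = "tsi_raster")
}

#' @export
print.tsi_raster <- function(x, ...) {
  cat("<tsi_raster>", nrow(x$values), "x", ncol(x$values), "pixels;",
      x$valid_count, "retrieved\n")
  if (x$valid_count > 0)
    cat(sprintf("  TSI mean %.2f, range [%.2f, %.2f]\n",
                mean(x$values, na.rm = TRUE), min(x$values, na.rm = TRUE),
                max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Full per-scene retrieval for one lake
#'
#' Convenience wrapper chaining cloud masking, water extraction,
#' classification and TSI inversion, and attaching per-class pixel counts.
#'
#' @param sc A [scene()].
#' @param outline A [lake_outline()].
#' @param thresholds [pipeline_thresholds()].
#' @param coeffs Coefficient table.
#' @return List with `classes` (class_map), `tsi` (tsi_raster, with
#'   `lake_total` filled in), `water_threshold`, `class_counts`,
#'   `coverage_pct`.
#' @export
process_scene <- function(sc, outline, thresholds = pipeline_thresholds(),
                          coeffs = default_tsi_coefficients()) {
  water <- extract_water(sc, outline, thresholds)
  classes <- classify_pixels(sc, water, thresholds)
  tsi <- invert_tsi(sc, classes, coeffs)
  lake <- attr(water, "lake_mask")
  tsi$lake_total <- sum(lake)
  counts <- table(factor(class_labels()[unclass(classes)], levels = class_labels()))
  cov <- if (tsi$lake_total > 0) 100 * tsi$valid_count / tsi$lake_total else NA_real_
  list(classes = classes, tsi = tsi,
       water_threshold = attr(water, "threshold"),
       class_counts = counts, coverage_pct = cov,
       lake_mask = lake)
}

#' Process several lakes in one scene
#'
#' Runs [process_scene()] for each outline and merges the per-lake results
#' into a scene-wide class map and TSI raster (each lake's classification is
#' written into its own outline region; everything else is land or cloud).
#'
#' @param sc A [scene()].
#' @param outlines List of [lake_outline()] objects.
#' @param thresholds,coeffs As in [process_scene()].
#' @return List with `classes`, `tsi` (matrix), and `lakes` (named list of
#'   per-lake [process_scene()] results).
#' @export
process_lakes <- function(sc, outlines, thresholds = pipeline_thresholds(),
                          coeffs = default_tsi_coefficients()) {
  usable <- mask_clouds(sc)
  codes <- matrix(1L, nrow(usable), ncol(usable))
  codes[!usable] <- 2L
  tsi <- matrix(NA_real_, nrow(usable), ncol(usable))
  res <- lapply(outlines, function(ol) process_scene(sc, ol, thresholds, coeffs))
  names(res) <- vapply(outlines, function(ol) ol$lake_id, "")
  for (r in res) {
    reg <- r$lake_mask
    codes[reg] <- unclass(r$classes)[reg]
    tsi[reg] <- r$tsi$values[reg]
  }
  list(classes = new_class_map(codes), tsi = tsi, lakes = res)
}
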