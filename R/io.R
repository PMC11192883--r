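qa_codes <- c(clear = 1L, low = 2L, medium = 3L, high = 4L)

scene_sidecar <- function(path) paste0(sub("\\.tif$", "", path), ".json")

#' Write / read a scene as multi-page TIFF with a JSON sidecar
#'
#' Scenes are stored as a 6-page 32-bit float TIFF (pages B, G, R, NIR, SWIR
#' and the QA layer encoded as codes 1-4 over 255) plus a JSON sidecar
#' (`<path>.json`) carrying the sensor id, blue-wavelength override,
#' geotransform, CRS and acquisition date. Reflectance is stored as
#' dimensionless floats; integer-scaled surface-reflectance inputs (the
#' x10000 dialect) are rescaled on read when the value range implies it.
#'
#' @param sc A [scene()].
#' @param path Output path (`.tif` appended if absent).
#' @return `write_scene()`: the path, invisibly. `read_scene()`: a
#'   [scene()].
#' @export
write_scene <- function(sc, path) {
  if (!grepl("\\.tif$", path)) path <- paste0(path, ".tif")
  pages <- c(unname(sc$bands[c("B", "G", "R", "NIR", "SWIR")]),
             list(matrix(qa_codes[sc$qa] / 255, nrow(sc$qa))))
  pages <- lapply(pages, function(p) pmin(pmax(p, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(sensor_id = sc$sensor$sensor_id,
               lambda_B = unname(sc$sensor$wavelengths[["B"]]),
               geotransform = sc$geotransform, crs = sc$crs,
               date = format(sc$date), bands = c("B", "G", "R", "NIR", "SWIR", "QA"))
  jsonlite::write_json(meta, scene_sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene
#' @param sensor_id Sensor override when the sidecar is missing.
#' @export
read_scene <- function(path, sensor_id = NULL) {
  if (!grepl("\\.tif$", path)) path <- paste0(path, ".tif")
  if (!file.exists(path)) stop("scene file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  meta <- if (file.exists(scene_sidecar(path)))
    jsonlite::read_json(scene_sidecar(path), simplifyVector = TRUE) else NULL
  if (length(pages) < 6) stop("expected 6 pages (B,G,R,NIR,SWIR,QA), found ",
                              length(pages))
  sid <- if (!is.null(meta)) meta$sensor_id else sensor_id
  if (is.null(sid)) stop("unknown sensor: no sidecar and no `sensor_id` given")
  # undo readTIFF's [0,1] scaling for integer-stored pages; 32-bit pages are
  # float samples and come back unscaled
  raw_page <- function(p) {
    bits <- attr(p, "bits.per.sample")
    v <- if (!is.null(bits) && bits %in% c(8L, 16L)) round(p * (2^bits - 1)) else p
    matrix(as.numeric(v), nrow = dim(p)[1])
  }
  bands <- lapply(pages[1:5], raw_page)
  names(bands) <- c("B", "G", "R", "NIR", "SWIR")
  # integer-scaled SR dialect (x10000) detection
  mx <- max(vapply(bands, max, 0), na.rm = TRUE)
  if (mx > 1.5) bands <- lapply(bands, function(b) b / 10000)
  qa_page <- raw_page(pages[[6]])
  # QA codes: stored /255 in float pages (max 4/255), raw integers otherwise
  qa_int <- if (max(qa_page) < 0.5) round(qa_page * 255) else round(qa_page)
  qa <- matrix(names(qa_codes)[pmin(pmax(qa_int, 1), 4)], nrow(pages[[6]]))
  sens <- if (!is.null(meta) && !is.null(meta$lambda_B))
    sensor_spec(sid, lambda_B = meta$lambda_B) else sensor_spec(sid)
  scene(bands, qa, sensor = sens,
        geotransform = if (!is.null(meta)) meta$geotransform else c(0, 1, 0, 0, 0, -1),
        date = if (!is.null(meta)) meta$date else as.Date("2000-01-01"),
        crs = if (!is.null(meta)) meta$crs else "local")
}

#' Write / read a classification map as 8-bit TIFF
#'
#' Class codes (see [class_labels()]) are stored one byte per pixel.
#'
#' @param classes A `class_map`.
#' @param path Output path.
#' @return The path / the `class_map`.
#' @export
write_class_map <- function(classes, path) {
  if (!grepl("\\.tif$", path)) path <- paste0(path, ".tif")
  tiff::writeTIFF(unclass(classes) / 255, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_class_map
#' @export
read_class_map <- function(path) {
  if (!grepl("\\.tif$", path)) path <- paste0(path, ".tif")
  img <- tiff::readTIFF(path)
  new_class_map(matrix(as.integer(round(img * 255)), nrow = dim(img)[1]))
}

#' Write / read a TSI raster as float TIFF
#'
#' Stored as two 32-bit float pages: TSI scaled to \[0, 1\] (TSI / 100) and a
#' validity mask (1 = retrieved). Missing pixels are NA after reading.
#'
#' @param tsi A `tsi_raster` (or plain matrix with NAs).
#' @param path Output path.
#' @return The path / a matrix with NAs for missing pixels.
#' @export
write_tsi_raster <- function(tsi, path) {
  if (!grepl("\\.tif$", path)) path <- paste0(path, ".tif")
  vals <- if (inherits(tsi, "tsi_raster")) tsi$values else tsi
  valid <- !is.na(vals)
  page1 <- vals / 100; page1[!valid] <- 0
  tiff::writeTIFF(list(pmin(pmax(page1, 0), 1), valid * 1),
                  path, bits.per.sample = 32L, compression = "none")
  invisible(path)
}

#' @rdname write_tsi_raster
#' @export
read_tsi_raster <- function(path) {
  if (!grepl("\\.tif$", path)) path <- paste0(path, ".tif")
  pages <- tiff::readTIFF(path, all = TRUE)
  vals <- pages[[1]] * 100
  vals[pages[[2]] < 0.5] <- NA_real_
  vals
}

#' Write / read lake outlines as GeoJSON
#'
#' FeatureCollection of Polygon features with properties `lake_id`, `name`,
#' `area_km2`, `zone`, `elevation_m`.
#'
#' @param outlines List of [lake_outline()] objects.
#' @param path GeoJSON path.
#' @return The path / a named list of [lake_outline()].
#' @export
write_lake_outlines <- function(outlines, path) {
  feats <- lapply(outlines, function(ol) {
    ring <- rbind(ol$polygon, ol$polygon[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(lake_id = ol$lake_id, name = ol$name,
                           area_km2 = ol$area_km2, zone = ol$zone,
                           elevation_m = ol$elevation_m),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) as.numeric(ring[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = unname(feats)),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_lake_outlines
#' @export
read_lake_outlines <- function(path) {
  if (!file.exists(path)) stop("outline file not found: ", path)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  out <- lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) as.numeric(unlist(p))))
    ring <- ring[-nrow(ring), , drop = FALSE]  # drop closing vertex
    pr <- f$properties
    nz <- function(x, d) if (is.null(x)) d else x
    lake_outline(nz(pr$lake_id, "unknown"), ring,
                 area_km2 = as.numeric(nz(pr$area_km2, NA_real_)),
                 zone = as.character(nz(pr$zone, NA_character_)),
                 elevation_m = as.numeric(nz(pr$elevation_m, NA_real_)),
                 name = as.character(nz(pr$name, "")))
  })
  names(out) <- vapply(out, function(o) o$lake_id, "")
  out
}

fmt_num <- function(x, digits) {
  if (is.null(digits)) return(x)
  ifelse(is.na(x), NA, sprintf(paste0("%.", digits, "f"), x))
}

#' Write the published-schema output tables
#'
#' Produces `lake_info.csv`, `annual_TSI.csv` and `annual_pixel.csv` with the
#' dataset's exact attribute names: lake metadata (Lake ID, Lake Name,
#' Lon (DD), Lat (DD), Lake Area, Lake Zone, Elevation (m), Row, Path);
#' one `TSI_<year>` column per year plus Average TSI, Trophic Level,
#' Trend_40y and Slope_40y; and Total Pixels plus one `Pixel_<year>` column
#' per year. Missing annual values are written as empty cells; TSI values
#' are fixed at 2 decimals for byte-stable output (`digits = NULL` keeps
#' full precision).
#'
#' @param records Annual records data frame (`lake_id`, `year`, `tsi_mean`,
#'   `pixel_count`), e.g. from [aggregate_annual()].
#' @param trends Named list of `mk_trend` objects keyed by lake id (or NULL
#'   to compute them from the records).
#' @param lakes List of [lake_outline()] objects (metadata source).
#' @param dir Output directory (created if needed).
#' @param years Years to emit columns for (default: range found in records).
#' @param alpha Significance level when trends are computed here.
#' @param digits Decimals for TSI columns (default 2).
#' @return Invisibly, the three file paths.
#' @export
write_tables <- function(records, trends = NULL, lakes, dir,
                         years = NULL, alpha = 0.05, digits = 2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(lakes, function(l) l$lake_id, "")
  if (anyDuplicated(ids)) stop("duplicate lake ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  if (is.null(years)) years <- seq(min(records$year), max(records$year))

  centroid <- function(poly) colMeans(poly)
  info <- data.frame(check.names = FALSE,
    `Lake ID` = ids,
    `Lake Name` = vapply(lakes, function(l) l$name, ""),
    `Lon (DD)` = vapply(lakes, function(l) centroid(l$polygon)[1], 0),
    `Lat (DD)` = vapply(lakes, function(l) centroid(l$polygon)[2], 0),
    `Lake Area` = vapply(lakes, function(l) l$area_km2, 0),
    `Lake Zone` = vapply(lakes, function(l) if (is.na(l$zone)) "" else l$zone, ""),
    `Elevation (m)` = vapply(lakes, function(l) l$elevation_m, 0),
    Row = NA_integer_, Path = NA_integer_)

  get_rec <- function(id, y, col) {
    v <- records[[col]][records$lake_id == id & records$year == y]
    if (length(v)) v[1] else NA
  }
  tsi_mat <- sapply(years, function(y) vapply(ids, function(id)
    as.numeric(get_rec(id, y, "tsi_mean")), 0))
  pix_mat <- sapply(years, function(y) vapply(ids, function(id)
    as.numeric(get_rec(id, y, "pixel_count")), 0))
  if (length(ids) == 1) { tsi_mat <- matrix(tsi_mat, 1); pix_mat <- matrix(pix_mat, 1) }
  colnames(tsi_mat) <- paste0("TSI_", years)
  colnames(pix_mat) <- paste0("Pixel_", years)

  if (is.null(trends)) {
    trends <- lapply(ids, function(id) {
      v <- tsi_mat[match(id, ids), ]
      if (sum(!is.na(v)) >= 2) mann_kendall(v, years, alpha = alpha) else NULL
    })
    names(trends) <- ids
  }
  avg <- apply(tsi_mat, 1, function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  lev <- rep(NA_character_, length(avg))
  lev[!is.na(avg)] <- as.character(trophic_level(pmin(pmax(avg[!is.na(avg)], 0), 100)))
  tr_lab <- vapply(ids, function(id)
    if (is.null(trends[[id]])) NA_character_ else trends[[id]]$trend, "")
  tr_slope <- vapply(ids, function(id)
    if (is.null(trends[[id]])) NA_real_ else trends[[id]]$sen_slope, 0)

  tsi_fmt <- matrix(fmt_num(tsi_mat, digits), nrow = nrow(tsi_mat),
                    dimnames = dimnames(tsi_mat))
  annual_tsi <- data.frame(check.names = FALSE, `Lake ID` = ids,
                           as.data.frame(tsi_fmt, check.names = FALSE),
                           `Average TSI` = fmt_num(avg, digits),
                           `Trophic Level` = lev,
                           Trend_40y = tr_lab,
                           Slope_40y = fmt_num(tr_slope, if (is.null(digits)) NULL else 4))
  total_px <- apply(pix_mat, 1, function(v) if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  annual_pixel <- data.frame(check.names = FALSE, `Lake ID` = ids,
                             `Total Pixels` = total_px,
                             as.data.frame(pix_mat, check.names = FALSE))

  p1 <- file.path(dir, "lake_info.csv")
  p2 <- file.path(dir, "annual_TSI.csv")
  p3 <- file.path(dir, "annual_pixel.csv")
  utils::write.csv(info, p1, row.names = FALSE, na = "")
  utils::write.csv(annual_tsi, p2, row.names = FALSE, na = "")
  utils::write.csv(annual_pixel, p3, row.names = FALSE, na = "")
  invisible(c(lake_info = p1, annual_TSI = p2, annual_pixel = p3))
}

#' Read the published-schema output tables
#'
#' @param dir Directory containing `lake_info.csv`, `annual_TSI.csv`,
#'   `annual_pixel.csv`.
#' @return Named list of the three data frames (original column names kept).
#' @export
read_tables <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), check.names = FALSE)
  list(lake_info = rd("lake_info.csv"),
       annual_TSI = rd("annual_TSI.csv"),
       annual_pixel = rd("annual_pixel.csv"))
}

#' Run configuration
#'
#' All tunable constants of the pipeline in one serializable object: the
#' decision-tree thresholds, the per-type inversion coefficients, the trend
#' significance level, the sensor blue-wavelength override and the
#' cross-sensor harmonization transform (per-band linear `gain * x + offset`,
#' default identity).
#'
#' @param thresholds [pipeline_thresholds()].
#' @param coefficients Coefficient table.
#' @param alpha Trend significance level (default 0.05).
#' @param lambda_B Named list of blue band-centre overrides per sensor id.
#' @param harmonization Named list per band of `c(gain, offset)`; identity
#'   when NULL.
#' @param seed Default seed.
#' @param verbosity 0 quiet, 1 normal, 2 verbose.
#' @return Object of class `run_config`.
#' @export
run_config <- function(thresholds = pipeline_thresholds(),
                       coefficients = default_tsi_coefficients(),
                       alpha = 0.05, lambda_B = NULL, harmonization = NULL,
                       seed = 1, verbosity = 1) {
  structure(list(thresholds = thresholds, coefficients = coefficients,
                 alpha = alpha, lambda_B = lambda_B,
                 harmonization = harmonization, seed = seed,
                 verbosity = verbosity), class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  th <- as.list(x$thresholds)
  cfg <- run_config(
    thresholds = pipeline_thresholds(
      fai_scum = th$fai_scum, fai_vegetation = th$fai_vegetation,
      fai_suspended = th$fai_suspended, twi_turbid = th$twi_turbid,
      clear_g = th$clear_g, ndwi_form = th$ndwi_form,
      strict_fai = isTRUE(th$strict_fai)),
    coefficients = as.data.frame(x$coefficients),
    alpha = x$alpha, lambda_B = x$lambda_B,
    harmonization = x$harmonization, seed = x$seed, verbosity = x$verbosity)
  cfg
}

#' Cross-sensor harmonization
#'
#' Applies a per-band linear transform (gain * reflectance + offset) to a
#' scene, the hook used to bring TM/ETM+ reflectance onto the OLI scale.
#' Default is the identity.
#'
#' @param sc A [scene()].
#' @param harmonization Named list per band of `c(gain, offset)`.
#' @return The transformed [scene()].
#' @export
harmonize_scene <- function(sc, harmonization = NULL) {
  if (is.null(harmonization)) return(sc)
  for (b in names(harmonization)) {
    if (!b %in% names(sc$bands)) stop("unknown band in harmonization: ", b)
    gv <- as.numeric(unlist(harmonization[[b]]))
    sc$bands[[b]] <- gv[1] * sc$bands[[b]] + gv[2]
  }
  sc
}
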