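#' Multiband reflectance scene
#'
#' In-memory container for one acquisition: five surface-reflectance band
#' grids (B, G, R, NIR, SWIR), a categorical cloud-confidence QA grid, the
#' sensor specification, an affine geotransform and the acquisition date.
#'
#' @param bands Named list of numeric matrices `B`, `G`, `R`, `NIR`, `SWIR`,
#'   all of identical dimension; dimensionless surface reflectance. Values
#'   outside \[0, 1\] are accepted (surface-reflectance products can exceed
#'   the physical range) but counted in attribute `n_out_of_range`.
#' @param qa Character or factor matrix of cloud confidence, values from
#'   `"clear"`, `"low"`, `"medium"`, `"high"`; same dimension as the bands.
#' @param sensor A [sensor_spec()] or sensor id.
#' @param geotransform Numeric length-6 GDAL-style affine
#'   `c(x0, dx, rx, y0, ry, dy)` mapping (col, row) pixel indices to CRS
#'   coordinates; defaults to a unit pixel grid.
#' @param date Acquisition date (`Date` or ISO-8601 string).
#' @param crs Free-text CRS identifier carried through to outputs.
#' @return Object of class `scene`.
#' @export
scene <- function(bands, qa, sensor = "OLI",
                  geotransform = c(0, 1, 0, 0, 0, -1),
                  date = as.Date("2000-01-01"), crs = "local") {
  need <- c("B", "G", "R", "NIR", "SWIR")
  if (!is.list(bands) || !all(need %in% names(bands)))
    stop("`bands` must be a named list containing matrices ", paste(need, collapse = ", "))
  bands <- bands[need]
  dims <- lapply(bands, dim)
  if (length(unique(dims)) != 1)
    stop("all band grids must share the same dimension")
  if (!all(dim(qa) == dims[[1]]))
    stop("`qa` grid dimension differs from the bands")
  qa_levels <- c("clear", "low", "medium", "high")
  qa <- matrix(as.character(qa), nrow = nrow(bands$B))
  if (!all(qa %in% qa_levels))
    stop("`qa` values must be one of: ", paste(qa_levels, collapse = ", "))
  stopifnot(length(geotransform) == 6, all(is.finite(geotransform)))
  n_oor <- sum(vapply(bands, function(b) sum(b < 0 | b > 1, na.rm = TRUE), 0))
  structure(list(bands = bands, qa = qa, sensor = as_sensor(sensor),
                 geotransform = as.numeric(geotransform),
                 date = as.Date(date), crs = crs,
                 n_out_of_range = n_oor),
            class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  d <- dim(x$bands$B)
  cat(sprintf("<scene> %dx%d px, sensor %s, %s\n",
              d[1], d[2], x$sensor$sensor_id, format(x$date)))
  cat("  cloud cover (medium+high QA):",
      sprintf("%.1f%%", 100 * mean(x$qa %in% c("medium", "high"))), "\n")
  if (x$n_out_of_range > 0)
    cat("  note:", x$n_out_of_range, "reflectance values outside [0,1]\n")
  invisible(x)
}

#' Lake outline
#'
#' A lake polygon with identifying attributes, in the same planar CRS as the
#' scenes it is applied to.
#'
#' @param lake_id Identifier string or number.
#' @param polygon Two-column numeric matrix of (x, y) vertices; the ring is
#'   closed implicitly.
#' @param area_km2 Lake surface area, km2 (>= 1 for the national dataset).
#' @param zone Limnological zone code, one of `"EPL"`, `"NPML"`, `"IMXL"`,
#'   `"YGPL"`, `"TPL"`, or NA.
#' @param elevation_m Mean lake-surface elevation, m.
#' @param name Lake name; may be empty (some lakes are unnamed).
#' @return Object of class `lake_outline`.
#' @export
lake_outline <- function(lake_id, polygon, area_km2 = NA_real_, zone = NA_character_,
                         elevation_m = NA_real_, name = "") {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2 || nrow(polygon) < 3 || any(!is.finite(polygon)))
    stop("`polygon` must be a finite 2-column matrix with >= 3 vertices")
  if (!is.na(zone) && !zone %in% c("EPL", "NPML", "IMXL", "YGPL", "TPL"))
    stop("unknown lake zone: ", zone)
  structure(list(lake_id = as.character(lake_id), polygon = polygon,
                 area_km2 = area_km2, zone = zone,
                 elevation_m = elevation_m, name = name),
            class = "lake_outline")
}

# Map CRS coordinates of pixel centres for a scene grid.
pixel_centres <- function(geotransform, nrow, ncol) {
  gt <- geotransform
  col <- rep(seq_len(ncol), each = nrow) - 0.5
  row <- rep(seq_len(nrow), times = ncol) - 0.5
  list(x = gt[1] + gt[2] * col + gt[3] * row,
       y = gt[4] + gt[5] * col + gt[6] * row)
}

# Even-odd (ray casting) point-in-polygon, vectorized over points.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize a lake outline onto a scene grid
#'
#' Marks pixels whose centre falls inside the outline polygon (even-odd rule).
#'
#' @param outline A [lake_outline()].
#' @param sc A [scene()] supplying grid shape and geotransform.
#' @return Logical matrix, TRUE inside the lake.
#' @export
rasterize_outline <- function(outline, sc) {
  d <- dim(sc$bands$B)
  ctr <- pixel_centres(sc$geotransform, d[1], d[2])
  matrix(point_in_polygon(ctr$x, ctr$y, outline$polygon), nrow = d[1])
}
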