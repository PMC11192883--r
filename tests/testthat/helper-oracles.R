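# Independent oracles used to cross-check the vectorized implementations.

# Naive scalar decision tree for one water pixel.
oracle_classify_pixel <- function(b, g, r, nir, swir, sensor = sensor_spec("OLI"),
                                  th = pipeline_thresholds()) {
  f <- fai(r, nir, swir, sensor)
  if (f > th$fai_scum) return("scum")
  if (f > th$fai_vegetation) return("vegetation")
  if (g < th$clear_g || b > g) return("type3")
  if (twi(r, swir) >= th$twi_turbid) return("type2")
  "type1"
}

# Exhaustive between-class variance maximization over 256 histogram bins.
# Returns the best cut and a function evaluating the between-class variance
# of an arbitrary cut (the objective is flat across empty histogram regions,
# so equally-optimal cuts must be compared by objective value).
oracle_otsu <- function(values, levels = 256) {
  bcv <- function(cut) {
    a <- values[values <= cut]; b <- values[values > cut]
    if (!length(a) || !length(b)) return(0)
    length(a) * length(b) * (mean(a) - mean(b))^2 / length(values)^2
  }
  rng <- range(values)
  breaks <- seq(rng[1], rng[2], length.out = levels + 1)
  cuts <- breaks[2:levels]
  vars <- vapply(cuts, bcv, 0)
  list(cut = cuts[which.max(vars)], max_var = max(vars), bcv = bcv)
}

# Brute-force Mann-Kendall S and Sen slope by direct pair enumeration.
oracle_mk <- function(x, t = seq_along(x)) {
  keep <- !is.na(x)
  x <- x[keep]; t <- t[keep]
  n <- length(x)
  s <- 0; slopes <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- s + sign(x[j] - x[i])
    slopes <- c(slopes, (x[j] - x[i]) / (t[j] - t[i]))
  }
  list(s = s, sen = median(slopes))
}

# Small constant-band scene for pipeline unit tests.
make_scene <- function(nr = 12, nc = 12, B = 0.05, G = 0.12, R = 0.08,
                       NIR = 0.04, SWIR = 0.03, qa = "clear", sensor = "OLI") {
  m <- function(v) if (is.matrix(v)) v else matrix(v, nr, nc)
  scene(list(B = m(B), G = m(G), R = m(R), NIR = m(NIR), SWIR = m(SWIR)),
        qa = m(qa), sensor = sensor, geotransform = c(0, 1, 0, 0, 0, 1))
}

# Rectangle polygon in the pixel-centre CRS used by make_scene.
rect_poly <- function(x0, x1, y0, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}
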