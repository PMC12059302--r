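# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written as naive brute-force code, independent of
# the package's implementation paths.

# small isotropic geometry centred on the origin
smallGeometry <- function(dims = c(10L, 10L, 10L), spacing = 1) {
  sp <- rep(spacing, length.out = 3)
  GridGeometry(origin = -(dims - 1) * sp / 2, spacing = sp,
               dims = as.integer(dims))
}

randomDoseGrid <- function(geometry, max = 10) {
  DoseGrid(geometry, array(runif(prod(geometry@dims), 0, max),
                           dim = geometry@dims))
}

# pointwise trilinear interpolation oracle: nested-loop, one point at a time
oracleTrilinear <- function(values, origin, spacing, p) {
  f <- (p - origin) / spacing
  d <- dim(values)
  if (any(f < 0) || any(f > d - 1)) return(0)
  i0 <- pmin(floor(f), d - 2); i0 <- pmax(i0, 0)
  w <- f - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[1] else 1 - w[1]) *
          (if (dy) w[2] else 1 - w[2]) *
          (if (dz) w[3] else 1 - w[3])
    acc <- acc + wt * values[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  acc
}

# dose at cumulative hottest volume v: sort, accumulate, interpolate
oracleDoseAtVolume <- function(doses, voxVolCc, v) {
  d <- sort(doses, decreasing = TRUE)
  cum <- cumsum(rep(voxVolCc, length(d)))
  if (v <= cum[1]) return(d[1])
  i <- which(cum >= v)[1]
  d[i - 1] + (d[i] - d[i - 1]) * (v - cum[i - 1]) / (cum[i] - cum[i - 1])
}

# brute-force Euclidean dilation: all-pairs distance between voxel centres
oracleDilate <- function(mask, geometry, marginMm) {
  d <- dim(mask)
  sp <- geometry@spacing
  idxTrue <- which(mask, arr.ind = TRUE)
  out <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    dist2 <- (idxTrue[, 1] - i)^2 * sp[1]^2 + (idxTrue[, 2] - j)^2 * sp[2]^2 +
             (idxTrue[, 3] - k)^2 * sp[3]^2
    if (any(dist2 <= marginMm^2 + 1e-9)) out[i, j, k] <- TRUE
  }
  out
}

# a tiny evaluated-constraint result row, for reporting tests
mockResult <- function(patient, structure = "Heart", metric = "Dmax",
                       category = "C1", threshold = NA, limit = 34,
                       unit = "Gy", comparator = "<=", report_only = FALSE,
                       value_tx = 10, value_total = 10.1) {
  pass_tx <- if (report_only) NA else switch(comparator,
    "<=" = value_tx <= limit, "<" = value_tx < limit, ">" = value_tx > limit)
  pass_total <- if (report_only) NA else switch(comparator,
    "<=" = value_total <= limit, "<" = value_total < limit,
    ">" = value_total > limit)
  imTx <- if (value_tx == 0 && value_total == 0) 0
          else if (value_tx == 0) Inf
          else 100 * (value_total - value_tx) / value_tx
  data.frame(patient = patient, protocol = "RTOG0915",
             structure = structure,
             label = paste(structure, metric), category = category,
             metric = metric, threshold = threshold, limit = limit,
             unit = unit, comparator = comparator,
             report_only = report_only, evaluated = TRUE,
             value_tx = value_tx, value_total = value_total,
             pass_tx = pass_tx, pass_total = pass_total,
             flipped = !report_only && !is.na(pass_tx) &&
               pass_tx != pass_total,
             im_over_tx_pct = imTx,
             im_over_rx_pct = if (category == "C1")
               100 * (value_total - value_tx) / 48 else NA_real_,
             stringsAsFactors = FALSE)
}

# uniform-density water phantom spanning the whole grid
waterPhantom <- function(geometry) {
  DensityGrid(geometry, array(1, dim = geometry@dims),
              array("soft", dim = geometry@dims))
}

# one small pre-built case per test session (48 Gy/4 fr, moderate stress)
sharedCase <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- makePhantom(Prescription(48, 4), "upper", "left",
                            stress = 0.5, seed = 42)
    cache
  }
})
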