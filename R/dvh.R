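#' @include grids.R structures.R
NULL

# All dose/volume metrics are computed directly from sorted voxel doses, so
# DVH bin width never limits accuracy; binned cumulative DVHs are built only
# for export and plotting.

#' Cumulative dose-volume histogram
#'
#' `volumeCc[i]` is the structure volume receiving a dose of at least
#' `doseEdges[i]`; it is non-increasing, starts at the total structure volume
#' (every voxel receives >= 0 Gy) and ends at or above 0.
#'
#' @slot doseEdges increasing dose values, Gy
#' @slot volumeCc volume receiving >= that dose, cc
#' @slot totalVolumeCc structure volume, cc
#' @export
setClass("CumulativeDVH",
  representation(doseEdges = "numeric", volumeCc = "numeric",
                 totalVolumeCc = "numeric"))

setValidity("CumulativeDVH", function(object) {
  msg <- character()
  if (length(object@doseEdges) != length(object@volumeCc))
    msg <- c(msg, "doseEdges and volumeCc must have equal length")
  if (is.unsorted(object@doseEdges, strictly = TRUE))
    msg <- c(msg, "doseEdges must be strictly increasing")
  if (any(diff(object@volumeCc) > 1e-9))
    msg <- c(msg, "volumeCc must be non-increasing in dose")
  if (length(object@volumeCc) &&
      abs(object@volumeCc[1] - object@totalVolumeCc) > 1e-9)
    msg <- c(msg, "volumeCc must start at the total structure volume")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CumulativeDVH", function(object) {
  cat(sprintf("CumulativeDVH: %d edges over [0, %.3g] Gy, structure volume %.3g cc\n",
              length(object@doseEdges), max(object@doseEdges),
              object@totalVolumeCc))
})

# masked dose vector with error on empty mask
.maskedDoses <- function(dose, mask, structure = "structure") {
  if (is.null(mask) || !any(mask))
    stop(sprintf("empty mask for '%s': no voxels to evaluate", structure))
  dose@values[mask]
}

#' Build a cumulative DVH by exact voxel counting
#'
#' @param dose a [DoseGrid-class]
#' @param mask logical array on the same geometry; must be non-empty
#' @param binWidth dose bin width in Gy (default 0.01)
#' @return a [CumulativeDVH-class] with edges from 0 to max dose plus one bin
#' @rdname computeDVH
#' @export
setMethod("computeDVH", signature("DoseGrid", "ANY"),
  function(dose, mask, binWidth = 0.01) {
    stopifnot(binWidth > 0)
    d <- sort(.maskedDoses(dose, mask))
    vv <- voxelVolumeCc(dose@geometry)
    edges <- seq(0, max(d) + binWidth, by = binWidth)
    # count of doses >= edge = n - (count strictly below edge)
    vol <- (length(d) - findInterval(edges, d, left.open = TRUE)) * vv
    new("CumulativeDVH", doseEdges = edges, volumeCc = vol,
        totalVolumeCc = length(d) * vv)
  })

# Dose at cumulative (hottest-first) volume v, from a sorted-desc dose vector:
# accumulate voxel volumes, then interpolate linearly inside the voxel run
# that crosses v. v at or below one voxel volume returns the maximum dose.
.doseAtVolumeSorted <- function(dSorted, voxVolCc, v) {
  n <- length(dSorted)
  cum <- seq_len(n) * voxVolCc
  if (v <= 0) stop("volume must be > 0 cc")
  if (v > cum[n] + 1e-12) stop("volume exceeds the structure volume")
  if (v <= cum[1]) return(dSorted[1])
  stats::approx(cum, dSorted, xout = min(v, cum[n]), ties = "ordered")$y
}

#' Dose received by the hottest given volume (Dmax convention)
#'
#' `doseAtVolume(dose, mask, v)` is the smallest dose D such that the volume
#' receiving at least D equals `v` cc, by descending-sorted voxel
#' accumulation with linear interpolation inside the crossing voxel.
#' `v = 0.03` is the clinical "Dmax to 0.03 cc". `v` equal to the structure
#' volume gives the minimum structure dose. A method on
#' [CumulativeDVH-class] interpolates the binned cumulative curve instead
#' (export-grade, bin-limited).
#'
#' @param x a [DoseGrid-class] or a [CumulativeDVH-class]
#' @param mask logical array (DoseGrid method)
#' @param v volume in cc, 0 < v <= structure volume
#' @param ... unused
#' @return dose in Gy
#' @rdname doseAtVolume
#' @export
setMethod("doseAtVolume", "DoseGrid", function(x, mask, v, ...) {
  d <- sort(.maskedDoses(x, mask), decreasing = TRUE)
  .doseAtVolumeSorted(d, voxelVolumeCc(x@geometry), v)
})

#' @rdname doseAtVolume
#' @export
setMethod("doseAtVolume", "CumulativeDVH", function(x, v, ...) {
  if (v <= 0) stop("volume must be > 0 cc")
  if (v > x@totalVolumeCc + 1e-12) stop("volume exceeds the structure volume")
  vol <- x@volumeCc
  # smallest dose whose receiving volume equals v: walk the cumulative curve
  if (v >= vol[1]) return(x@doseEdges[1])
  i <- max(which(vol >= v))
  if (i == length(vol) || vol[i] == v) return(x@doseEdges[i])
  # linear interpolation between edges i and i+1
  x@doseEdges[i] + (vol[i] - v) / (vol[i] - vol[i + 1]) *
    (x@doseEdges[i + 1] - x@doseEdges[i])
})

#' Dose to the hottest p percent of a structure (D2% and friends)
#'
#' @inheritParams doseAtVolume
#' @param dose a [DoseGrid-class]
#' @param p percent of the structure volume, 0 < p <= 100; `p = 2` is D2%
#' @return dose in Gy
#' @export
doseAtVolumePct <- function(dose, mask, p) {
  stopifnot(p > 0, p <= 100)
  d <- sort(.maskedDoses(dose, mask), decreasing = TRUE)
  vv <- voxelVolumeCc(dose@geometry)
  .doseAtVolumeSorted(d, vv, p / 100 * length(d) * vv)
}

#' Mean structure dose
#' @inheritParams doseAtVolumePct
#' @return mean dose over masked voxels, Gy
#' @export
meanDose <- function(dose, mask) {
  mean(.maskedDoses(dose, mask))
}

#' Volume receiving at least a dose, in cc
#'
#' Clinical "volume receiving a dose higher than D". At voxel level the
#' default comparison is `>=`, which keeps the uniform-dose edge case (VD at
#' exactly D) non-pathological; `strict = TRUE` switches to `>`.
#'
#' @inheritParams doseAtVolumePct
#' @param D dose threshold, Gy, >= 0
#' @param strict use strictly-greater comparison
#' @return volume in cc (0 for an empty mask)
#' @export
volumeAboveCc <- function(dose, mask, D, strict = FALSE) {
  stopifnot(D >= 0)
  if (is.null(mask) || !any(mask)) return(0)
  d <- dose@values[mask]
  n <- if (strict) sum(d > D) else sum(d >= D)
  n * voxelVolumeCc(dose@geometry)
}

#' Volume receiving at least a dose, as percent of the structure
#' @inheritParams volumeAboveCc
#' @return percent of the structure volume
#' @export
volumeAbovePct <- function(dose, mask, D, strict = FALSE) {
  total <- volumeCc(mask, dose@geometry)
  if (total == 0) stop("empty mask: percent volume undefined")
  100 * volumeAboveCc(dose, mask, D, strict) / total
}

#' PTV coverage: percent of the PTV receiving a percent of the prescription
#'
#' `ptvCoveragePct(dose, ptv, rx, 90)` is the PTV V90%: the percent of the
#' PTV volume receiving at least 90% of the prescription dose.
#'
#' @inheritParams volumeAbovePct
#' @param rx prescription dose, Gy, > 0
#' @param pctOfRx percent of the prescription defining the threshold, in
#'   (0, 100]
#' @export
ptvCoveragePct <- function(dose, mask, rx, pctOfRx = 90, strict = FALSE) {
  stopifnot(rx > 0, pctOfRx > 0, pctOfRx <= 100)
  volumeAbovePct(dose, mask, pctOfRx / 100 * rx, strict)
}

#' Write a DVH as two-column plain text
#'
#' @param dvh a [CumulativeDVH-class]
#' @param file path
#' @export
writeDVH <- function(dvh, file) {
  utils::write.table(
    data.frame(dose_gy = dvh@doseEdges, volume_cc = dvh@volumeCc),
    file, sep = "\t", row.names = FALSE, quote = FALSE)
}
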