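#' @include AllGenerics.R
NULL

# ---- GridGeometry -----------------------------------------------------------

#' Regular-grid geometry
#'
#' Describes a regular 3D voxel grid in a fixed patient frame: x points to
#' patient-left, y to patient-posterior, z to patient-superior, all in mm.
#' `origin` is the position of the *centre* of voxel (1,1,1) (0-based index
#' (0,0,0)); `spacing` the per-axis voxel edge lengths; `dims` the per-axis
#' voxel counts. Arrays on the grid use R's native layout (x fastest).
#'
#' @slot origin numeric(3), mm
#' @slot spacing numeric(3), mm, all > 0
#' @slot dims integer(3), all >= 1
#' @export
setClass("GridGeometry",
  representation(origin = "numeric", spacing = "numeric", dims = "integer"))

setValidity("GridGeometry", function(object) {
  msg <- character()
  if (length(object@origin) != 3L || !all(is.finite(object@origin)))
    msg <- c(msg, "'origin' must be 3 finite numbers (mm)")
  if (length(object@spacing) != 3L || !all(is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive numbers (mm)")
  if (length(object@dims) != 3L || any(is.na(object@dims)) ||
      any(object@dims < 1L))
    msg <- c(msg, "'dims' must be 3 integers >= 1")
  if (length(msg)) msg else TRUE
})

#' @param origin,spacing,dims see slots
#' @rdname GridGeometry-class
#' @export
GridGeometry <- function(origin, spacing, dims) {
  new("GridGeometry", origin = as.numeric(origin),
      spacing = as.numeric(spacing), dims = as.integer(dims))
}

setMethod("show", "GridGeometry", function(object) {
  cat(sprintf("GridGeometry: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              object@dims[1], object@dims[2], object@dims[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  cat(sprintf("  origin (%.1f, %.1f, %.1f) mm  [x: left, y: posterior, z: superior]\n",
              object@origin[1], object@origin[2], object@origin[3]))
})

#' @rdname GridGeometry-class
#' @param x,object a `GridGeometry`
#' @param axis 1, 2 or 3
#' @export
axisCoords <- function(x, axis) {
  x@origin[axis] + (seq_len(x@dims[axis]) - 1) * x@spacing[axis]
}

#' Voxel volume in mm^3 / cc
#' @rdname GridGeometry-class
#' @export
voxelVolumeMm3 <- function(x) prod(x@spacing)

#' @rdname GridGeometry-class
#' @export
voxelVolumeCc <- function(x) prod(x@spacing) / 1000

#' Coordinates of every voxel centre
#'
#' @return a list with components `x`, `y`, `z`, each a vector of length
#'   `prod(dims)` in array order (x fastest).
#' @rdname GridGeometry-class
#' @export
voxelCoords <- function(x) {
  d <- x@dims
  list(
    x = rep(axisCoords(x, 1), times = d[2] * d[3]),
    y = rep(rep(axisCoords(x, 2), each = d[1]), times = d[3]),
    z = rep(axisCoords(x, 3), each = d[1] * d[2])
  )
}

#' Do two geometries coincide?
#' @param a,b `GridGeometry` objects
#' @param tol absolute tolerance, mm
#' @rdname GridGeometry-class
#' @export
sameGeometry <- function(a, b, tol = 1e-6) {
  all(a@dims == b@dims) &&
    all(abs(a@origin - b@origin) < tol) &&
    all(abs(a@spacing - b@spacing) < tol)
}

.describeGeometry <- function(g) {
  sprintf("[%dx%dx%d @ (%.2f,%.2f,%.2f) mm, spacing (%.2f,%.2f,%.2f) mm]",
          g@dims[1], g@dims[2], g@dims[3], g@origin[1], g@origin[2],
          g@origin[3], g@spacing[1], g@spacing[2], g@spacing[3])
}

# ---- DoseGrid ---------------------------------------------------------------

#' Absorbed-dose scalar field
#'
#' A 3D field of absorbed dose (Gy) on a [GridGeometry-class]. Values must be
#' finite and non-negative. Holds treatment dose (Tx), imaging dose (Im) or
#' their sum (Tx + Im) interchangeably.
#'
#' @slot geometry a [GridGeometry-class]
#' @slot values 3D numeric array matching `dims`, Gy
#' @export
setClass("DoseGrid",
  representation(geometry = "GridGeometry", values = "array"))

setValidity("DoseGrid", function(object) {
  msg <- character()
  if (!identical(dim(object@values), as.integer(object@geometry@dims)))
    msg <- c(msg, "value array shape must match geometry dims")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "dose values must be finite")
  else if (any(object@values < 0))
    msg <- c(msg, "dose values must be >= 0 Gy")
  if (length(msg)) msg else TRUE
})

#' @param geometry a [GridGeometry-class]
#' @param values array matching `dims`, or a scalar to fill with
#' @rdname DoseGrid-class
#' @export
DoseGrid <- function(geometry, values = 0) {
  if (length(values) == 1L)
    values <- array(as.numeric(values), dim = geometry@dims)
  else
    values <- array(as.numeric(values), dim = geometry@dims)
  new("DoseGrid", geometry = geometry, values = values)
}

setMethod("show", "DoseGrid", function(object) {
  cat("DoseGrid\n")
  show(object@geometry)
  v <- object@values
  cat(sprintf("  dose range [%.4g, %.4g] Gy, mean %.4g Gy\n",
              min(v), max(v), mean(v)))
})

#' @rdname geometry
#' @export
setMethod("geometry", "DoseGrid", function(x) x@geometry)

#' @rdname geometry
#' @export
setMethod("doseValues", "DoseGrid", function(x) x@values)

# ---- DensityGrid ------------------------------------------------------------

#' Material classes used by the density model
#' @export
MATERIAL_LEVELS <- c("air", "lung", "soft", "bone")

#' Mass-density field with material labels
#'
#' Relative (to water) mass density on a [GridGeometry-class], with a
#' per-voxel material class out of air/lung/soft/bone. The density drives
#' radiological path lengths in the kV surrogate; the material label drives
#' the bone dose-enhancement factor.
#'
#' @slot geometry a [GridGeometry-class]
#' @slot values 3D numeric array, relative density >= 0
#' @slot materials 3D integer array, codes indexing [MATERIAL_LEVELS]
#' @export
setClass("DensityGrid",
  representation(geometry = "GridGeometry", values = "array",
                 materials = "array"))

setValidity("DensityGrid", function(object) {
  msg <- character()
  if (!identical(dim(object@values), as.integer(object@geometry@dims)))
    msg <- c(msg, "density array shape must match geometry dims")
  if (anyNA(object@values) || any(object@values < 0))
    msg <- c(msg, "densities must be finite and >= 0")
  if (!identical(dim(object@materials), as.integer(object@geometry@dims)))
    msg <- c(msg, "material array shape must match geometry dims")
  else if (!all(object@materials %in% seq_along(MATERIAL_LEVELS)))
    msg <- c(msg, "material codes must index MATERIAL_LEVELS")
  if (length(msg)) msg else TRUE
})

#' @param geometry,values,materials see slots; `materials` may be a character
#'   array of level names or an integer code array
#' @rdname DensityGrid-class
#' @export
DensityGrid <- function(geometry, values, materials) {
  if (is.character(materials)) {
    m <- match(materials, MATERIAL_LEVELS)
    materials <- array(as.integer(m), dim = geometry@dims)
  }
  new("DensityGrid", geometry = geometry,
      values = array(as.numeric(values), dim = geometry@dims),
      materials = array(as.integer(materials), dim = geometry@dims))
}

setMethod("show", "DensityGrid", function(object) {
  cat("DensityGrid\n")
  show(object@geometry)
  tab <- table(factor(MATERIAL_LEVELS[object@materials],
                      levels = MATERIAL_LEVELS))
  cat("  material voxels:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

#' @rdname geometry
#' @export
setMethod("geometry", "DensityGrid", function(x) x@geometry)

#' Material label array of a density grid
#' @param x a [DensityGrid-class]
#' @return character array of material names
#' @export
materialLabels <- function(x) {
  array(MATERIAL_LEVELS[x@materials], dim = x@geometry@dims)
}

# ---- voxelwise algebra ------------------------------------------------------

#' Voxelwise dose accumulation
#'
#' `addDose(a, b)` sums two dose grids voxelwise; both must share one
#' geometry (resample first with [resampleTo()]). `scaleDose(a, k)` scales by
#' a non-negative factor (per-image dose times image count, mAs rescaling).
#' The `+` and `*` operators are available as shorthand.
#'
#' @param a,b [DoseGrid-class] objects on identical geometry
#' @param k scalar factor >= 0
#' @return a [DoseGrid-class]
#' @export
addDose <- function(a, b) {
  if (!sameGeometry(a@geometry, b@geometry))
    stop("dose grids have different geometries: ",
         .describeGeometry(a@geometry), " vs ", .describeGeometry(b@geometry))
  new("DoseGrid", geometry = a@geometry, values = a@values + b@values)
}

#' @rdname addDose
#' @export
scaleDose <- function(a, k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0)
    stop("scale factor must be a single finite number >= 0")
  new("DoseGrid", geometry = a@geometry, values = a@values * k)
}

#' @rdname addDose
#' @param e1,e2 operands
#' @export
setMethod("+", signature("DoseGrid", "DoseGrid"),
          function(e1, e2) addDose(e1, e2))

#' @rdname addDose
#' @export
setMethod("*", signature("DoseGrid", "numeric"),
          function(e1, e2) scaleDose(e1, e2))

#' @rdname addDose
#' @export
setMethod("*", signature("numeric", "DoseGrid"),
          function(e1, e2) scaleDose(e2, e1))

# ---- trilinear interpolation ------------------------------------------------

# Trilinear sample of a 3D array at continuous 0-based voxel coordinates.
# Out-of-support points (outside the voxel-centre hull) return `outside`.
.trilinearSample <- function(values, dims, fx, fy, fz, outside = 0) {
  inside <- fx >= 0 & fx <= dims[1] - 1 &
            fy >= 0 & fy <= dims[2] - 1 &
            fz >= 0 & fz <= dims[3] - 1
  out <- rep(outside, length(fx))
  if (!any(inside)) return(out)
  fx <- fx[inside]; fy <- fy[inside]; fz <- fz[inside]
  i0 <- pmin(floor(fx), dims[1] - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(fy), dims[2] - 2); j0 <- pmax(j0, 0)
  k0 <- pmin(floor(fz), dims[3] - 2); k0 <- pmax(k0, 0)
  # degenerate axes (a single voxel along an axis): collapse the weight
  if (dims[1] == 1L) i0 <- rep(0, length(fx))
  if (dims[2] == 1L) j0 <- rep(0, length(fy))
  if (dims[3] == 1L) k0 <- rep(0, length(fz))
  wx <- if (dims[1] == 1L) rep(0, length(fx)) else fx - i0
  wy <- if (dims[2] == 1L) rep(0, length(fy)) else fy - j0
  wz <- if (dims[3] == 1L) rep(0, length(fz)) else fz - k0
  nx <- dims[1]; nxy <- dims[1] * dims[2]
  i1 <- pmin(i0 + 1, dims[1] - 1)
  j1 <- pmin(j0 + 1, dims[2] - 1)
  k1 <- pmin(k0 + 1, dims[3] - 1)
  idx <- function(i, j, k) 1 + i + nx * j + nxy * k
  v <- (1 - wx) * (1 - wy) * (1 - wz) * values[idx(i0, j0, k0)] +
       wx       * (1 - wy) * (1 - wz) * values[idx(i1, j0, k0)] +
       (1 - wx) * wy       * (1 - wz) * values[idx(i0, j1, k0)] +
       wx       * wy       * (1 - wz) * values[idx(i1, j1, k0)] +
       (1 - wx) * (1 - wy) * wz       * values[idx(i0, j0, k1)] +
       wx       * (1 - wy) * wz       * values[idx(i1, j0, k1)] +
       (1 - wx) * wy       * wz       * values[idx(i0, j1, k1)] +
       wx       * wy       * wz       * values[idx(i1, j1, k1)]
  out[inside] <- v
  out
}

# Sample a DoseGrid at arbitrary patient coordinates (mm).
.sampleDoseAt <- function(grid, px, py, pz, outside = 0) {
  g <- grid@geometry
  .trilinearSample(grid@values, g@dims,
                   (px - g@origin[1]) / g@spacing[1],
                   (py - g@origin[2]) / g@spacing[2],
                   (pz - g@origin[3]) / g@spacing[3],
                   outside = outside)
}

#' @rdname resampleTo
#' @export
setMethod("resampleTo", signature("DoseGrid", "GridGeometry"),
  function(x, target) {
    if (anyNA(x@values) || any(!is.finite(x@values)))
      stop("source dose grid contains non-finite values")
    if (sameGeometry(x@geometry, target)) return(x)
    p <- voxelCoords(target)
    v <- .sampleDoseAt(x, p$x, p$y, p$z, outside = 0)
    new("DoseGrid", geometry = target,
        values = array(v, dim = target@dims))
  })
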