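#' Resample a dose grid onto a target geometry
#'
#' Trilinear interpolation of the source grid at every voxel centre of the
#' target geometry. Points outside the support of the source grid (i.e.
#' beyond the outermost voxel centres) map to 0 Gy, reflecting that dose
#' outside the computed extent is negligible.
#'
#' @param x a [DoseGrid-class]
#' @param target a [GridGeometry-class]
#' @return a [DoseGrid-class] on `target`
#' @export
setGeneric("resampleTo", function(x, target) standardGeneric("resampleTo"))

#' @rdname computeDVH
#' @export
setGeneric("computeDVH", function(dose, mask, binWidth = 0.01)
  standardGeneric("computeDVH"))

#' @rdname doseAtVolume
#' @export
setGeneric("doseAtVolume", function(x, ...) standardGeneric("doseAtVolume"))

#' Grid accessors
#'
#' @param x an object carrying a [GridGeometry-class]
#' @return `geometry()` returns the [GridGeometry-class]; `doseValues()` the
#'   3D array of voxel values.
#' @aliases doseValues
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname geometry
#' @export
setGeneric("doseValues", function(x) standardGeneric("doseValues"))
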