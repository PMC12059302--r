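#' @include grids.R
NULL

# ---- Structure / StructureSet ----------------------------------------------

#' Anatomical structure
#'
#' A named anatomical region given as per-slice closed polygons (mm, in the
#' patient frame) and/or a boolean voxel mask on a host geometry. Roles follow
#' planning usage: `"PTV"` for the target, `"OAR"` for constrained organs,
#' `"support"` for anything else (ITV, couch, ...).
#'
#' @slot name character label, e.g. "Lt Lung", "Spinal Cord PRV", "Bone"
#' @slot role one of "PTV", "OAR", "support"
#' @slot contours list of `list(z = <mm>, xy = <n x 2 matrix, mm>)` closed
#'   planar polygons (the closing edge last-to-first point is implicit), or
#'   an empty list
#' @slot mask logical 3D array on the host geometry, or a 0-length logical
#' @export
setClass("Structure",
  representation(name = "character", role = "character",
                 contours = "list", mask = "logical"))

setValidity("Structure", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a non-empty string")
  if (length(object@role) != 1L ||
      !object@role %in% c("PTV", "OAR", "support"))
    msg <- c(msg, "'role' must be one of PTV, OAR, support")
  if (length(object@contours) == 0L && length(object@mask) == 0L)
    msg <- c(msg, "at least one of contours/mask must be present")
  if (length(msg)) msg else TRUE
})

#' @param name,role,contours,mask see slots
#' @rdname Structure-class
#' @export
Structure <- function(name, role = "OAR", contours = list(), mask = logical(0)) {
  new("Structure", name = name, role = role, contours = contours,
      mask = as.logical(mask))
}

setMethod("show", "Structure", function(object) {
  cat(sprintf("Structure \"%s\" (%s): %d contour(s), %s\n",
              object@name, object@role, length(object@contours),
              if (length(object@mask)) sprintf("mask with %d voxels on",
                                               sum(object@mask)) else "no mask"))
})

#' Set of anatomical structures on one grid frame
#'
#' @slot structures named list of [Structure-class] objects
#' @slot frame the [GridGeometry-class] shared by all masks
#' @export
setClass("StructureSet",
  representation(structures = "list", frame = "GridGeometry"))

setValidity("StructureSet", function(object) {
  msg <- character()
  nm <- names(object@structures)
  if (length(object@structures) &&
      (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm))))
    msg <- c(msg, "structures must be uniquely named")
  nv <- prod(object@frame@dims)
  for (s in object@structures) {
    if (!is(s, "Structure")) { msg <- c(msg, "all elements must be Structure"); break }
    if (length(s@mask) && length(s@mask) != nv) {
      msg <- c(msg, sprintf("mask of '%s' does not match the frame", s@name))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @param structures list of [Structure-class] (named or not; names default to
#'   the structure names)
#' @param frame shared [GridGeometry-class]
#' @rdname StructureSet-class
#' @export
StructureSet <- function(structures = list(), frame) {
  if (is.null(names(structures)) && length(structures))
    names(structures) <- vapply(structures, function(s) s@name, character(1))
  new("StructureSet", structures = structures, frame = frame)
}

setMethod("show", "StructureSet", function(object) {
  cat(sprintf("StructureSet with %d structure(s) on ", length(object@structures)))
  show(object@frame)
  if (length(object@structures))
    cat("  ", paste(names(object@structures), collapse = ", "), "\n")
})

#' @rdname StructureSet-class
#' @param x a `StructureSet`
#' @export
structureNames <- function(x) names(x@structures)

#' Look up a structure, optionally through an alias table
#'
#' @param x a [StructureSet-class]
#' @param name requested name
#' @param aliases named character vector mapping variant names to the names
#'   used in `x` (applied when `name` itself is absent)
#' @return the [Structure-class], or `NULL` when unresolved
#' @export
getStructure <- function(x, name, aliases = NULL) {
  if (name %in% names(x@structures)) return(x@structures[[name]])
  if (!is.null(aliases) && name %in% names(aliases)) {
    tr <- aliases[[name]]
    if (tr %in% names(x@structures)) return(x@structures[[tr]])
  }
  NULL
}

#' Boolean mask of a structure on the set's frame
#'
#' Returns the stored mask, rasterizing the contours on the frame when only
#' contours are present.
#'
#' @inheritParams getStructure
#' @return logical 3D array, or `NULL` when the structure is unresolved
#' @export
structureMask <- function(x, name, aliases = NULL) {
  s <- getStructure(x, name, aliases)
  if (is.null(s)) return(NULL)
  if (length(s@mask)) return(array(s@mask, dim = x@frame@dims))
  rasterizeContours(s@contours, x@frame)
}

# ---- rasterization ----------------------------------------------------------

# Even-odd point-in-polygon, vectorized over points. Standard crossing test.
.pointsInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  xj <- poly[n, 1]; yj <- poly[n, 2]
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    if (yi != yj) {
      cross <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
    }
    xj <- xi; yj <- yi
  }
  inside
}

# Do any two (non-adjacent) polygon edges properly intersect?
.selfIntersects <- function(poly) {
  n <- nrow(poly)
  if (n < 4) return(FALSE)
  seg <- cbind(poly, poly[c(2:n, 1), ])
  cross2 <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    js <- js[!(i == 1 & js == n)]
    if (!length(js)) next
    d1 <- cross2(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[js, 1], seg[js, 2])
    d2 <- cross2(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[js, 3], seg[js, 4])
    d3 <- cross2(seg[js, 1], seg[js, 2], seg[js, 3], seg[js, 4],
                 rep(seg[i, 1], length(js)), rep(seg[i, 2], length(js)))
    d4 <- cross2(seg[js, 1], seg[js, 2], seg[js, 3], seg[js, 4],
                 rep(seg[i, 3], length(js)), rep(seg[i, 4], length(js)))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Rasterize planar contours to a voxel mask
#'
#' A voxel is inside iff its centre is inside the polygon(s) of the slice it
#' falls on, under the even-odd rule; nested polygons therefore carve holes.
#' Contours must lie on planes matching grid slices to within half a slice
#' spacing. Self-intersecting polygons are accepted with a warning (the
#' even-odd result is still well defined). An empty contour list yields an
#' empty mask.
#'
#' @param contours list of `list(z =, xy =)` closed polygons (mm)
#' @param target a [GridGeometry-class]
#' @return logical 3D array on `target`
#' @export
rasterizeContours <- function(contours, target) {
  mask <- array(FALSE, dim = target@dims)
  if (!length(contours)) return(mask)
  zc <- axisCoords(target, 3)
  xs <- axisCoords(target, 1)
  ys <- axisCoords(target, 2)
  for (ct in contours) {
    poly <- ct$xy
    if (is.null(dim(poly)) || nrow(poly) < 3) next
    # drop an explicit closing point
    if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
    k <- which.min(abs(zc - ct$z))
    if (abs(zc[k] - ct$z) > target@spacing[3] / 2 + 1e-9)
      stop(sprintf("contour plane z = %.2f mm does not match any grid slice", ct$z))
    if (.selfIntersects(poly))
      warning("self-intersecting polygon rasterized under the even-odd rule")
    # restrict the inclusion test to the polygon's bounding box
    ix <- which(xs >= min(poly[, 1]) - 1e-9 & xs <= max(poly[, 1]) + 1e-9)
    iy <- which(ys >= min(poly[, 2]) - 1e-9 & ys <= max(poly[, 2]) + 1e-9)
    if (!length(ix) || !length(iy)) next
    px <- rep(xs[ix], times = length(iy))
    py <- rep(ys[iy], each = length(ix))
    inside <- .pointsInPolygon(px, py, poly)
    slice <- mask[, , k]
    sub <- slice[ix, iy]
    slice[ix, iy] <- xor(sub, matrix(inside, nrow = length(ix)))
    mask[, , k] <- slice
  }
  mask
}

# ---- margin expansion -------------------------------------------------------

#' Isotropic margin expansion (PTV/PRV construction)
#'
#' Morphological dilation with a Euclidean ball: an output voxel is true iff
#' its centre lies within `marginMm` of the centre of any true input voxel.
#' Anisotropic spacing is respected; `marginMm = 0` is the identity. This is
#' the 5 mm expansion used to build the PTV from the ITV and the planning
#' organ-at-risk volumes (PRV) from trachea, esophagus and spinal cord.
#'
#' @param mask logical 3D array
#' @param geometry the [GridGeometry-class] the mask lives on
#' @param marginMm margin in mm, >= 0
#' @return logical 3D array
#' @export
expandMargin <- function(mask, geometry, marginMm) {
  stopifnot(marginMm >= 0)
  if (marginMm == 0 || !any(mask)) return(mask)
  sp <- geometry@spacing
  rr <- ceiling(marginMm / sp)
  offs <- expand.grid(dx = -rr[1]:rr[1], dy = -rr[2]:rr[2], dz = -rr[3]:rr[3])
  d2 <- (offs$dx * sp[1])^2 + (offs$dy * sp[2])^2 + (offs$dz * sp[3])^2
  offs <- offs[d2 <= marginMm^2 + 1e-9, , drop = FALSE]
  d <- dim(mask)
  # dilate inside the padded bounding box of the input only
  w <- which(mask) - 1L
  ix <- w %% d[1]; iy <- (w %/% d[1]) %% d[2]; iz <- w %/% (d[1] * d[2])
  b1 <- pmax(c(min(ix), min(iy), min(iz)) + 1L - rr, 1L)
  b2 <- pmin(c(max(ix), max(iy), max(iz)) + 1L + rr, d)
  sub <- mask[b1[1]:b2[1], b1[2]:b2[2], b1[3]:b2[3], drop = FALSE]
  ds <- dim(sub)
  outSub <- array(FALSE, dim = ds)
  for (r in seq_len(nrow(offs))) {
    dx <- offs$dx[r]; dy <- offs$dy[r]; dz <- offs$dz[r]
    sx <- max(1, 1 + dx):min(ds[1], ds[1] + dx)
    sy <- max(1, 1 + dy):min(ds[2], ds[2] + dy)
    sz <- max(1, 1 + dz):min(ds[3], ds[3] + dz)
    outSub[sx, sy, sz] <- outSub[sx, sy, sz] | sub[sx - dx, sy - dy, sz - dz]
  }
  out <- array(FALSE, dim = d)
  out[b1[1]:b2[1], b1[2]:b2[2], b1[3]:b2[3]] <- outSub
  out
}

#' Volume of a mask in cc
#'
#' Count of true voxels times the voxel volume (1 cc = 1000 mm^3).
#'
#' @inheritParams expandMargin
#' @return volume in cc
#' @export
volumeCc <- function(mask, geometry) {
  sum(mask) * voxelVolumeMm3(geometry) / 1000
}
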