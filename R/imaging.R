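#' @include grids.R
NULL

# ---- kV hardware ------------------------------------------------------------

#' kV imaging tube
#'
#' One of the two floor-mounted x-ray tubes of a stereoscopic room-mounted
#' tumour-monitoring system. Tubes sit posterior-oblique below the couch, so
#' their beams enter through the patient's back; each is aimed at the imaging
#' isocenter and illuminates a divergent cone.
#'
#' @slot id "A" or "B"
#' @slot sourcePosition tube focal spot, mm, patient frame
#' @slot axisTarget point the central axis is aimed at (the isocenter), mm
#' @slot fieldHalfAngle half-opening angle of the cone, degrees
#' @export
setClass("KvTube",
  representation(id = "character", sourcePosition = "numeric",
                 axisTarget = "numeric", fieldHalfAngle = "numeric"))

setValidity("KvTube", function(object) {
  msg <- character()
  if (!object@id %in% c("A", "B"))
    msg <- c(msg, "'id' must be \"A\" or \"B\"")
  if (length(object@sourcePosition) != 3L ||
      !all(is.finite(object@sourcePosition)))
    msg <- c(msg, "'sourcePosition' must be 3 finite numbers (mm)")
  if (length(object@axisTarget) != 3L || !all(is.finite(object@axisTarget)))
    msg <- c(msg, "'axisTarget' must be 3 finite numbers (mm)")
  if (all(object@axisTarget == object@sourcePosition))
    msg <- c(msg, "axis target must differ from the source position")
  if (length(object@fieldHalfAngle) != 1L || object@fieldHalfAngle <= 0 ||
      object@fieldHalfAngle >= 90)
    msg <- c(msg, "'fieldHalfAngle' must be in (0, 90) degrees")
  if (length(msg)) msg else TRUE
})

#' @param id,sourcePosition,axisTarget,fieldHalfAngle see slots
#' @rdname KvTube-class
#' @export
KvTube <- function(id, sourcePosition, axisTarget = c(0, 0, 0),
                   fieldHalfAngle = 8) {
  new("KvTube", id = id, sourcePosition = as.numeric(sourcePosition),
      axisTarget = as.numeric(axisTarget),
      fieldHalfAngle = as.numeric(fieldHalfAngle))
}

#' Central axis unit vector of a tube
#' @param tube a [KvTube-class]
#' @export
tubeAxis <- function(tube) {
  v <- tube@axisTarget - tube@sourcePosition
  v / sqrt(sum(v^2))
}

#' Default posterior-oblique tube pair
#'
#' Floor-mounted sources posterior-inferior to the patient, laterally
#' symmetric, aimed at the isocenter.
#'
#' @param isocenter aim point, mm (typically the tumour centre)
#' @param fieldHalfAngle cone half-angle, degrees
#' @return list of two [KvTube-class] objects
#' @export
defaultTubes <- function(isocenter = c(0, 0, 0), fieldHalfAngle = 8) {
  list(
    A = KvTube("A", isocenter + c(-700, 900, -350), isocenter, fieldHalfAngle),
    B = KvTube("B", isocenter + c(700, 900, -350), isocenter, fieldHalfAngle)
  )
}

#' kV imaging technique
#'
#' Acquisition settings and the beam-quality parameters of the analytic
#' primary-beam dose model. `airKermaRef` is the water-surface dose per mAs
#' at `refDistMm` from the source; `muWater` the effective linear attenuation
#' coefficient of water at this tube potential; `boneFactor` the dose
#' enhancement of bone relative to soft tissue at equal fluence (about 4 at
#' kV energies, driven by the photoelectric cross-section of calcium).
#'
#' @slot kvp tube potential, kV
#' @slot masPerImage tube charge per image, mAs
#' @slot muWater effective linear attenuation coefficient in water, 1/mm
#' @slot boneFactor bone-to-soft dose ratio at equal fluence, >= 1
#' @slot airKermaRef reference surface dose, Gy per mAs at `refDistMm`
#' @slot refDistMm reference distance, mm
#' @export
setClass("ImagingTechnique",
  representation(kvp = "numeric", masPerImage = "numeric",
                 muWater = "numeric", boneFactor = "numeric",
                 airKermaRef = "numeric", refDistMm = "numeric"))

setValidity("ImagingTechnique", function(object) {
  vals <- c(object@kvp, object@masPerImage, object@muWater,
            object@boneFactor, object@airKermaRef, object@refDistMm)
  msg <- character()
  if (length(vals) != 6L || any(!is.finite(vals)) || any(vals <= 0))
    msg <- c(msg, "all technique parameters must be single positive numbers")
  if (length(object@boneFactor) == 1L && object@boneFactor < 1)
    msg <- c(msg, "'boneFactor' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param kvp,masPerImage,muWater,boneFactor,airKermaRef,refDistMm see slots
#' @rdname ImagingTechnique-class
#' @export
ImagingTechnique <- function(kvp, masPerImage, muWater, boneFactor = 4,
                             airKermaRef = 2e-05, refDistMm = 1000) {
  new("ImagingTechnique", kvp = as.numeric(kvp),
      masPerImage = as.numeric(masPerImage), muWater = as.numeric(muWater),
      boneFactor = as.numeric(boneFactor),
      airKermaRef = as.numeric(airKermaRef),
      refDistMm = as.numeric(refDistMm))
}

#' Patient-size-dependent technique lookup
#'
#' Vendor-style automatic technique selection: the water-equivalent lateral
#' thickness of the patient picks one of three (kVp, mAs) rows; the matching
#' effective attenuation coefficient tracks beam hardening with kVp.
#'
#' @param wetMm water-equivalent lateral thickness through the isocenter, mm
#' @param table data.frame with columns `max_wet_mm`, `kvp`, `mas`, `mu_water`
#'   (rows ordered by `max_wet_mm`; the last row catches everything)
#' @param boneFactor,airKermaRef,refDistMm passed through
#' @return an [ImagingTechnique-class]
#' @export
techniqueForSize <- function(wetMm,
                             table = defaultTechniqueTable(),
                             boneFactor = 4, airKermaRef = 2e-05,
                             refDistMm = 1000) {
  i <- which(wetMm <= table$max_wet_mm)[1]
  if (is.na(i)) i <- nrow(table)
  ImagingTechnique(table$kvp[i], table$mas[i], table$mu_water[i],
                   boneFactor, airKermaRef, refDistMm)
}

#' @rdname techniqueForSize
#' @export
defaultTechniqueTable <- function() {
  data.frame(
    size = c("small", "medium", "large"),
    max_wet_mm = c(110, 135, Inf),
    kvp = c(110, 120, 130),
    mas = c(10, 16, 25),
    mu_water = c(0.0235, 0.0223, 0.0212)
  )
}

#' Water-equivalent lateral thickness through a point
#'
#' Line integral of relative density along the lateral (x) axis through the
#' given point, by trilinear sampling at 1 mm steps.
#'
#' @param density a [DensityGrid-class]
#' @param at point the lateral ray passes through, mm (default isocenter)
#' @return thickness in mm of water
#' @export
waterEquivalentThickness <- function(density, at = c(0, 0, 0)) {
  g <- density@geometry
  xs <- seq(g@origin[1], g@origin[1] + (g@dims[1] - 1) * g@spacing[1], by = 1)
  rho <- .trilinearSample(density@values, g@dims,
                         (xs - g@origin[1]) / g@spacing[1],
                         rep((at[2] - g@origin[2]) / g@spacing[2], length(xs)),
                         rep((at[3] - g@origin[3]) / g@spacing[3], length(xs)))
  sum(rho) * 1
}

# ---- VMAT arcs and the imaging schedule -------------------------------------

#' VMAT arc
#'
#' One volumetric-arc delivery: gantry sweep on the IEC scale (0 degrees =
#' beam from anterior), rotation sense, and delivery time. Gantry motion is
#' taken as uniform in time across the arc. Equal start and stop angles
#' denote a full 360-degree arc.
#'
#' @slot gantryStart,gantryStop degrees in [0, 360)
#' @slot direction "CW" (increasing angle) or "CCW"
#' @slot deliveryTime seconds, > 0
#' @export
setClass("VmatArc",
  representation(gantryStart = "numeric", gantryStop = "numeric",
                 direction = "character", deliveryTime = "numeric"))

setValidity("VmatArc", function(object) {
  msg <- character()
  if (!object@direction %in% c("CW", "CCW"))
    msg <- c(msg, "'direction' must be CW or CCW")
  if (object@deliveryTime <= 0)
    msg <- c(msg, "'deliveryTime' must be > 0 s")
  if (length(msg)) msg else TRUE
})

#' @param gantryStart,gantryStop,direction,deliveryTime see slots
#' @rdname VmatArc-class
#' @export
VmatArc <- function(gantryStart, gantryStop, direction = "CW",
                    deliveryTime = 120) {
  new("VmatArc", gantryStart = gantryStart %% 360,
      gantryStop = gantryStop %% 360, direction = direction,
      deliveryTime = as.numeric(deliveryTime))
}

#' Angular span of an arc, degrees (360 for a full arc)
#' @param arc a [VmatArc-class]
#' @export
arcSpan <- function(arc) {
  s <- if (arc@direction == "CW") (arc@gantryStop - arc@gantryStart) %% 360
       else (arc@gantryStart - arc@gantryStop) %% 360
  if (s == 0) 360 else s
}

#' Stereoscopic/monoscopic imaging schedule
#'
#' The partition of one arc's delivery time into intervals during which both
#' tubes see the target (stereo), exactly one does (mono; the other is
#' blocked by the rotating gantry), or neither does (mono with no active
#' tube, contributing no dose).
#'
#' @slot intervals data.frame with columns `duration` (s), `mode`
#'   ("stereo"/"mono"), `tubeA`, `tubeB` (logical: tube active)
#' @slot frequency imaging frequency, images/s
#' @export
setClass("ImagingSchedule",
  representation(intervals = "data.frame", frequency = "numeric"))

setValidity("ImagingSchedule", function(object) {
  msg <- character()
  need <- c("duration", "mode", "tubeA", "tubeB")
  if (!all(need %in% names(object@intervals)))
    msg <- c(msg, "intervals must have duration/mode/tubeA/tubeB columns")
  else {
    iv <- object@intervals
    if (any(iv$duration < 0)) msg <- c(msg, "durations must be >= 0")
    nAct <- iv$tubeA + iv$tubeB
    if (any(iv$mode == "stereo" & nAct != 2L))
      msg <- c(msg, "stereo intervals must have both tubes active")
    if (any(iv$mode == "mono" & nAct > 1L))
      msg <- c(msg, "mono intervals must have at most one tube active")
  }
  if (object@frequency <= 0) msg <- c(msg, "'frequency' must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ImagingSchedule", function(object) {
  iv <- object@intervals
  cat(sprintf(
    "ImagingSchedule: %d interval(s), %.1f s total (%.1f s stereo), %.2f Hz\n",
    nrow(iv), sum(iv$duration), sum(iv$duration[iv$mode == "stereo"]),
    object@frequency))
})

.inAngularRange <- function(a, range) {
  lo <- range[1] %% 360; hi <- range[2] %% 360
  a <- a %% 360
  if (lo <= hi) a >= lo & a <= hi else a >= lo | a <= hi
}

#' Partition a VMAT arc into stereoscopic and monoscopic periods
#'
#' While the gantry head sweeps through a tube's blocked angular range, that
#' tube's view is obstructed and imaging falls back to the other tube
#' (monoscopic). The arc's sweep is split at every blocked-range boundary;
#' each piece is labelled by which tubes remain unblocked. Gantry speed is
#' assumed constant, so durations are proportional to angular extent.
#'
#' @param arc a [VmatArc-class]
#' @param blockedRanges named list `list(A = c(lo, hi), B = c(lo, hi))` of
#'   gantry-angle intervals (degrees, may wrap through 0) during which each
#'   tube is blocked; entries may be `NULL` (never blocked) or a list of
#'   several ranges
#' @param frequency imaging frequency, images/s
#' @return an [ImagingSchedule-class]; interval durations sum exactly to the
#'   arc delivery time
#' @export
partitionArc <- function(arc, blockedRanges = defaultBlockedRanges(),
                         frequency = 1.67) {
  span <- arcSpan(arc)
  sgn <- if (arc@direction == "CW") 1 else -1
  asRangeList <- function(r) {
    if (is.null(r)) list()
    else if (is.numeric(r)) list(r)
    else r
  }
  rangesA <- asRangeList(blockedRanges$A)
  rangesB <- asRangeList(blockedRanges$B)
  # sweep parameter s in [0, span]; boundary crossings of every range edge
  cuts <- c(0, span)
  for (r in c(rangesA, rangesB)) {
    for (edge in r) {
      s0 <- (sgn * (edge - arc@gantryStart)) %% 360
      while (s0 <= span) { cuts <- c(cuts, s0); s0 <- s0 + 360 }
    }
  }
  cuts <- sort(unique(pmin(pmax(cuts, 0), span)))
  mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
  angles <- (arc@gantryStart + sgn * mids) %% 360
  blockedA <- vapply(angles, function(a)
    any(vapply(rangesA, function(r) .inAngularRange(a, r), logical(1))),
    logical(1))
  blockedB <- vapply(angles, function(a)
    any(vapply(rangesB, function(r) .inAngularRange(a, r), logical(1))),
    logical(1))
  if (length(rangesA) == 0) blockedA <- rep(FALSE, length(mids))
  if (length(rangesB) == 0) blockedB <- rep(FALSE, length(mids))
  dur <- diff(cuts) / span * arc@deliveryTime
  keep <- dur > 0
  iv <- data.frame(
    duration = dur[keep],
    mode = ifelse(!blockedA[keep] & !blockedB[keep], "stereo", "mono"),
    tubeA = !blockedA[keep],
    tubeB = !blockedB[keep],
    stringsAsFactors = FALSE)
  # merge contiguous intervals with identical labelling
  if (nrow(iv) > 1) {
    key <- paste(iv$mode, iv$tubeA, iv$tubeB)
    grp <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
    iv <- data.frame(
      duration = as.numeric(tapply(iv$duration, grp, sum)),
      mode = tapply(iv$mode, grp, `[`, 1),
      tubeA = as.logical(tapply(iv$tubeA, grp, `[`, 1)),
      tubeB = as.logical(tapply(iv$tubeB, grp, `[`, 1)),
      stringsAsFactors = FALSE)
  }
  new("ImagingSchedule", intervals = iv, frequency = frequency)
}

#' Default gantry-blocking ranges
#'
#' Each tube is taken as blocked while the gantry head is within a half-width
#' of that tube's line of sight. With posterior-oblique floor tubes the lines
#' of sight project to gantry angles of about 240 (tube A, patient-right
#' beam exit) and 120 (tube B) degrees.
#'
#' @param centerA,centerB gantry angles of the two lines of sight, degrees
#' @param halfWidth blocking half-width, degrees
#' @export
defaultBlockedRanges <- function(centerA = 240, centerB = 120,
                                 halfWidth = 60) {
  list(A = c(centerA - halfWidth, centerA + halfWidth) %% 360,
       B = c(centerB - halfWidth, centerB + halfWidth) %% 360)
}

#' Per-tube image counts of a schedule
#'
#' Each interval contributes `floor(duration * frequency)` images; a tube's
#' total is the sum over the intervals in which it is active.
#'
#' @param schedule an [ImagingSchedule-class]
#' @return list with `perInterval` (integer vector) and `perTube`
#'   (named c(A =, B =))
#' @export
imageCounts <- function(schedule) {
  iv <- schedule@intervals
  n <- floor(iv$duration * schedule@frequency)
  list(perInterval = as.integer(n),
       perTube = c(A = sum(n[iv$tubeA]), B = sum(n[iv$tubeB])))
}

# ---- analytic kV dose surrogate ---------------------------------------------

#' Per-image kV dose from one tube (analytic primary-beam model)
#'
#' A deliberately simple, closed-form transport model: for every voxel inside
#' the tube's divergent cone,
#' \deqn{D = K_{ref} \cdot mAs \cdot (d_{ref}/r)^2 \cdot
#'       e^{-\mu_w \, t_{rad}} \cdot f_{mat}}
#' where `r` is the distance from the source, `t_rad` the radiological
#' (density-weighted) path length from the grid entry point to the voxel,
#' and `f_mat` the bone enhancement factor for bone voxels (1 otherwise).
#' Scatter, the heel effect and spectral changes along the path are ignored;
#' the model preserves the gross behaviour the constraint analysis relies on:
#' posterior weighting, a surface maximum, inverse-square and attenuation
#' falloff, and bone enhancement.
#'
#' The radiological path is a midpoint-rule line integral of the density
#' sampled at `nSamples` points between the ray's entry into the grid
#' bounding box and the voxel; vacuum (zero-density) stretches contribute no
#' attenuation.
#'
#' @param density a [DensityGrid-class]
#' @param tube a [KvTube-class]
#' @param technique an [ImagingTechnique-class]
#' @param doseGeometry geometry to compute the dose on (defaults to the
#'   density geometry; a coarser grid is typical, then resampled onto the
#'   treatment grid by the caller)
#' @param nSamples line-integral sample count per voxel
#' @return a [DoseGrid-class] on `doseGeometry`, Gy per image
#' @export
computeImageDose <- function(density, tube, technique,
                             doseGeometry = NULL, nSamples = 96) {
  g <- if (is.null(doseGeometry)) density@geometry else doseGeometry
  src <- tube@sourcePosition
  axis <- tubeAxis(tube)
  p <- voxelCoords(g)
  vx <- p$x - src[1]; vy <- p$y - src[2]; vz <- p$z - src[3]
  r <- sqrt(vx^2 + vy^2 + vz^2)
  cosang <- (vx * axis[1] + vy * axis[2] + vz * axis[3]) / r
  inCone <- cosang >= cos(tube@fieldHalfAngle * pi / 180)
  dose <- numeric(length(r))
  if (any(inCone)) {
    idx <- which(inCone)
    ux <- vx[idx] / r[idx]; uy <- vy[idx] / r[idx]; uz <- vz[idx] / r[idx]
    ri <- r[idx]
    # entry of each ray into the density-grid bounding box (slab method)
    dg <- density@geometry
    lo <- dg@origin - dg@spacing / 2
    hi <- dg@origin + (dg@dims - 0.5) * dg@spacing
    tIn <- rep(0, length(idx))
    u <- list(ux, uy, uz)
    for (ax in 1:3) {
      uax <- u[[ax]]
      t1 <- ifelse(uax > 0, (lo[ax] - src[ax]) / uax,
            ifelse(uax < 0, (hi[ax] - src[ax]) / uax, -Inf))
      tIn <- pmax(tIn, t1)
    }
    tIn <- pmin(tIn, ri)  # voxels before the box: no material upstream
    L <- ri - tIn
    acc <- numeric(length(idx))
    for (k in seq_len(nSamples)) {
      tk <- tIn + L * (k - 0.5) / nSamples
      acc <- acc + .trilinearSample(
        density@values, dg@dims,
        (src[1] + ux * tk - dg@origin[1]) / dg@spacing[1],
        (src[2] + uy * tk - dg@origin[2]) / dg@spacing[2],
        (src[3] + uz * tk - dg@origin[3]) / dg@spacing[3])
    }
    tRad <- acc * L / nSamples
    # material factor at the voxel itself (nearest-neighbour lookup)
    fi <- round((p$x[idx] - dg@origin[1]) / dg@spacing[1])
    fj <- round((p$y[idx] - dg@origin[2]) / dg@spacing[2])
    fk <- round((p$z[idx] - dg@origin[3]) / dg@spacing[3])
    okm <- fi >= 0 & fi <= dg@dims[1] - 1 & fj >= 0 & fj <= dg@dims[2] - 1 &
           fk >= 0 & fk <= dg@dims[3] - 1
    matFac <- rep(1, length(idx))
    lin <- 1 + fi[okm] + dg@dims[1] * (fj[okm] + dg@dims[2] * fk[okm])
    matFac[okm] <- ifelse(density@materials[lin] == 4L,
                          technique@boneFactor, 1)
    dose[idx] <- technique@airKermaRef * technique@masPerImage *
      (technique@refDistMm / ri)^2 * exp(-technique@muWater * tRad) * matFac
  }
  new("DoseGrid", geometry = g, values = array(dose, dim = g@dims))
}

#' Accumulate the real-time imaging dose over a treatment course
#'
#' Sums, over fractions, arcs and schedule intervals, the per-tube image
#' count times the per-image dose of each active tube. Per-image dose is
#' computed once per tube (it does not depend on the gantry), so the total is
#' linear in mAs, image count and fraction number.
#'
#' @param density a [DensityGrid-class]
#' @param arcs list of [VmatArc-class]
#' @param tubes list of two [KvTube-class] named A and B
#' @param technique an [ImagingTechnique-class]
#' @param nFractions number of identically delivered fractions
#' @param blockedRanges see [partitionArc()]
#' @param frequency imaging frequency, images/s
#' @param doseGeometry,nSamples see [computeImageDose()]
#' @return total-course imaging-dose [DoseGrid-class] on `doseGeometry`
#' @export
accumulateCourse <- function(density, arcs, tubes, technique, nFractions,
                             blockedRanges = defaultBlockedRanges(),
                             frequency = 1.67, doseGeometry = NULL,
                             nSamples = 96) {
  counts <- c(A = 0, B = 0)
  for (arc in arcs) {
    sched <- partitionArc(arc, blockedRanges, frequency)
    counts <- counts + imageCounts(sched)$perTube
  }
  counts <- counts * nFractions
  g <- if (is.null(doseGeometry)) density@geometry else doseGeometry
  total <- DoseGrid(g, 0)
  for (id in names(tubes)) {
    if (counts[[id]] > 0) {
      per <- computeImageDose(density, tubes[[id]], technique, g, nSamples)
      total <- total + per * counts[[id]]
    }
  }
  total
}
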