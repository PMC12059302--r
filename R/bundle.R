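#' @include cohort.R
NULL

# Native case-bundle format: one JSON metadata document plus raw
# little-endian arrays in R's native axis order (x fastest, then y, then z).
# density.f32 / txdose.f32: float32; materials.u8: material codes;
# masks.u8: one byte per voxel per structure, concatenated in the order the
# metadata lists the structures.

#' Write a patient case as a native fixture bundle
#'
#' @param case a [PatientCase-class]
#' @param dir bundle directory (created if needed)
#' @return invisibly, `dir`
#' @export
writeCaseBundle <- function(case, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- case@density@geometry
  st <- case@structures@structures
  meta <- list(
    format = "kvimpact-case-bundle",
    version = 1L,
    id = case@id,
    geometry = list(origin = g@origin, spacing = g@spacing, dims = g@dims),
    axis_order = "x fastest, then y, then z; little-endian",
    prescription = list(rx_total_gy = case@prescription@rxTotal,
                        n_fractions = case@prescription@nFractions),
    isocenter_mm = case@isocenter,
    arcs = lapply(case@arcs, function(a)
      list(gantry_start = a@gantryStart, gantry_stop = a@gantryStop,
           direction = a@direction, delivery_time_s = a@deliveryTime)),
    structures = lapply(st, function(s) list(name = s@name, role = s@role)),
    files = list(density = "density.f32", materials = "materials.u8",
                 tx_dose = "txdose.f32", masks = "masks.u8"))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wf32 <- function(x, f) {
    con <- file(file.path(dir, f), "wb")
    on.exit(close(con))
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  wf32(case@density@values, "density.f32")
  wf32(case@txDose@values, "txdose.f32")
  con <- file(file.path(dir, "materials.u8"), "wb")
  writeBin(as.raw(case@density@materials), con)
  close(con)
  con <- file(file.path(dir, "masks.u8"), "wb")
  for (s in st)
    writeBin(as.raw(as.integer(s@mask)), con)
  close(con)
  invisible(dir)
}

#' Read a native fixture bundle back into a patient case
#'
#' @param dir bundle directory written by [writeCaseBundle()]
#' @return a [PatientCase-class]
#' @export
readCaseBundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(meta$format, "kvimpact-case-bundle"))
    stop("'", dir, "' is not a case bundle")
  g <- GridGeometry(meta$geometry$origin, meta$geometry$spacing,
                    meta$geometry$dims)
  nv <- prod(g@dims)
  rf32 <- function(f) {
    con <- file(file.path(dir, f), "rb")
    on.exit(close(con))
    array(readBin(con, "numeric", n = nv, size = 4, endian = "little"),
          dim = g@dims)
  }
  ru8 <- function(f, n) {
    con <- file(file.path(dir, f), "rb")
    on.exit(close(con))
    as.integer(readBin(con, "raw", n = n))
  }
  density <- new("DensityGrid", geometry = g, values = rf32("density.f32"),
                 materials = array(ru8("materials.u8", nv), dim = g@dims))
  tx <- new("DoseGrid", geometry = g, values = rf32("txdose.f32"))
  maskBytes <- ru8("masks.u8", nv * length(meta$structures))
  st <- lapply(seq_along(meta$structures), function(i) {
    m <- meta$structures[[i]]
    Structure(m$name, m$role,
              mask = maskBytes[(i - 1) * nv + seq_len(nv)] > 0L)
  })
  arcs <- lapply(meta$arcs, function(a)
    VmatArc(a$gantry_start, a$gantry_stop, a$direction, a$delivery_time_s))
  new("PatientCase", id = meta$id, density = density,
      structures = StructureSet(st, frame = g), txDose = tx,
      prescription = Prescription(meta$prescription$rx_total_gy,
                                  meta$prescription$n_fractions),
      arcs = arcs, isocenter = as.numeric(meta$isocenter_mm))
}
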