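#' @include dvh.R
NULL

# ---- Prescription -----------------------------------------------------------

#' Prescription
#'
#' Total prescription dose and fractionation. The total dose is the Rx of the
#' Im/Rx (%) increment columns.
#'
#' @slot rxTotal prescription dose over the course, Gy, > 0
#' @slot nFractions number of fractions, >= 1
#' @export
setClass("Prescription",
  representation(rxTotal = "numeric", nFractions = "integer"))

setValidity("Prescription", function(object) {
  msg <- character()
  if (length(object@rxTotal) != 1L || !is.finite(object@rxTotal) ||
      object@rxTotal <= 0)
    msg <- c(msg, "'rxTotal' must be a single positive dose in Gy")
  if (length(object@nFractions) != 1L || is.na(object@nFractions) ||
      object@nFractions < 1L)
    msg <- c(msg, "'nFractions' must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' @param rxTotal,nFractions see slots
#' @rdname Prescription-class
#' @export
Prescription <- function(rxTotal, nFractions) {
  new("Prescription", rxTotal = as.numeric(rxTotal),
      nFractions = as.integer(nFractions))
}

setMethod("show", "Prescription", function(object) {
  cat(sprintf("Prescription: %g Gy / %d fr\n", object@rxTotal,
              object@nFractions))
})

# ---- protocol tables --------------------------------------------------------

.PROTOCOLS <- c(RTOG0915 = "rtog0915.csv", LUSTER = "luster.csv",
                SUNSET = "sunset.csv")

#' Load a clinical constraint table
#'
#' Ships the RTOG 0915 (4-fraction), LUSTER (8-fraction) and SUNSET
#' (15-fraction) lung-SBRT constraint sets as human-editable CSV files under
#' `inst/extdata/protocols/`. Rows marked not-applicable by a protocol are
#' absent from its file. Two report-only bone metrics (V30 Gy in cc and D2%)
#' are appended to every protocol for comparison with the chest wall; they
#' carry no limit and are excluded from pass/fail accounting.
#'
#' Constraint categories follow planning usage: C1 are absolute dose rules
#' (Gy: Dmean, Dmax to 0.03 cc, D2%), C2 absolute volume rules (cc), C3
#' percent-volume rules (% of the structure, including PTV coverage).
#'
#' @param name one of `"RTOG0915"`, `"LUSTER"`, `"SUNSET"`
#' @param path optional directory holding the protocol CSVs (defaults to the
#'   files shipped with the package)
#' @return a data.frame of constraint specifications with columns
#'   `structure`, `category`, `metric`, `threshold`, `limit`, `unit`,
#'   `comparator`, `report_only`
#' @export
loadProtocol <- function(name, path = NULL) {
  if (length(name) != 1L || !name %in% names(.PROTOCOLS))
    stop("unknown protocol '", paste(name, collapse = ","),
         "'; valid names: ", paste(names(.PROTOCOLS), collapse = ", "))
  file <- if (is.null(path))
    system.file("extdata", "protocols", .PROTOCOLS[[name]],
                package = "kvimpact", mustWork = TRUE)
  else file.path(path, .PROTOCOLS[[name]])
  specs <- utils::read.csv(file, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = c(structure = "character",
                                          category = "character",
                                          metric = "character",
                                          threshold = "numeric",
                                          limit = "numeric",
                                          unit = "character",
                                          comparator = "character",
                                          report_only = "logical"))
  specs$protocol <- name
  .validateSpecs(specs)
  specs
}

.validateSpecs <- function(specs) {
  catOf <- c(Dmean = "C1", Dmax = "C1", D2pct = "C1",
             V_cc = "C2", V_pct = "C3", PTV_VpctRx = "C3")
  bad <- specs$category != catOf[specs$metric]
  if (any(bad))
    stop("constraint category inconsistent with metric kind in row(s) ",
         paste(which(bad), collapse = ", "))
  if (any(!specs$report_only & is.na(specs$limit)))
    stop("enforceable constraints must carry a limit")
  if (any(specs$report_only & !is.na(specs$limit)))
    stop("report-only rows must not carry a limit")
  needsThr <- specs$metric %in% c("V_cc", "V_pct", "PTV_VpctRx")
  if (any(needsThr & is.na(specs$threshold)))
    stop("volume-type constraints must carry a dose threshold")
  invisible(specs)
}

#' Protocol selected by fractionation
#'
#' 4 fractions map to RTOG 0915, 8 to LUSTER, 15 to SUNSET.
#'
#' @param nFractions fraction count
#' @return protocol name
#' @export
protocolForFractions <- function(nFractions) {
  p <- switch(as.character(nFractions),
              "4" = "RTOG0915", "8" = "LUSTER", "15" = "SUNSET")
  if (is.null(p))
    stop("no protocol is defined for ", nFractions,
         " fractions (known: 4, 8, 15)")
  p
}

#' Human-readable label of a constraint row
#' @param spec one-row spec data.frame
#' @return e.g. "Trachea PRV V15.6 Gy", "Lt Lung Dmean", "PTV V90%"
#' @export
constraintLabel <- function(spec) {
  switch(spec$metric,
         Dmean = paste(spec$structure, "Dmean"),
         Dmax = paste(spec$structure, "Dmax"),
         D2pct = paste(spec$structure, "D2%"),
         V_cc = sprintf("%s V%g Gy", spec$structure, spec$threshold),
         V_pct = sprintf("%s V%g Gy", spec$structure, spec$threshold),
         PTV_VpctRx = sprintf("%s V%g%%", spec$structure, spec$threshold))
}

# ---- evaluation -------------------------------------------------------------

#' Evaluate one constraint metric
#'
#' Routes a constraint specification to the matching DVH metric: Dmean,
#' Dmax (dose to the hottest 0.03 cc), D2%, VD in cc or percent, or PTV
#' coverage relative to the prescription.
#'
#' @param spec a one-row spec data.frame (see [loadProtocol()])
#' @param dose a [DoseGrid-class]
#' @param structures a [StructureSet-class] on the dose geometry
#' @param rx a [Prescription-class] (used by PTV coverage)
#' @param aliases optional structure-name alias table
#' @param strict use strictly-greater dose-threshold comparison for V metrics
#' @return the metric value, or `NA` when the structure cannot be resolved
#'   (recorded as not evaluated downstream)
#' @export
evaluateMetric <- function(spec, dose, structures, rx, aliases = NULL,
                           strict = FALSE) {
  mask <- structureMask(structures, spec$structure, aliases)
  if (is.null(mask) || !any(mask)) return(NA_real_)
  switch(spec$metric,
         Dmean = meanDose(dose, mask),
         Dmax = doseAtVolume(dose, mask, 0.03),
         D2pct = doseAtVolumePct(dose, mask, 2),
         V_cc = volumeAboveCc(dose, mask, spec$threshold, strict),
         V_pct = volumeAbovePct(dose, mask, spec$threshold, strict),
         PTV_VpctRx = ptvCoveragePct(dose, mask, rx@rxTotal,
                                     spec$threshold, strict),
         stop("unknown metric kind '", spec$metric, "'"))
}

#' Apply a constraint comparator to an unrounded value
#'
#' Pass/fail is decided on unrounded metric values; report rendering rounds
#' separately. A value exactly at a `<=` limit passes.
#'
#' @param value metric value (finite)
#' @param spec one-row spec data.frame carrying `comparator` and `limit`
#' @return logical pass, or `NA` for report-only rows
#' @export
applyComparator <- function(value, spec) {
  if (isTRUE(spec$report_only)) return(NA)
  stopifnot(is.finite(value))
  switch(spec$comparator,
         "<=" = value <= spec$limit,
         "<"  = value <  spec$limit,
         ">"  = value >  spec$limit,
         stop("unknown comparator '", spec$comparator, "'"))
}

#' Evaluate one constraint under Tx and Tx + Im
#'
#' Computes the metric under the treatment dose and under the total dose,
#' applies the comparator to both, flags pass/fail flips, and reports the
#' constraint-value increments: Im/Tx (%) = 100 (total - tx) / tx (0/0
#' defined as 0; tx = 0 with a positive total is reported as `Inf` with a
#' warning), and, for C1 (dose-valued) rules only, Im/Rx (%) =
#' 100 (total - tx) / Rx.
#'
#' @param spec one-row spec data.frame
#' @param tx treatment-dose [DoseGrid-class]
#' @param total total-dose [DoseGrid-class] on the same geometry
#' @param structures a [StructureSet-class]
#' @param rx a [Prescription-class]
#' @inheritParams evaluateMetric
#' @return a one-row data.frame (a constraint result)
#' @export
evaluateConstraint <- function(spec, tx, total, structures, rx,
                               aliases = NULL, strict = FALSE) {
  vTx <- evaluateMetric(spec, tx, structures, rx, aliases, strict)
  vTot <- evaluateMetric(spec, total, structures, rx, aliases, strict)
  evaluated <- is.finite(vTx) && is.finite(vTot)
  if (evaluated) {
    passTx <- applyComparator(vTx, spec)
    passTot <- applyComparator(vTot, spec)
    if (vTx == 0 && vTot == 0) {
      imTx <- 0
    } else if (vTx == 0) {
      warning(sprintf(
        "%s: Tx value is 0 with a positive total; Im/Tx (%%) is undefined",
        constraintLabel(spec)))
      imTx <- Inf
    } else {
      imTx <- 100 * (vTot - vTx) / vTx
    }
    imRx <- if (spec$category == "C1") 100 * (vTot - vTx) / rx@rxTotal
            else NA_real_
  } else {
    passTx <- NA; passTot <- NA; imTx <- NA_real_; imRx <- NA_real_
  }
  data.frame(structure = spec$structure,
             label = constraintLabel(spec),
             category = spec$category,
             metric = spec$metric,
             threshold = spec$threshold,
             limit = spec$limit,
             unit = spec$unit,
             comparator = spec$comparator,
             report_only = spec$report_only,
             evaluated = evaluated,
             value_tx = vTx,
             value_total = vTot,
             pass_tx = passTx,
             pass_total = passTot,
             flipped = evaluated && !spec$report_only &&
               !is.na(passTx) && !is.na(passTot) && passTx != passTot,
             im_over_tx_pct = imTx,
             im_over_rx_pct = imRx,
             stringsAsFactors = FALSE)
}

#' Evaluate every protocol constraint for one patient
#'
#' The protocol is selected by the case prescription (4 fractions: RTOG 0915;
#' 8: LUSTER; 15: SUNSET). Returns one result row per constraint, in protocol
#' order, including the report-only bone rows. With a `NULL` or all-zero
#' imaging dose, results reduce to a Tx-only evaluation.
#'
#' @param case a [PatientCase-class]
#' @param imDose imaging-dose [DoseGrid-class] (any geometry; it is resampled
#'   onto the treatment-dose grid), or `NULL` for no imaging
#' @inheritParams evaluateMetric
#' @return data.frame of constraint results with a `patient` column
#' @export
evaluatePatient <- function(case, imDose = NULL, aliases = NULL,
                            strict = FALSE) {
  specs <- loadProtocol(protocolForFractions(case@prescription@nFractions))
  tx <- case@txDose
  total <- if (is.null(imDose)) tx
           else tx + resampleTo(imDose, tx@geometry)
  rows <- lapply(seq_len(nrow(specs)), function(i)
    evaluateConstraint(specs[i, , drop = FALSE], tx, total,
                       case@structures, case@prescription, aliases, strict))
  out <- do.call(rbind, rows)
  out <- cbind(patient = case@id, protocol = specs$protocol[1], out)
  rownames(out) <- NULL
  out
}
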