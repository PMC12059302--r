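#' @include protocols.R
NULL

# Results may arrive as one data.frame (with a `patient` column) or a list of
# per-patient data.frames; normalize to one data.frame.
.bindResults <- function(results) {
  if (is.data.frame(results)) return(results)
  if (!length(results)) stop("no constraint results to summarize")
  do.call(rbind, results)
}

.oarRows <- function(res) {
  res[!res$report_only & res$metric != "PTV_VpctRx" & res$evaluated, ,
      drop = FALSE]
}

.ptvRows <- function(res) {
  res[res$metric == "PTV_VpctRx" & res$evaluated, , drop = FALSE]
}

#' Cohort-level constraint summary
#'
#' Tallies, over all evaluated organ-at-risk constraints of a cohort (PTV
#' coverage is tracked separately, report-only rows are excluded from every
#' denominator): failure counts under Tx and Tx + Im, pass/fail flips, and
#' the distribution of the Im/Tx (%) constraint increments including the
#' census of increments exceeding 5% (the conventional reporting threshold
#' for imaging dose, applied here with strict >). Percentages are rounded to
#' one decimal.
#'
#' @slot nPatients patients contributing results
#' @slot nConstraintsEvaluated evaluated OAR constraints (denominator)
#' @slot nFailedTx,nFailedTotal failed OAR constraints under Tx / Tx + Im
#' @slot nFlipped OAR constraints whose pass/fail state changed
#' @slot pctFailedTx,pctFlipped 100 x count / denominator, 1 decimal
#' @slot imOverTxMin,imOverTxMean,imOverTxMax distribution of Im/Tx (%)
#' @slot nImOverTxAbove5 count of constraints with Im/Tx (%) > 5
#' @slot maxImOverRx largest Im/Rx (%) and
#' @slot maxImOverRxLabel the constraint it occurred on
#' @slot nPtv,nPtvFailedTx,nPtvFailedTotal,nPtvFlipped PTV coverage tallies
#' @export
setClass("CohortSummary",
  representation(nPatients = "integer", nConstraintsEvaluated = "integer",
                 nFailedTx = "integer", nFailedTotal = "integer",
                 nFlipped = "integer", pctFailedTx = "numeric",
                 pctFlipped = "numeric", imOverTxMin = "numeric",
                 imOverTxMean = "numeric", imOverTxMax = "numeric",
                 nImOverTxAbove5 = "integer", maxImOverRx = "numeric",
                 maxImOverRxLabel = "character", nPtv = "integer",
                 nPtvFailedTx = "integer", nPtvFailedTotal = "integer",
                 nPtvFlipped = "integer"))

setMethod("show", "CohortSummary", function(object) {
  cat(sprintf("CohortSummary: %d patients\n", object@nPatients))
  cat(sprintf("  OAR constraints evaluated: %d\n",
              object@nConstraintsEvaluated))
  cat(sprintf("  failed under Tx: %d (%.1f%%), under Tx+Im: %d; flips: %d (%.1f%%)\n",
              object@nFailedTx, object@pctFailedTx, object@nFailedTotal,
              object@nFlipped, object@pctFlipped))
  cat(sprintf("  Im/Tx (%%): min %.2f, mean %.2f, max %.2f; > 5%%: %d\n",
              object@imOverTxMin, object@imOverTxMean, object@imOverTxMax,
              object@nImOverTxAbove5))
  cat(sprintf("  max Im/Rx (%%): %.2f (%s)\n", object@maxImOverRx,
              object@maxImOverRxLabel))
  cat(sprintf("  PTV coverage: %d evaluated, failed Tx %d, failed Tx+Im %d, flips %d\n",
              object@nPtv, object@nPtvFailedTx, object@nPtvFailedTotal,
              object@nPtvFlipped))
})

#' Summarize a cohort of constraint results
#'
#' @param results a list of per-patient result data.frames (from
#'   [evaluatePatient()]) or one combined data.frame
#' @return a [CohortSummary-class]
#' @export
summarizeCohort <- function(results) {
  res <- .bindResults(results)
  if (!nrow(res)) stop("no constraint results to summarize")
  oar <- .oarRows(res)
  ptv <- .ptvRows(res)
  imTx <- oar$im_over_tx_pct[is.finite(oar$im_over_tx_pct)]
  imRx <- res$im_over_rx_pct[res$evaluated & !res$report_only]
  lab <- res$label[res$evaluated & !res$report_only]
  pat <- res$patient[res$evaluated & !res$report_only]
  ok <- is.finite(imRx)
  iMax <- if (any(ok)) which(ok)[which.max(imRx[ok])] else NA_integer_
  new("CohortSummary",
      nPatients = length(unique(res$patient)),
      nConstraintsEvaluated = nrow(oar),
      nFailedTx = sum(!oar$pass_tx),
      nFailedTotal = sum(!oar$pass_total),
      nFlipped = sum(oar$flipped),
      pctFailedTx = round(100 * sum(!oar$pass_tx) / nrow(oar), 1),
      pctFlipped = round(100 * sum(oar$flipped) / nrow(oar), 1),
      imOverTxMin = if (length(imTx)) min(imTx) else NA_real_,
      imOverTxMean = if (length(imTx)) mean(imTx) else NA_real_,
      imOverTxMax = if (length(imTx)) max(imTx) else NA_real_,
      nImOverTxAbove5 = sum(imTx > 5),
      maxImOverRx = if (!is.na(iMax)) imRx[iMax] else NA_real_,
      maxImOverRxLabel = if (!is.na(iMax))
        sprintf("%s (%s)", lab[iMax], pat[iMax]) else NA_character_,
      nPtv = nrow(ptv),
      nPtvFailedTx = sum(!ptv$pass_tx),
      nPtvFailedTotal = sum(!ptv$pass_total),
      nPtvFlipped = sum(ptv$flipped))
}

#' Cohort summary as a plain list (for JSON export)
#' @param x a [CohortSummary-class]
#' @export
summaryAsList <- function(x) {
  sl <- methods::slotNames(class(x))
  out <- lapply(sl, function(s) methods::slot(x, s))
  names(out) <- sl
  out
}

#' Paired comparison of bone and chest-wall V30 Gy
#'
#' Bone absorbs markedly more kilovoltage dose than soft tissue, so the
#' bone V30 Gy volume is tracked alongside the clinical chest-wall V30 Gy
#' rule. This runs a two-sided paired t-test on the per-patient differences
#' (bone minus chest wall, cc). With zero variance of the differences the
#' test is degenerate: means are reported without a p-value.
#'
#' @param results as in [summarizeCohort()]
#' @param which `"total"` (Tx + Im, default) or `"tx"`
#' @return list with `meanBone`, `meanChestWall`, `meanDiff`, `n`, `t`,
#'   `df`, `p`, `degenerate`
#' @export
pairedBoneChestwall <- function(results, which = c("total", "tx")) {
  which <- match.arg(which)
  col <- if (which == "total") "value_total" else "value_tx"
  res <- .bindResults(results)
  pick <- function(structure) {
    r <- res[res$structure == structure & res$metric == "V_cc" &
               res$threshold == 30 & res$evaluated, , drop = FALSE]
    stats::setNames(r[[col]], r$patient)
  }
  bone <- pick("Bone")
  cw <- pick("Chest Wall")
  common <- intersect(names(bone), names(cw))
  if (length(common) < 2)
    stop("need at least 2 patients with both V30 Gy metrics")
  b <- bone[common]; w <- cw[common]
  d <- b - w
  out <- list(meanBone = mean(b), meanChestWall = mean(w),
              meanDiff = mean(d), n = length(d))
  if (stats::sd(d) == 0) {
    out$degenerate <- TRUE
    out$t <- NA_real_; out$df <- NA_real_; out$p <- NA_real_
  } else {
    tt <- stats::t.test(b, w, paired = TRUE)
    out$degenerate <- FALSE
    out$t <- unname(tt$statistic)
    out$df <- unname(tt$parameter)
    out$p <- signif(tt$p.value, 3)
  }
  out
}

# ---- per-patient tables -----------------------------------------------------

.fmtValue <- function(value, metric) {
  digits <- if (metric == "PTV_VpctRx") 2 else 1
  sprintf(paste0("%.", digits, "f"), value)
}

.fmtRequirement <- function(row) {
  if (row$report_only) return("N/A")
  sprintf("%s%g %s", row$comparator, row$limit, row$unit)
}

#' Render a per-patient constraint table
#'
#' Formats one patient's constraint results with the clinical report layout:
#' category, constraint, requirement, Tx, Tx + Im, Im/Tx (%), Im/Rx (%) (C1
#' rows only, "-" otherwise). Metric values are rounded to 1 decimal (2 for
#' PTV coverage), increments to 2 decimals; unmet constraints are marked
#' with "*". Pass/fail was decided upstream on unrounded values.
#'
#' @param results one patient's result data.frame
#' @return data.frame of formatted strings (also used for CSV export)
#' @export
renderPatientTable <- function(results) {
  res <- .bindResults(results)
  mark <- function(value, pass, metric) {
    v <- .fmtValue(value, metric)
    ifelse(!is.na(pass) & !pass, paste0(v, "*"), v)
  }
  data.frame(
    category = res$category,
    constraint = res$label,
    requirement = vapply(seq_len(nrow(res)), function(i)
      .fmtRequirement(res[i, , drop = FALSE]), character(1)),
    tx = ifelse(res$evaluated,
                mapply(mark, res$value_tx, res$pass_tx, res$metric),
                "not evaluated"),
    tx_plus_im = ifelse(res$evaluated,
                        mapply(mark, res$value_total, res$pass_total,
                               res$metric),
                        "not evaluated"),
    im_over_tx_pct = ifelse(res$evaluated & is.finite(res$im_over_tx_pct),
                            sprintf("%.2f", res$im_over_tx_pct), "-"),
    im_over_rx_pct = ifelse(res$evaluated & !is.na(res$im_over_rx_pct),
                            sprintf("%.2f", res$im_over_rx_pct), "-"),
    stringsAsFactors = FALSE)
}

#' Write a patient report as CSV and aligned text
#'
#' Both renderings contain identical numbers; the text table adds a footnote
#' explaining the unmet-constraint marker.
#'
#' @param results one patient's result data.frame
#' @param csvFile,txtFile output paths (either may be `NULL` to skip)
#' @return invisibly, the formatted table
#' @export
writePatientReport <- function(results, csvFile = NULL, txtFile = NULL) {
  tab <- renderPatientTable(results)
  if (!is.null(csvFile))
    utils::write.csv(tab, csvFile, row.names = FALSE, quote = FALSE)
  if (!is.null(txtFile)) {
    header <- c("Cat", "Constraint", "Requirement", "Tx", "Tx + Im",
                "Im/Tx (%)", "Im/Rx (%)")
    cells <- rbind(header, as.matrix(tab))
    widths <- apply(nchar(cells), 2, max)
    lines <- apply(cells, 1, function(r)
      paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  "))
    lines <- c(lines, "", "* unmet constraint")
    writeLines(lines, txtFile)
  }
  invisible(tab)
}
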