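# Constraint tables, comparator semantics and constraint evaluation.

test_that("protocol tables load with the published rule counts and values", {
  rtog <- loadProtocol("RTOG0915")
  luster <- loadProtocol("LUSTER")
  sunset <- loadProtocol("SUNSET")
  expect_equal(sum(!rtog$report_only), 21)
  expect_equal(sum(rtog$report_only), 2)
  expect_equal(sum(!luster$report_only), 20)
  expect_equal(sum(!sunset$report_only), 17)
  # both spinal-cord volume rules of the 4-fraction protocol
  cord <- rtog[rtog$structure == "Spinal Cord PRV" & rtog$metric == "V_cc", ]
  expect_setequal(cord$threshold, c(20.8, 13.6))
  expect_equal(cord$limit[cord$threshold == 20.8], 0.35)
  expect_equal(cord$limit[cord$threshold == 13.6], 1.2)
  # 8-fraction heart Dmax
  hd <- luster[luster$structure == "Heart" & luster$metric == "Dmax", ]
  expect_equal(hd$limit, 64)
  expect_equal(hd$comparator, "<=")
  # the 15-fraction protocol carries no skin rules
  expect_false(any(sunset$structure == "Skin"))
  # report-only bone rows carry no limit
  expect_true(all(is.na(rtog$limit[rtog$report_only])))
  expect_error(loadProtocol("NOPE"), "RTOG0915, LUSTER, SUNSET")
})

test_that("fractionation selects the protocol", {
  expect_equal(protocolForFractions(4), "RTOG0915")
  expect_equal(protocolForFractions(8), "LUSTER")
  expect_equal(protocolForFractions(15), "SUNSET")
  expect_error(protocolForFractions(5), "no protocol")
})

test_that("protocol tables round-trip through serialization", {
  rtog <- loadProtocol("RTOG0915")
  dir <- tempfile(); dir.create(dir)
  write.csv(rtog[setdiff(names(rtog), "protocol")],
            file.path(dir, "rtog0915.csv"), row.names = FALSE, na = "")
  back <- loadProtocol("RTOG0915", path = dir)
  expect_equal(back, rtog)
})

test_that("comparators act on unrounded values with boundary semantics", {
  ptv <- data.frame(structure = "PTV", category = "C3", metric = "PTV_VpctRx",
                    threshold = 90, limit = 99, unit = "%", comparator = ">",
                    report_only = FALSE)
  expect_false(applyComparator(98.96, ptv))
  expect_true(applyComparator(99.10, ptv))
  lung <- data.frame(structure = "Lt Lung", category = "C1",
                     metric = "Dmean", threshold = NA, limit = 6,
                     unit = "Gy", comparator = "<=", report_only = FALSE)
  expect_false(applyComparator(6.2, lung))
  expect_true(applyComparator(6.0, lung))    # exactly at a <= limit passes
  skin <- data.frame(structure = "Skin", category = "C1", metric = "Dmax",
                     threshold = NA, limit = 36, unit = "Gy",
                     comparator = "<", report_only = FALSE)
  expect_false(applyComparator(36, skin))    # < is exclusive
  expect_true(applyComparator(35.999, skin))
})

test_that("metric evaluation routes each constraint to the right DVH metric", {
  g <- smallGeometry(c(10L, 10L, 10L), 2)
  lungMask <- array(TRUE, dim = g@dims)
  set <- StructureSet(list(Structure("Lt Lung", "OAR", mask = lungMask)),
                      frame = g)
  rx <- Prescription(48, 4)
  dmean <- data.frame(structure = "Lt Lung", category = "C1",
                      metric = "Dmean", threshold = NA, limit = 6,
                      unit = "Gy", comparator = "<=", report_only = FALSE)
  expect_equal(evaluateMetric(dmean, DoseGrid(g, 6), set, rx), 6.0)
  set.seed(41)
  v <- array(ifelse(runif(1000) < 0.304, 25, 5), dim = g@dims)
  vpct <- dmean; vpct$metric <- "V_pct"; vpct$category <- "C3"
  vpct$threshold <- 20
  expect_equal(evaluateMetric(vpct, DoseGrid(g, v), set, rx),
               100 * mean(v >= 20))
  vcc <- dmean; vcc$metric <- "V_cc"; vcc$category <- "C2"
  vcc$threshold <- 15.6
  expect_equal(evaluateMetric(vcc, DoseGrid(g, 10), set, rx), 0.0)
  missing <- dmean; missing$structure <- "Esophagus PRV"
  expect_true(is.na(evaluateMetric(missing, DoseGrid(g, 10), set, rx)))
})

test_that("a marginal pass under Tx flips to fail with a 0.10 Gy increment", {
  g <- smallGeometry(c(10L, 10L, 10L), 2)
  mask <- array(TRUE, dim = g@dims)
  set <- StructureSet(list(Structure("Lt Lung", "OAR", mask = mask)),
                      frame = g)
  spec <- data.frame(structure = "Lt Lung", category = "C1",
                     metric = "Dmean", threshold = NA_real_, limit = 6,
                     unit = "Gy", comparator = "<=", report_only = FALSE)
  tx <- DoseGrid(g, 5.95)
  total <- DoseGrid(g, 6.05)
  res <- evaluateConstraint(spec, tx, total, set, Prescription(48, 4))
  expect_true(res$pass_tx); expect_false(res$pass_total)
  expect_true(res$flipped)
  expect_equal(res$im_over_tx_pct, 100 * 0.10 / 5.95, tolerance = 1e-9)
  expect_equal(res$im_over_rx_pct, 100 * 0.10 / 48, tolerance = 1e-9)
})

test_that("increment edge cases: zero/zero gives 0, zero Tx warns with Inf", {
  g <- smallGeometry(c(6L, 6L, 6L), 2)
  mask <- array(TRUE, dim = g@dims)
  set <- StructureSet(list(Structure("Trachea PRV", "OAR", mask = mask)),
                      frame = g)
  spec <- data.frame(structure = "Trachea PRV", category = "C2",
                     metric = "V_cc", threshold = 62, limit = 10,
                     unit = "cc", comparator = "<=", report_only = FALSE)
  rx <- Prescription(60, 15)
  res0 <- evaluateConstraint(spec, DoseGrid(g, 1), DoseGrid(g, 2), set, rx)
  expect_equal(res0$value_tx, 0); expect_equal(res0$value_total, 0)
  expect_equal(res0$im_over_tx_pct, 0)
  expect_warning(
    resInf <- evaluateConstraint(spec, DoseGrid(g, 1), DoseGrid(g, 63),
                                 set, rx),
    "undefined")
  expect_true(is.infinite(resInf$im_over_tx_pct))
})

test_that("patient evaluation covers the protocol, in order, and is Tx-identical without imaging", {
  cs <- sharedCase()
  res <- evaluatePatient(cs, imDose = NULL)
  specs <- loadProtocol("RTOG0915")
  expect_equal(nrow(res), nrow(specs))
  expect_equal(res$label,
               vapply(seq_len(nrow(specs)), function(i)
                 constraintLabel(specs[i, , drop = FALSE]), character(1)))
  expect_true(all(res$evaluated))
  expect_equal(res$value_tx, res$value_total)
  expect_false(any(res$flipped))
  expect_true(all(res$im_over_tx_pct[res$evaluated] == 0))
})

test_that("flip directions are one-way: OAR pass->fail, PTV coverage fail->pass", {
  set.seed(43)
  g <- smallGeometry(c(8L, 8L, 8L), 2)
  mask <- array(TRUE, dim = g@dims)
  set <- StructureSet(list(Structure("Heart", "OAR", mask = mask),
                           Structure("PTV", "PTV", mask = mask)),
                      frame = g)
  rx <- Prescription(48, 4)
  oarSpec <- data.frame(structure = "Heart", category = "C1",
                        metric = "Dmax", threshold = NA_real_, limit = 34,
                        unit = "Gy", comparator = "<=", report_only = FALSE)
  ptvSpec <- data.frame(structure = "PTV", category = "C3",
                        metric = "PTV_VpctRx", threshold = 90, limit = 99,
                        unit = "%", comparator = ">", report_only = FALSE)
  for (rep in 1:20) {
    tx <- randomDoseGrid(g, 45)
    tot <- tx + randomDoseGrid(g, 2)
    ro <- evaluateConstraint(oarSpec, tx, tot, set, rx)
    expect_true(ro$value_total >= ro$value_tx)
    if (ro$flipped) { expect_true(ro$pass_tx); expect_false(ro$pass_total) }
    rp <- evaluateConstraint(ptvSpec, tx, tot, set, rx)
    if (rp$flipped) { expect_false(rp$pass_tx); expect_true(rp$pass_total) }
  }
})
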