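# DVH construction and the dose/volume metric family.

test_that("uniform and two-level dose fields give the expected DVH", {
  g <- smallGeometry(c(10L, 10L, 20L), 1)  # 1 mm voxels, 0.001 cc
  mask <- array(FALSE, dim = g@dims)
  mask[, , 1:20] <- TRUE  # 2 cc
  dose <- DoseGrid(g, 10)
  dvh <- computeDVH(dose, mask, binWidth = 0.5)
  expect_equal(dvh@totalVolumeCc, 2)
  expect_true(all(dvh@volumeCc[dvh@doseEdges <= 10] == 2))
  expect_true(all(dvh@volumeCc[dvh@doseEdges > 10] == 0))
  # two 1 cc halves at 5 and 15 Gy
  v <- array(5, dim = g@dims); v[, , 11:20] <- 15
  dvh2 <- computeDVH(DoseGrid(g, v), mask, binWidth = 1)
  expect_equal(dvh2@volumeCc[dvh2@doseEdges <= 5], rep(2, 6))
  expect_equal(dvh2@volumeCc[dvh2@doseEdges > 5 & dvh2@doseEdges <= 15],
               rep(1, 10))
  expect_true(all(dvh2@volumeCc[dvh2@doseEdges > 15] == 0))
})

test_that("the cumulative DVH equals a direct counting oracle", {
  set.seed(31)
  g <- smallGeometry(c(10L, 10L, 10L), 1)
  dose <- randomDoseGrid(g, max = 30)
  mask <- array(TRUE, dim = g@dims)
  dvh <- computeDVH(dose, mask, binWidth = 0.7)
  d <- doseValues(dose)[mask]
  for (i in seq(1, length(dvh@doseEdges), by = 7)) {
    expect_equal(dvh@volumeCc[i],
                 sum(d >= dvh@doseEdges[i]) * voxelVolumeCc(g))
  }
  expect_error(computeDVH(dose, array(FALSE, dim = g@dims)), "empty mask")
})

test_that("Dmax to 0.03 cc interpolates inside the crossing voxel", {
  # 3 mm voxels: 0.027 cc each; hottest 20 Gy, next 18 Gy
  g <- smallGeometry(c(4L, 4L, 4L), 3)
  v <- array(1, dim = g@dims)
  v[1, 1, 1] <- 20; v[2, 1, 1] <- 18
  dose <- DoseGrid(g, v)
  mask <- array(TRUE, dim = g@dims)
  dmax <- doseAtVolume(dose, mask, 0.03)
  expect_gt(dmax, 18); expect_lt(dmax, 20)
  expect_equal(dmax, oracleDoseAtVolume(v[mask], 0.027, 0.03),
               tolerance = 1e-12)
  # v at the total volume returns the minimum dose
  expect_equal(doseAtVolume(dose, mask, 64 * 0.027), 1)
  # uniform field: any valid volume returns the uniform dose
  u <- DoseGrid(g, 12)
  expect_equal(doseAtVolume(u, mask, 0.03), 12)
  expect_equal(doseAtVolumePct(u, mask, 37), 12)
  expect_error(doseAtVolume(dose, mask, 0), "> 0")
  expect_error(doseAtVolume(dose, mask, 1e3), "exceeds")
})

test_that("percent-volume dose agrees with the sorted-voxel oracle", {
  set.seed(32)
  g <- smallGeometry(c(8L, 8L, 8L), 2)
  dose <- randomDoseGrid(g, 40)
  mask <- array(runif(prod(g@dims)) < 0.7, dim = g@dims)
  vv <- voxelVolumeCc(g)
  n <- sum(mask)
  for (p in c(2, 10, 50, 100)) {
    expect_equal(doseAtVolumePct(dose, mask, p),
                 oracleDoseAtVolume(doseValues(dose)[mask], vv,
                                    p / 100 * n * vv),
                 tolerance = 1e-12)
  }
  expect_equal(doseAtVolumePct(dose, mask, 100),
               min(doseValues(dose)[mask]))
})

test_that("mean dose is the arithmetic mean over the mask", {
  g <- smallGeometry(c(6L, 6L, 6L), 1)
  expect_equal(meanDose(DoseGrid(g, 6), array(TRUE, dim = g@dims)), 6)
  v <- array(0, dim = g@dims); v[1:3, , ] <- 12
  expect_equal(meanDose(DoseGrid(g, v), array(TRUE, dim = g@dims)), 6)
  set.seed(33)
  dose <- randomDoseGrid(g)
  mask <- array(runif(216) < 0.5, dim = g@dims)
  expect_equal(meanDose(dose, mask),
               sum(doseValues(dose)[mask]) / sum(mask))
  expect_error(meanDose(dose, array(FALSE, dim = g@dims)), "empty mask")
})

test_that("volume-above metrics count voxels at or above the threshold", {
  # graded slab: 30 slabs of 1 cc with voxel doses 0.5, 1.5, ..., 29.5 Gy
  g <- GridGeometry(c(0, 0, 0), c(10, 10, 10), c(1L, 1L, 30L))
  dose <- DoseGrid(g, array(seq(0.5, 29.5, by = 1), dim = c(1, 1, 30)))
  mask <- array(TRUE, dim = g@dims)
  expect_equal(volumeAboveCc(dose, mask, 15), 15)
  expect_equal(volumeAboveCc(dose, mask, 15.5), 15)  # >= includes 15.5
  expect_equal(volumeAboveCc(dose, mask, 15.5, strict = TRUE), 14)
  g2 <- smallGeometry(c(10L, 10L, 40L), 1)
  u <- DoseGrid(g2, 10)
  m4 <- array(FALSE, dim = g2@dims); m4[, , 1:40] <- TRUE  # 4 cc
  expect_equal(volumeAboveCc(u, m4, 5), 4)
  expect_equal(volumeAboveCc(u, m4, 11), 0)
  expect_equal(volumeAbovePct(u, m4, 5), 100)
  v <- array(c(0, 20), dim = g2@dims)
  expect_equal(volumeAbovePct(DoseGrid(g2, v), m4, 10), 50)
})

test_that("PTV coverage uses the percent-of-prescription threshold", {
  g <- smallGeometry(c(10L, 10L, 10L), 2)
  mask <- array(TRUE, dim = g@dims)
  expect_equal(ptvCoveragePct(DoseGrid(g, 48), mask, rx = 48), 100)
  set.seed(34)
  v <- array(ifelse(runif(1000) < 0.991, 48, 40), dim = g@dims)
  dose <- DoseGrid(g, v)
  expect_equal(ptvCoveragePct(dose, mask, 48, 90),
               100 * sum(v >= 43.2) / 1000)
  expect_equal(ptvCoveragePct(DoseGrid(g, 40), mask, 48, 90), 0)
})

test_that("adding non-negative dose never decreases any metric (monotonicity)", {
  set.seed(35)
  g <- smallGeometry(c(8L, 8L, 8L), 2)
  for (rep in 1:5) {
    tx <- randomDoseGrid(g, 30)
    im <- randomDoseGrid(g, 0.5)
    tot <- tx + im
    mask <- array(runif(prod(g@dims)) < 0.6, dim = g@dims)
    expect_gte(meanDose(tot, mask), meanDose(tx, mask))
    expect_gte(doseAtVolume(tot, mask, 0.03), doseAtVolume(tx, mask, 0.03))
    expect_gte(doseAtVolumePct(tot, mask, 2), doseAtVolumePct(tx, mask, 2))
    expect_gte(volumeAboveCc(tot, mask, 10), volumeAboveCc(tx, mask, 10))
    expect_gte(volumeAbovePct(tot, mask, 10), volumeAbovePct(tx, mask, 10))
    expect_gte(ptvCoveragePct(tot, mask, 30), ptvCoveragePct(tx, mask, 30))
  }
})

test_that("dose-at-volume and volume-above are inverse-consistent", {
  set.seed(36)
  g <- smallGeometry(c(10L, 10L, 10L), 1.5)
  dose <- randomDoseGrid(g, 25)
  mask <- array(TRUE, dim = g@dims)
  vv <- voxelVolumeCc(g)
  for (v in c(0.05, 1, 2)) {
    D <- doseAtVolume(dose, mask, v)
    expect_lt(abs(volumeAboveCc(dose, mask, D) - v), vv * 1.5)
  }
})

test_that("DVH objects interpolate and export", {
  g <- smallGeometry(c(10L, 10L, 10L), 1)
  v <- array(rep(seq(1, 10), each = 100), dim = g@dims)
  dose <- DoseGrid(g, v)
  mask <- array(TRUE, dim = g@dims)
  dvh <- computeDVH(dose, mask, binWidth = 0.25)
  expect_equal(doseAtVolume(dvh, dvh@totalVolumeCc), 0)
  d <- doseAtVolume(dvh, 0.05)
  expect_equal(d, max(dvh@doseEdges[dvh@volumeCc >= 0.05]), tolerance = 0.25)
  f <- tempfile(fileext = ".txt")
  writeDVH(dvh, f)
  tab <- read.delim(f)
  expect_equal(tab$volume_cc, dvh@volumeCc)
})
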