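# Stereoscopic/monoscopic schedule model and the analytic kV dose surrogate.

test_that("a full arc with two disjoint 60-degree blocked ranges splits 80/20/20 s", {
  arc <- VmatArc(0, 0, "CW", 120)        # full 360 degrees in 120 s
  blocked <- list(A = c(90, 150), B = c(200, 260))
  sched <- partitionArc(arc, blocked)
  iv <- sched@intervals
  expect_equal(sum(iv$duration), 120)
  expect_equal(sum(iv$duration[iv$mode == "stereo"]), 80)
  expect_equal(sum(iv$duration[iv$mode == "mono" & iv$tubeB]), 20)
  expect_equal(sum(iv$duration[iv$mode == "mono" & iv$tubeA]), 20)
})

test_that("no blocking gives one all-stereo interval; total blocking one mono interval", {
  arc <- VmatArc(180, 270, "CW", 30)
  s1 <- partitionArc(arc, list(A = NULL, B = NULL))
  expect_equal(nrow(s1@intervals), 1)
  expect_equal(s1@intervals$mode, "stereo")
  expect_equal(s1@intervals$duration, 30)
  # arc entirely inside tube A's blocked range: tube B only
  s2 <- partitionArc(arc, list(A = c(170, 280), B = NULL))
  expect_equal(nrow(s2@intervals), 1)
  expect_equal(s2@intervals$mode, "mono")
  expect_false(s2@intervals$tubeA)
  expect_true(s2@intervals$tubeB)
})

test_that("schedule durations always partition the delivery time", {
  set.seed(51)
  for (rep in 1:40) {
    arc <- VmatArc(runif(1, 0, 360), runif(1, 0, 360),
                   sample(c("CW", "CCW"), 1), runif(1, 30, 240))
    blocked <- list(A = sort(runif(2, 0, 360)), B = sort(runif(2, 0, 360)))
    sched <- partitionArc(arc, blocked)
    expect_equal(sum(sched@intervals$duration), arc@deliveryTime,
                 tolerance = 1e-9)
  }
})

test_that("image counts floor the per-interval duration-frequency product", {
  arc <- VmatArc(0, 0, "CW", 60)
  sched <- partitionArc(arc, list(A = NULL, B = NULL), frequency = 1.67)
  counts <- imageCounts(sched)
  expect_equal(unname(counts$perTube["A"]), 100)  # floor(60 x 1.67)
  expect_equal(unname(counts$perTube["B"]), 100)
  zero <- partitionArc(VmatArc(0, 0, "CW", 1e-9), list(A = NULL, B = NULL))
  expect_equal(sum(imageCounts(zero)$perTube), 0)
  double <- partitionArc(VmatArc(0, 0, "CW", 120), list(A = NULL, B = NULL),
                         frequency = 1.67)
  expect_equal(unname(imageCounts(double)$perTube["A"]), 200)
})

test_that("central-axis depth dose in water follows attenuation times inverse square", {
  # water slab from z = 0 downward; source on the +z axis above it
  g <- GridGeometry(c(-50, -50, -147.5), c(5, 5, 5), c(21L, 21L, 30L))
  density <- waterPhantom(g)
  R <- 500  # source-to-surface distance: surface at z = 0 is the slab top
  tube <- KvTube("A", c(0, 0, R), c(0, 0, -100), fieldHalfAngle = 20)
  tech <- ImagingTechnique(120, 16, muWater = 0.022, airKermaRef = 5e-5)
  dose <- computeImageDose(density, tube, tech, nSamples = 200)
  zc <- axisCoords(g, 3)
  axial <- doseValues(dose)[11, 11, ]
  surfaceZ <- max(zc)
  for (pair in list(c(28, 20), c(25, 12), c(30, 5))) {
    z1 <- zc[pair[1]]; z2 <- zc[pair[2]]
    d1 <- surfaceZ - z1 + 2.5; d2 <- surfaceZ - z2 + 2.5  # depth below slab top
    expected <- exp(-tech@muWater * (d2 - d1)) *
      ((R - surfaceZ - 2.5 + d1) / (R - surfaceZ - 2.5 + d2))^2
    expect_equal(axial[pair[2]] / axial[pair[1]], expected, tolerance = 0.01)
  }
  # the surface voxel is the maximum along the beam path
  expect_equal(which.max(axial), 30)
})

test_that("the surrogate is linear in mAs and respects the cone boundary", {
  g <- smallGeometry(c(12L, 12L, 12L), 5)
  density <- waterPhantom(g)
  tube <- KvTube("A", c(0, 600, 0), c(0, 0, 0), fieldHalfAngle = 4)
  t1 <- ImagingTechnique(120, 8, 0.022)
  t2 <- ImagingTechnique(120, 16, 0.022)
  d1 <- doseValues(computeImageDose(density, tube, t1))
  d2 <- doseValues(computeImageDose(density, tube, t2))
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  # voxels outside the 4-degree cone get exactly zero
  p <- voxelCoords(g)
  vx <- p$x; vy <- p$y - 600; vz <- p$z
  cosang <- -vy / sqrt(vx^2 + vy^2 + vz^2)
  expect_true(all(d1[cosang < cos(4 * pi / 180)] == 0))
  expect_true(any(d1 > 0))
})

test_that("bone voxels get the configured enhancement at equal radiological depth", {
  g <- GridGeometry(c(-10, -10, -10), c(10, 10, 10), c(3L, 3L, 3L))
  mats <- array("soft", dim = g@dims)
  mats[1, 2, 2] <- "bone"  # same density, bone label: equal attenuation path
  density <- DensityGrid(g, array(1, dim = g@dims), mats)
  # symmetric geometry: source on +y axis, bone and soft voxels mirrored in x
  tube <- KvTube("A", c(0, 2000, 0), c(0, 0, 0), fieldHalfAngle = 10)
  tech <- ImagingTechnique(120, 16, 0.022, boneFactor = 4)
  d <- doseValues(computeImageDose(density, tube, tech, nSamples = 64))
  expect_equal(d[1, 2, 2] / d[3, 2, 2], 4.0, tolerance = 1e-9)
})

test_that("course accumulation is linear in images and fractions, stereo = sum of monos", {
  cs <- sharedCase()
  g <- geometry(cs@density)
  tubes <- defaultTubes(cs@isocenter)
  tech <- ImagingTechnique(120, 16, 0.022)
  coarse <- GridGeometry(g@origin, c(10, 10, 10), c(22L, 16L, 20L))
  perA <- computeImageDose(cs@density, tubes$A, tech, coarse, nSamples = 48)
  perB <- computeImageDose(cs@density, tubes$B, tech, coarse, nSamples = 48)
  arcs <- list(VmatArc(0, 0, "CW", 60))
  noBlock <- list(A = NULL, B = NULL)
  one <- accumulateCourse(cs@density, arcs, tubes, tech, 1, noBlock,
                          frequency = 1.67, doseGeometry = coarse,
                          nSamples = 48)
  # 100 stereo images/tube: the course equals 100 x (tube A + tube B)
  expect_equal(doseValues(one), 100 * (doseValues(perA) + doseValues(perB)),
               tolerance = 1e-12)
  four <- accumulateCourse(cs@density, arcs, tubes, tech, 4, noBlock,
                           frequency = 1.67, doseGeometry = coarse,
                           nSamples = 48)
  expect_equal(doseValues(four), 4 * doseValues(one), tolerance = 1e-12)
})

test_that("posterior tubes load the posterior half of the thorax more", {
  cs <- sharedCase()
  im <- imagingDoseForCase(cs)
  p <- voxelCoords(geometry(im))
  v <- doseValues(im)
  body <- v > 0
  post <- p$y > 0
  expect_gt(mean(v[body & post]), mean(v[body & !post]))
})

test_that("technique selection follows the water-equivalent thickness classes", {
  tab <- defaultTechniqueTable()
  small <- techniqueForSize(100, tab)
  large <- techniqueForSize(200, tab)
  expect_lt(small@kvp, large@kvp)
  expect_lt(small@masPerImage, large@masPerImage)
  expect_gt(small@muWater, large@muWater)  # softer beams attenuate faster
})
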