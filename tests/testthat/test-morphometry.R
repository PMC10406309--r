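test_that("planar area is voxel count times pixel area", {
  mkBlock <- function(pix) {
    d <- array(0, c(21, 21, 9))
    for (k in 1:9) d[6:15, 6:15, k] <- 1          # 100 voxels per slice
    aff <- diag(c(pix, pix, 1, 1))
    cordVolume(d, aff)
  }
  v1 <- mkBlock(1)
  cl <- extractCenterline(v1, smoothing_mm = 0)
  sm <- sliceMetrics(v1, cl)
  expect_true(all(sm$planar_area == 100))
  expect_true(all(sm$angle == 0))
  expect_true(all(sm$corrected_area == 100))
  expect_true(all(is.na(sm$distance_pmj)))        # no PMJ anchor

  v08 <- mkBlock(0.8)
  sm08 <- sliceMetrics(v08, extractCenterline(v08, smoothing_mm = 0))
  expect_equal(sm08$planar_area, rep(64, 9))      # 100 x 0.64
})

test_that("angulation correction recovers the perpendicular area of tilted cylinders", {
  for (tilt in c(10, 20, 30)) {
    ph <- tiltedPhantom(tilt)
    res <- csaPMJ(ph$mask, ph$labels)
    planar <- mean(perSliceMetrics(res)$planar_area)
    expect_lt(abs(csaValue(res) / (25 * pi) - 1), 0.03)
    expect_lt(abs(planar / (25 * pi / cospi(tilt / 180)) - 1), 0.03)
    # measured angle close to the applied tilt
    expect_lt(abs(mean(perSliceMetrics(res)$angle) - tilt * pi / 180), 0.02)
  }
})

test_that("a mask slice without a centerline point is an error", {
  ph <- straightPhantom()
  cl <- extractCenterline(ph$mask, pmjLabelOf(ph))
  short <- centerline(cl@points[1:20, ], cl@sliceIndex[1:20],
                      pmjAnchored = TRUE)
  expect_error(sliceMetrics(ph$mask, short), "centerline incomplete")
})

test_that("csaPMJ is invariant to translating the phantom inside the grid", {
  base <- makeTubePhantom(phantomSpec("straight", radius_mm = 5,
                                      extent_si_mm = 120))
  shifted <- makeTubePhantom(phantomSpec("poly", radius_mm = 5,
                                         extent_si_mm = 120,
                                         poly_x = 10, poly_y = 10))
  a <- csaValue(csaPMJ(base$mask, base$labels))
  b <- csaValue(csaPMJ(shifted$mask, shifted$labels))
  expect_equal(a, b, tolerance = 1e-7)
})

test_that("csaPMJ equals the plain mean of planar areas for an untilted tube", {
  ph <- straightPhantom()
  res <- csaPMJ(ph$mask, ph$labels)
  expect_identical(csaValue(res), mean(perSliceMetrics(res)$planar_area))
})

test_that("vertebral CSA averages the disc-bounded span", {
  spec <- phantomSpec("straight", radius_mm = 5, extent_si_mm = 120,
                      disc_arcs_mm = c("2" = 54, "3" = 64, "4" = 74))
  ph <- cachedPhantom("straight_discs", spec)
  res <- csaVertebral(ph$mask, ph$labels)
  expect_lt(abs(csaValue(res) / (25 * pi) - 1), 0.02)
  expect_identical(res@nSlices, 21L)              # discs straddle 21 slices

  expect_error(csaVertebral(ph$mask, list(pmjLabelOf(ph))),
               "missing disc label with code 2")
})

test_that("vertebral CSA tracks a tapering radius profile", {
  spec <- phantomSpec("straight", radius_mm = function(s) 5 - 0.015 * s,
                      extent_si_mm = 120,
                      disc_arcs_mm = c("2" = 54, "4" = 74))
  ph <- makeTubePhantom(spec)
  res <- csaVertebral(ph$mask, ph$labels)
  sel <- ph$truth$arc_length >= 54 & ph$truth$arc_length <= 74
  expect_lt(abs(csaValue(res) / mean(ph$truth$true_csa[sel]) - 1), 0.03)
})

test_that("compareMethods matches paired t-test expectations", {
  a <- c(60, 65, 70, 75, 80)
  same <- compareMethods(a, a)
  expect_identical(same$t, 0)
  expect_identical(same$mean_difference, 0)

  shift <- compareMethods(a, a + 1)
  expect_equal(shift$mean_difference, -1)
  expect_lt(shift$p, 1e-6)

  # simulated pairs: diff ~ N(0.5, 1), n = 400 -> E[t] ~ 0.5 * sqrt(400) = 10
  set.seed(99)
  x <- rnorm(400, 70, 5)
  y <- x - rnorm(400, 0.5, 1)
  cm <- compareMethods(x, y)
  expect_lt(abs(cm$t - 10), 3)
  expect_equal(cm$summary$cov,
               c(covPercent(x), covPercent(y)))
})
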