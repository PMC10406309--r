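test_that("straight tube centerline sits on the tube axis", {
  ph <- straightPhantom()
  cl <- extractCenterline(ph$mask, pmjLabelOf(ph))
  onSlice <- !is.na(cl@sliceIndex)
  # axis x/y from the truth table (constant for a straight tube)
  expect_true(all(abs(cl@points[onSlice, 1] - ph$truth$x[1]) < 0.1))
  expect_true(all(abs(cl@points[onSlice, 2] - ph$truth$y[1]) < 0.1))
  expect_true(cl@pmjAnchored)
  expect_identical(cl@arcLength[1], 0)
})

test_that("a fully-missing interior slice is filled by linear interpolation", {
  d <- array(0, c(21, 21, 15))
  for (k in 1:15) d[6:10, 9:13, k] <- 1     # constant in-plane block
  d[, , 8] <- 0                              # knock out one slice
  # drift the block on later slices so the midpoint is informative
  d[, , 9:15] <- 0
  for (k in 9:15) d[8:12, 9:13, k] <- 1      # shifted by +2 in x
  v <- cordVolume(d)
  cl <- extractCenterline(v, pmj = NULL, smoothing_mm = 0)
  i8 <- which(cl@sliceIndex == 8)
  i7 <- which(cl@sliceIndex == 7)
  i9 <- which(cl@sliceIndex == 9)
  expect_equal(cl@points[i8, 1:2],
               (cl@points[i7, 1:2] + cl@points[i9, 1:2]) / 2)
})

test_that("curved phantom centerline stays within half a voxel of the truth", {
  ph <- arcPhantom()
  cl <- extractCenterline(ph$mask, pmjLabelOf(ph))
  m <- match(ph$truth$slice, cl@sliceIndex)
  ok <- !is.na(m)
  dev <- sqrt((ph$truth$x[ok] - cl@points[m[ok], 1])^2 +
              (ph$truth$y[ok] - cl@points[m[ok], 2])^2)
  expect_lt(max(dev), 0.5)
})

test_that("centerline error modes are distinct", {
  expect_error(extractCenterline(cordVolume(array(0, c(5, 5, 5)))),
               "empty")
  ph <- straightPhantom()
  low <- pointLabelAt(ph$mask, c(9, 9, 2))   # caudal to the mask
  expect_error(extractCenterline(ph$mask, low), "inferior")
})

test_that("arc length of analytic centerlines matches closed forms", {
  # straight vertical line at 1 mm spacing: distance at point k is k mm
  pts <- cbind(0, 0, seq(100, 0, by = -1))
  cl <- centerline(pts, pmjAnchored = TRUE)
  expect_equal(arcLengthFromPMJ(cl), 0:100)

  # quarter circle R = 50 sampled at 1 mm SI spacing: length pi R / 2
  R <- 50
  z <- seq(50, 0, by = -1)
  th <- asin(z / R)
  q <- cbind(0, R * cos(th), z)
  clq <- centerline(q)
  expect_lt(abs(max(arcLengthFromPMJ(clq)) / (pi * R / 2) - 1), 0.005)

  # helix, radius 10, pitch 40, two turns: length per turn
  # sqrt((2 pi r)^2 + pitch^2)
  r <- 10; pitch <- 40
  z <- seq(80, 0, by = -1)
  t <- 2 * pi * z / pitch
  hx <- cbind(r * cos(t), r * sin(t), z)
  clh <- centerline(hx)
  lTrue <- 2 * sqrt((2 * pi * r)^2 + pitch^2)
  expect_lt(abs(max(arcLengthFromPMJ(clh)) / lTrue - 1), 0.005)
})

test_that("extracted arc length agrees with the truth curve within 1%", {
  ph <- arcPhantom()   # bend radius 200 mm >= 100 mm regime
  cl <- extractCenterline(ph$mask, pmjLabelOf(ph))
  m <- match(ph$truth$slice, cl@sliceIndex)
  ok <- !is.na(m) & ph$truth$arc_length > 20
  expect_true(all(abs(cl@arcLength[m[ok]] / ph$truth$arc_length[ok] - 1)
                  < 0.01))
})

test_that("centerline arc length is bounded below by the straight distance", {
  for (ph in list(straightPhantom(), arcPhantom())) {
    cl <- extractCenterline(ph$mask, pmjLabelOf(ph))
    chord <- sqrt(sum((cl@points[nrow(cl@points), ] - cl@points[1, ])^2))
    expect_gte(max(cl@arcLength) + 1e-9, chord)
  }
})

test_that("stronger smoothing never lengthens the centerline", {
  ph <- arcPhantom()
  pmj <- pmjLabelOf(ph)
  lens <- vapply(c(0, 15, 30, 45), function(w) {
    max(arcLengthFromPMJ(extractCenterline(ph$mask, pmj, smoothing_mm = w)))
  }, 0)
  expect_true(all(diff(lens) <= 1e-9))
})

test_that("slicesInExtent selects the closed arc-length interval", {
  pts <- cbind(0, 0, seq(120, 0, by = -1))
  cl <- centerline(pts, sliceIndex = c(NA, 120:1), pmjAnchored = TRUE)

  sel <- slicesInExtent(cl, 64, 20)
  expect_length(sel, 21)
  expect_setequal(arcLengthFromPMJ(cl)[match(sel, cl@sliceIndex)], 54:74)

  expect_identical(slicesInExtent(cl, 64, 0),
                   cl@sliceIndex[which(arcLengthFromPMJ(cl) == 64)])
  expect_error(slicesInExtent(cl, 200, 20), "outside the centerline coverage")
})

test_that("curved-phantom extent slices all lie inside the arc-length band", {
  ph <- arcPhantom()
  cl <- extractCenterline(ph$mask, pmjLabelOf(ph))
  sel <- slicesInExtent(cl, 64, 20)
  truth <- ph$truth$arc_length[match(sel, ph$truth$slice)]
  expect_true(all(truth >= 53.5 & truth <= 74.5))  # rasterized vs true curve
})

test_that("mirrored volumes return the exact symmetry slice", {
  v <- mirroredVolume(center = 21)
  for (shift in c(-10, -5, 0, 5, 10)) {
    cand <- pointLabelAt(v, c(21 + shift, 16, 21))
    r <- findMedialSlice(v, cand, search_range_mm = 15)
    expect_identical(r$slice, 21L)
  }
})

test_that("a lateral blob outside the window does not move the symmetry slice", {
  v <- mirroredVolume(nx = 51, ny = 51, nz = 41, center = 26)
  d <- volumeData(v)
  d[40:44, 46:50, 5:9] <- 10              # bright off-axis blob, one side
  vb <- cordVolume(d, volumeAffine(v))
  cand <- pointLabelAt(vb, c(23, 26, 21))
  r <- findMedialSlice(vb, cand, window_mm = c(30, 30), window_si_mm = 20,
                       search_range_mm = 10)
  expect_identical(r$slice, 26L)
})

test_that("flat windows are rejected", {
  v <- cordVolume(array(1, c(31, 31, 31)))
  cand <- pointLabelAt(v, c(16, 16, 16))
  expect_error(findMedialSlice(v, cand), "constant")
})
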