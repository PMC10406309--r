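# Centerline geometry: per-slice centers of mass, PMJ anchoring,
# arc-length parameterization, extent selection, and the mirrored
# cross-correlation search for the right-left symmetry slice.

#' Build a Centerline from points
#'
#' Constructs a [Centerline-class] directly from ordered physical points
#' (superior first), computing cumulative arc-length and unit tangents.
#' Used by [extractCenterline()] and handy for analytic curves in tests.
#'
#' @param points n x 3 matrix of physical mm coordinates, superior first.
#' @param sliceIndex integer vector of 1-based axial slice indices (NA
#'   where a point is not tied to a slice, e.g. the PMJ anchor).
#' @param pmjAnchored logical; is the first point the PMJ?
#' @return a [Centerline-class].
#' @export
centerline <- function(points, sliceIndex = rep(NA_integer_, nrow(points)),
                       pmjAnchored = FALSE) {
  points <- as.matrix(points)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  new("Centerline", points = points,
      sliceIndex = as.integer(sliceIndex),
      arcLength = c(0, cumsum(seg)),
      tangents = .curveTangents(points),
      pmjAnchored = isTRUE(pmjAnchored))
}

# Hann-weighted local linear smoother over an arc-length window.
# Degree-1 local regression rather than a plain weighted mean so the
# one-sided windows at the ends of the centerline stay unbiased for
# straight segments (a weighted mean drags endpoints inward).
.hannSmooth <- function(y, s, window) {
  if (window <= 0) return(y)
  n <- length(y)
  out <- y
  for (i in seq_len(n)) {
    d <- s - s[i]
    w <- which(abs(d) <= window / 2)
    if (length(w) < 3L) next
    wt <- 0.5 * (1 + cos(2 * pi * d[w] / window))
    sw <- sum(wt); sx <- sum(wt * d[w]); sxx <- sum(wt * d[w]^2)
    sy <- sum(wt * y[w]); sxy <- sum(wt * d[w] * y[w])
    den <- sw * sxx - sx^2
    out[i] <- if (den < 1e-12) sy / sw else (sxx * sy - sx * sxy) / den
  }
  out
}

#' Extract the cord centerline from a binary segmentation
#'
#' Computes the center of mass of every axial slice containing mask
#' voxels, fills fully missing interior slices by linear interpolation of
#' the in-plane coordinates against slice index, optionally appends the
#' PMJ coordinate as the superior terminus, then smooths the in-plane
#' coordinates with a Hann-weighted local linear smoother over a
#' `smoothing_mm` arc-length window (the superior-inferior coordinate and
#' the PMJ anchor are never displaced). Tangents are central differences,
#' one-sided at the termini, renormalized to unit length.
#'
#' @param mask binary [CordVolume-class]; canonicalized internally.
#' @param pmj a [PointLabel-class] for the PMJ, or NULL to extract an
#'   unanchored centerline (used by the vertebral-level method). The PMJ
#'   must lie superior to the topmost mask slice (tolerance: 2 slices).
#' @param smoothing_mm arc-length window of the smoother; 0 disables
#'   smoothing.
#' @return a [Centerline-class], points ordered superior to inferior.
#' @export
extractCenterline <- function(mask, pmj = NULL, smoothing_mm = 30) {
  stopifnot(is(mask, "CordVolume"))
  mask <- canonicalize(mask)
  d <- mask@data
  if (!all(d %in% c(0, 1)))
    stop("extractCenterline: mask must be binary (0/1)")
  idx <- which(d == 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("extractCenterline: mask is empty")

  ks <- sort(unique(idx[, 3]))
  ci <- tapply(idx[, 1], idx[, 3], mean)
  cj <- tapply(idx[, 2], idx[, 3], mean)
  kk <- as.integer(names(ci))
  full <- seq(min(ks), max(ks))
  # fill fully-missing interior slices by linear interpolation vs slice index
  ifull <- stats::approx(kk, ci, xout = full)$y
  jfull <- stats::approx(kk, cj, xout = full)$y

  vox <- cbind(ifull, jfull, full)
  phys <- voxelToPhysical(mask, vox)
  ord <- order(phys[, 3], decreasing = TRUE)    # superior first
  phys <- phys[ord, , drop = FALSE]
  slices <- full[ord]
  hz <- voxelSizes(mask)[3]

  anchored <- !is.null(pmj)
  if (anchored) {
    stopifnot(is(pmj, "PointLabel"))
    ztop <- phys[1, 3]
    if (pmj@physical[3] < ztop - 2 * hz)
      stop("extractCenterline: PMJ lies inferior to the top of the mask; ",
           "check orientation/labeling")
    keep <- phys[, 3] < pmj@physical[3]  # drop mask slices at/above the PMJ
    phys <- phys[keep, , drop = FALSE]
    slices <- slices[keep]
    phys <- rbind(pmj@physical, phys)
    slices <- c(NA_integer_, slices)
  }
  if (nrow(phys) < 2L)
    stop("extractCenterline: fewer than 2 centerline points")

  if (smoothing_mm > 0 && nrow(phys) > 3L) {
    seg <- sqrt(rowSums(diff(phys)^2))
    s0 <- c(0, cumsum(seg))                 # provisional arc-length
    # never displace the anchor: smooth every point except the PMJ
    sel <- if (anchored) seq_len(nrow(phys)) > 1L else
             rep(TRUE, nrow(phys))
    xs <- .hannSmooth(phys[sel, 1], s0[sel], smoothing_mm)
    ys <- .hannSmooth(phys[sel, 2], s0[sel], smoothing_mm)
    phys[sel, 1] <- xs
    phys[sel, 2] <- ys
  }
  centerline(phys, slices, pmjAnchored = anchored)
}

#' Arc-length distance from the PMJ
#'
#' Cumulative polyline distance from the centerline's superior terminus
#' (the PMJ when anchored), one value per centerline point.
#'
#' @param cl a [Centerline-class].
#' @return numeric vector of distances in mm.
#' @export
arcLengthFromPMJ <- function(cl) {
  stopifnot(is(cl, "Centerline"))
  cl@arcLength
}

#' Axial slices within an arc-length extent
#'
#' Returns the 1-based axial slice indices whose centerline arc-length
#' from the PMJ lies in the closed interval
#' [distance_mm - extent_mm/2, distance_mm + extent_mm/2].
#'
#' @param cl a [Centerline-class].
#' @param distance_mm center of the extent (mm from the PMJ; the reference
#'   distance is 64 mm).
#' @param extent_mm width of the extent (20 mm by default upstream); 0
#'   selects the single nearest slice.
#' @return integer vector of slice indices.
#' @export
slicesInExtent <- function(cl, distance_mm, extent_mm) {
  stopifnot(is(cl, "Centerline"), extent_mm >= 0)
  onSlice <- !is.na(cl@sliceIndex)
  s <- cl@arcLength
  if (extent_mm == 0) {
    cand <- which(onSlice)
    return(cl@sliceIndex[cand[which.min(abs(s[cand] - distance_mm))]])
  }
  lo <- distance_mm - extent_mm / 2
  hi <- distance_mm + extent_mm / 2
  sel <- onSlice & s >= lo & s <= hi
  if (!any(sel)) {
    rng <- range(s[onSlice])
    stop(sprintf(paste0("slicesInExtent: requested span [%.1f, %.1f] mm is ",
                        "outside the centerline coverage [%.1f, %.1f] mm ",
                        "from the PMJ"), lo, hi, rng[1], rng[2]))
  }
  cl@sliceIndex[sel]
}

#' Find the right-left symmetry slice by mirrored cross-correlation
#'
#' For each sagittal slice within `search_range_mm` of a candidate point's
#' right-left position, extracts a window centered on the candidate
#' in-plane and on the test slice along right-left, and computes the
#' normalized cross-correlation between the window and its mirror image in
#' the right-left orientation. The slice maximizing the correlation is
#' taken as the right-left symmetry slice (used to refine a mid-sagittal
#' PMJ candidate into the anatomical medial plane).
#'
#' @param image a [CordVolume-class] (intensity image or mask);
#'   canonicalized internally.
#' @param candidate a [PointLabel-class] marking the starting point.
#' @param window_mm length-2 in-plane window size (right-left,
#'   anterior-posterior) in mm.
#' @param search_range_mm half-range of the sagittal search around the
#'   candidate, in mm.
#' @param window_si_mm superior-inferior window span in mm, or NULL for
#'   the volume's full span.
#' @return list with `slice` (the 1-based sagittal index of the symmetry
#'   slice) and `profile` (data.frame of slice and correlation score).
#' @export
findMedialSlice <- function(image, candidate, window_mm = c(30, 30),
                            search_range_mm = 15, window_si_mm = NULL) {
  stopifnot(is(image, "CordVolume"), is(candidate, "PointLabel"))
  image <- canonicalize(image)
  d <- image@data
  dm <- dim(d)
  h <- voxelSizes(image)
  vox <- round(physicalToVoxel(image, candidate@physical))
  if (any(vox < 1) || any(vox > dm))
    stop("findMedialSlice: candidate lies outside the volume")
  i0 <- vox[1]

  wy <- max(1L, round(window_mm[2] / 2 / h[2]))
  ylo <- vox[2] - wy; yhi <- vox[2] + wy
  if (ylo < 1 || yhi > dm[2]) {
    clip <- max(1 - ylo, yhi - dm[2])
    warning("findMedialSlice: window exceeds grid along anterior-posterior; ",
            "clipped symmetrically by ", clip, " voxels")
    ylo <- ylo + clip; yhi <- yhi - clip
  }
  if (is.null(window_si_mm)) {
    zlo <- 1L; zhi <- dm[3]
  } else {
    wz <- max(1L, round(window_si_mm / 2 / h[3]))
    zlo <- vox[3] - wz; zhi <- vox[3] + wz
    if (zlo < 1 || zhi > dm[3]) {
      clip <- max(1 - zlo, zhi - dm[3])
      warning("findMedialSlice: window exceeds grid along superior-inferior; ",
              "clipped symmetrically by ", clip, " voxels")
      zlo <- zlo + clip; zhi <- zhi - clip
    }
  }
  wx <- max(1L, round(window_mm[1] / 2 / h[1]))
  sr <- round(search_range_mm / h[1])
  cand <- seq(max(2L, i0 - sr), min(dm[1] - 1L, i0 + sr))

  score <- rep(NA_real_, length(cand))
  for (m in seq_along(cand)) {
    i <- cand[m]
    wxi <- min(wx, i - 1L, dm[1] - i)   # keep the mirror inside the grid
    A <- d[(i - wxi):(i + wxi), ylo:yhi, zlo:zhi, drop = FALSE]
    if (stats::sd(A) == 0) next      # flat block at this test slice
    B <- A[dim(A)[1]:1, , , drop = FALSE]
    score[m] <- stats::cor(as.vector(A), as.vector(B))
  }
  if (all(is.na(score)))
    stop("findMedialSlice: window is constant over the whole search range; ",
         "correlation undefined")
  best <- cand[which.max(replace(score, is.na(score), -Inf))]
  list(slice = best, profile = data.frame(slice = cand, score = score))
}
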