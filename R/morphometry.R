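# Slice-wise angulation-corrected CSA and the two aggregate measures:
# PMJ-referenced (distance + extent along the centerline) and vertebral
# (C2-C3 disc span).

#' Slice-wise angulation-corrected cross-sectional areas
#'
#' For every axial slice with mask voxels: planar area = voxel count x
#' in-plane pixel area; angle = angle between the centerline tangent and
#' the superior-inferior axis (the axial slice normal); corrected area =
#' planar area x cos(angle) - the standard cosine correction estimating
#' the area perpendicular to the cord.
#'
#' @param mask binary [CordVolume-class]; canonicalized internally.
#' @param cl a [Centerline-class] covering every mask slice.
#' @return data.frame with columns `slice`, `planar_area`, `angle`
#'   (radians), `corrected_area`, and `distance_pmj` (NA when the
#'   centerline is not PMJ-anchored).
#' @export
sliceMetrics <- function(mask, cl) {
  stopifnot(is(mask, "CordVolume"), is(cl, "Centerline"))
  mask <- canonicalize(mask)
  d <- mask@data
  if (!all(d %in% c(0, 1)))
    stop("sliceMetrics: mask must be binary (0/1)")
  h <- voxelSizes(mask)
  pixArea <- h[1] * h[2]
  counts <- apply(d, 3, sum)
  ks <- which(counts > 0)
  if (!length(ks)) stop("sliceMetrics: mask is empty")

  m <- match(ks, cl@sliceIndex)
  if (anyNA(m))
    stop("sliceMetrics: centerline has no point for mask slice(s) ",
         paste(ks[is.na(m)], collapse = ", "), "; centerline incomplete")
  tz <- abs(cl@tangents[m, 3])
  angle <- acos(pmin(1, tz))
  planar <- counts[ks] * pixArea
  data.frame(slice = ks,
             planar_area = planar,
             angle = angle,
             corrected_area = planar * cos(angle),
             distance_pmj = if (cl@pmjAnchored) cl@arcLength[m]
                            else NA_real_)
}

.csaResult <- function(metrics, slices, method, reference) {
  rows <- metrics[metrics$slice %in% slices, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("CSA extent selects no mask slices")
  new("CsaResult", value = mean(rows$corrected_area), method = method,
      reference = reference, nSlices = nrow(rows), perSlice = rows)
}

#' PMJ-referenced cross-sectional area
#'
#' Extracts the PMJ-anchored centerline, computes slice-wise corrected
#' areas, and averages them (unweighted) over the axial slices whose
#' arc-length from the PMJ lies within `extent_mm` centered at
#' `distance_mm`. The defaults - 64 mm from the PMJ, 20 mm extent -
#' correspond to the mean PMJ-to-C2-C3-disc distance in adults.
#'
#' @param mask binary cord segmentation ([CordVolume-class]).
#' @param pmj PMJ landmark: a [PointLabel-class], or a label
#'   [CordVolume-class] containing the PMJ code.
#' @param distance_mm arc-length distance of the extent center from the
#'   PMJ (mm).
#' @param extent_mm extent width (mm).
#' @param smoothing_mm centerline smoothing window (mm).
#' @param pmj_code label code of the PMJ in a label volume (default 50).
#' @return a [CsaResult-class].
#' @examples
#' ph <- makeTubePhantom(phantomSpec("straight", radius_mm = 5))
#' res <- csaPMJ(ph$mask, ph$labels)
#' csaValue(res)  # ~ pi * 25 mm^2
#' @export
csaPMJ <- function(mask, pmj, distance_mm = 64, extent_mm = 20,
                   smoothing_mm = 30, pmj_code = 50L) {
  pmj <- .asPointLabel(pmj, pmj_code, "PMJ")
  cl <- extractCenterline(mask, pmj, smoothing_mm = smoothing_mm)
  metrics <- sliceMetrics(mask, cl)
  slices <- slicesInExtent(cl, distance_mm, extent_mm)
  .csaResult(metrics, slices, "pmj",
             list(distance_mm = distance_mm, extent_mm = extent_mm))
}

#' Vertebral-level cross-sectional area (C2-C3)
#'
#' Averages slice-wise corrected areas over the axial slices whose
#' centerline point lies (in physical superior-inferior position) between
#' two disc landmarks - by default the C1-C2 disc (code 2) and the C3-C4
#' disc (code 4), i.e. the span of vertebral levels C2 and C3. The
#' interval is closed at both ends.
#'
#' @param mask binary cord segmentation ([CordVolume-class]).
#' @param discs disc landmarks: a list of [PointLabel-class] or a label
#'   [CordVolume-class].
#' @param upper_code,lower_code label codes bounding the span (2 = C1-C2
#'   disc above, 4 = C3-C4 disc below, the SCT convention).
#' @param smoothing_mm centerline smoothing window (mm).
#' @return a [CsaResult-class].
#' @export
csaVertebral <- function(mask, discs, upper_code = 2L, lower_code = 4L,
                         smoothing_mm = 30) {
  if (is(discs, "CordVolume")) discs <- extractPointLabels(discs)
  if (is(discs, "PointLabel")) discs <- list(discs)
  up <- .findLabel(discs, upper_code)
  lo <- .findLabel(discs, lower_code)
  if (is.null(up))
    stop("csaVertebral: missing disc label with code ", upper_code)
  if (is.null(lo))
    stop("csaVertebral: missing disc label with code ", lower_code)
  cl <- extractCenterline(mask, pmj = NULL, smoothing_mm = smoothing_mm)
  metrics <- sliceMetrics(mask, cl)
  zhi <- max(up@physical[3], lo@physical[3])
  zlo <- min(up@physical[3], lo@physical[3])
  onSlice <- !is.na(cl@sliceIndex)
  z <- cl@points[, 3]
  slices <- cl@sliceIndex[onSlice & z >= zlo & z <= zhi]
  if (!length(slices))
    stop("csaVertebral: no centerline slices between the disc labels")
  .csaResult(metrics, slices, "vertebral",
             list(upper_code = upper_code, lower_code = lower_code,
                  span_mm = c(zlo, zhi)))
}

.asPointLabel <- function(x, code, what) {
  if (is(x, "PointLabel")) return(x)
  if (is(x, "CordVolume")) {
    l <- .findLabel(extractPointLabels(x), code)
    if (is.null(l))
      stop("no ", what, " label with code ", code, " in label volume")
    return(l)
  }
  stop(what, " must be a PointLabel or a label CordVolume")
}

#' Paired comparison of two CSA measurement methods
#'
#' Two-sided paired t-test between per-participant CSA values from two
#' methods, plus per-method mean, STD, median and coefficient of
#' variation.
#'
#' @param a,b numeric vectors of CSA values (or lists of
#'   [CsaResult-class]), equal length, same participant order.
#' @return list with `mean_difference` (mean of a - b), `t`, `p`, `df`,
#'   `n`, and a `summary` data.frame (one row per method).
#' @export
compareMethods <- function(a, b) {
  if (is.list(a)) a <- vapply(a, csaValue, 0)
  if (is.list(b)) b <- vapply(b, csaValue, 0)
  if (length(a) != length(b))
    stop("compareMethods: lengths differ (", length(a), " vs ", length(b), ")")
  if (length(a) < 2L) stop("compareMethods: need at least 2 pairs")
  diffs <- a - b
  if (stats::sd(diffs) == 0) {
    # degenerate pairs: identical lists give t = 0; a constant non-zero
    # offset is infinitely significant
    tt <- if (mean(diffs) == 0)
      list(statistic = c(t = 0), p.value = 1,
           parameter = c(df = length(a) - 1))
    else
      list(statistic = c(t = sign(mean(diffs)) * Inf), p.value = 0,
           parameter = c(df = length(a) - 1))
  } else {
    tt <- stats::t.test(a, b, paired = TRUE)
  }
  summ <- data.frame(
    method = c("a", "b"),
    mean = c(mean(a), mean(b)),
    std = c(stats::sd(a), stats::sd(b)),
    median = c(stats::median(a), stats::median(b)),
    cov = c(covPercent(a), covPercent(b)))
  list(mean_difference = mean(diffs),
       t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), n = length(a), summary = summ)
}
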