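#' @import methods
NULL

#' CordVolume: a 3D scalar grid with a voxel-to-physical affine
#'
#' Container for NIfTI-backed volumes (images, binary cord segmentations,
#' point-label volumes). The affine maps 0-based voxel indices to physical
#' millimetre coordinates in the scanner RAS frame (x increasing toward the
#' participant's Right, y toward Anterior, z toward Superior). R-facing
#' array indices are the usual 1-based ones; [voxelToPhysical()] does the
#' off-by-one conversion.
#'
#' @slot data 3D numeric array (unitless for masks and label volumes).
#' @slot affine 4x4 matrix, voxel (0-based) to physical mm.
#' @slot orientation three-letter code giving the anatomical direction in
#'   which each grid axis increases (e.g. "RAS", "LPI"), derived from the
#'   affine's dominant directions.
#'
#' @seealso [readVolume()], [canonicalize()], [voxelToPhysical()]
#' @export
setClass("CordVolume",
         representation(data = "array", affine = "matrix",
                        orientation = "character"))

setValidity("CordVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be 4x4")
  else {
    if (abs(det(object@affine[1:3, 1:3])) < 1e-12)
      msg <- c(msg, "affine is singular")
    if (any(sqrt(colSums(object@affine[1:3, 1:3]^2)) <= 0))
      msg <- c(msg, "voxel sizes must be strictly positive")
  }
  if (length(object@orientation) != 1L || nchar(object@orientation) != 3L)
    msg <- c(msg, "orientation must be a single 3-letter code")
  if (length(msg)) msg else TRUE
})

#' PointLabel: a single-voxel anatomical landmark
#'
#' One labelled voxel from a point-label volume, e.g. the pontomedullary
#' junction (code 50) or the posterior tip of an intervertebral disc
#' (C1-C2 = 2, C2-C3 = 3, C3-C4 = 4, following the SCT convention).
#'
#' @slot value integer label code.
#' @slot voxel 0-based voxel index triple.
#' @slot physical physical mm coordinate (affine applied to the voxel index).
#' @export
setClass("PointLabel",
         representation(value = "integer", voxel = "numeric",
                        physical = "numeric"))

setValidity("PointLabel", function(object) {
  msg <- character()
  if (length(object@voxel) != 3L) msg <- c(msg, "voxel must have length 3")
  if (length(object@physical) != 3L) msg <- c(msg, "physical must have length 3")
  if (length(object@value) != 1L || is.na(object@value) || object@value <= 0L)
    msg <- c(msg, "value must be a single positive integer")
  if (length(msg)) msg else TRUE
})

#' Centerline: ordered cord centerline points with arc-length and tangents
#'
#' Physical-space polyline through the per-slice cord centers, ordered
#' superior to inferior, optionally anchored at the PMJ as its first point.
#' Arc length is the cumulative polyline distance from the first point
#' (0 at the PMJ when anchored).
#'
#' @slot points n x 3 matrix of physical mm coordinates.
#' @slot sliceIndex integer vector of 1-based axial slice indices
#'   (NA for the PMJ anchor, which does not sit on a mask slice).
#' @slot arcLength cumulative mm distance from the first point.
#' @slot tangents n x 3 matrix of unit tangents (pointing caudally).
#' @slot pmjAnchored logical; TRUE when the first point is the PMJ.
#' @export
setClass("Centerline",
         representation(points = "matrix", sliceIndex = "integer",
                        arcLength = "numeric", tangents = "matrix",
                        pmjAnchored = "logical"))

setValidity("Centerline", function(object) {
  msg <- character()
  n <- nrow(object@points)
  if (ncol(object@points) != 3L) msg <- c(msg, "points must be n x 3")
  if (n < 2L) msg <- c(msg, "centerline needs at least 2 points")
  if (length(object@arcLength) != n || length(object@sliceIndex) != n)
    msg <- c(msg, "arcLength/sliceIndex length must match points")
  if (!all(dim(object@tangents) == dim(object@points)))
    msg <- c(msg, "tangents must match points in shape")
  if (n >= 2L) {
    if (object@arcLength[1L] != 0) msg <- c(msg, "arcLength must start at 0")
    if (any(diff(object@arcLength) <= 0))
      msg <- c(msg, "arcLength must be strictly increasing")
    nrm <- sqrt(rowSums(object@tangents^2))
    if (any(abs(nrm - 1) > 1e-8)) msg <- c(msg, "tangents must have unit norm")
  }
  if (length(msg)) msg else TRUE
})

#' CsaResult: an aggregated cross-sectional area measurement
#'
#' @slot value mean angulation-corrected CSA in mm^2 over the contributing
#'   slices (unweighted).
#' @slot method "pmj" (distance-from-PMJ reference) or "vertebral"
#'   (C2-C3 disc span).
#' @slot reference named list describing the reference (distance/extent in mm
#'   for the PMJ method; the disc codes bounding the span for vertebral).
#' @slot nSlices number of contributing slices.
#' @slot perSlice data.frame of slice-wise metrics (slice, planar_area,
#'   angle, corrected_area, distance_pmj when available).
#' @export
setClass("CsaResult",
         representation(value = "numeric", method = "character",
                        reference = "list", nSlices = "integer",
                        perSlice = "data.frame"))

setValidity("CsaResult", function(object) {
  msg <- character()
  if (!object@method %in% c("pmj", "vertebral"))
    msg <- c(msg, "method must be 'pmj' or 'vertebral'")
  if (object@nSlices < 1L) msg <- c(msg, "nSlices must be >= 1")
  if (length(msg)) msg else TRUE
})

#' NormalizationModel: regression-residual CSA normalization coefficients
#'
#' Holds everything needed to apply
#' CSA_norm = CSA_meas + sum_j c_j (X_j,mean - X_j,meas)
#' and the z-score (CSA_norm - mu_norm) / sigma_norm.
#'
#' Interaction predictors are named "sex:<predictor>" and are raw products
#' of sex (0 = female, 1 = male) with the predictor; their means are means
#' of the product.
#'
#' @slot id short model identifier (e.g. "M2-PMJ").
#' @slot predictors ordered predictor names.
#' @slot coefficients residual coefficients c_j (mm^2 per predictor unit).
#' @slot means predictor means X_j,mean.
#' @slot muNorm mean of the normalized CSA (mm^2).
#' @slot sigmaNorm STD of the normalized CSA (mm^2), > 0.
#' @slot reference "pmj" or "c2c3".
#' @slot provenance "published" or "refit".
#' @slot note free-text caveat shown by the show method (e.g. the published
#'   C2-C3 sex coefficient whose printed magnitude is inconsistent).
#' @export
setClass("NormalizationModel",
         representation(id = "character", predictors = "character",
                        coefficients = "numeric", means = "numeric",
                        muNorm = "numeric", sigmaNorm = "numeric",
                        reference = "character", provenance = "character",
                        note = "character"))

setValidity("NormalizationModel", function(object) {
  msg <- character()
  p <- length(object@predictors)
  if (length(object@coefficients) != p || length(object@means) != p)
    msg <- c(msg, "coefficients and means must align with predictors")
  if (!identical(names(object@coefficients), object@predictors) ||
      !identical(names(object@means), object@predictors))
    msg <- c(msg, "coefficients/means must be named by predictors")
  if (object@sigmaNorm <= 0) msg <- c(msg, "sigmaNorm must be > 0")
  if (!object@reference %in% c("pmj", "c2c3"))
    msg <- c(msg, "reference must be 'pmj' or 'c2c3'")
  if (!object@provenance %in% c("published", "refit"))
    msg <- c(msg, "provenance must be 'published' or 'refit'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CordVolume", function(object) {
  d <- dim(object@data)
  vs <- sqrt(colSums(object@affine[1:3, 1:3]^2))
  cat(sprintf("CordVolume %d x %d x %d  (%s)\n", d[1], d[2], d[3],
              object@orientation))
  cat(sprintf("  voxel size: %.3g x %.3g x %.3g mm\n", vs[1], vs[2], vs[3]))
  cat(sprintf("  data range: [%g, %g]\n", min(object@data), max(object@data)))
})

setMethod("show", "PointLabel", function(object) {
  cat(sprintf("PointLabel %d at voxel (%g, %g, %g), %.2f/%.2f/%.2f mm\n",
              object@value, object@voxel[1], object@voxel[2], object@voxel[3],
              object@physical[1], object@physical[2], object@physical[3]))
})

setMethod("show", "Centerline", function(object) {
  cat(sprintf("Centerline: %d points%s, arc length %.2f mm\n",
              nrow(object@points),
              if (object@pmjAnchored) " (PMJ-anchored)" else "",
              max(object@arcLength)))
})

setMethod("show", "CsaResult", function(object) {
  ref <- paste(names(object@reference),
               vapply(object@reference, function(x) paste(x, collapse = ":"),
                      ""), sep = "=", collapse = ", ")
  cat(sprintf("CsaResult [%s]: %.3f mm^2 over %d slices (%s)\n",
              object@method, object@value, object@nSlices, ref))
})

setMethod("show", "NormalizationModel", function(object) {
  cat(sprintf("NormalizationModel %s (%s, %s reference)\n",
              object@id, object@provenance, object@reference))
  for (p in object@predictors)
    cat(sprintf("  %-22s c = %12.5g   mean = %12.6g\n",
                p, object@coefficients[[p]], object@means[[p]]))
  cat(sprintf("  mu_norm = %.2f mm^2, sigma_norm = %.2f mm^2\n",
              object@muNorm, object@sigmaNorm))
  if (length(object@note) && nzchar(object@note))
    cat("  note:", object@note, "\n")
})
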