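#' @rdname accessors
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))

#' @rdname accessors
#' @export
setGeneric("volumeAffine", function(x) standardGeneric("volumeAffine"))

#' @rdname accessors
#' @export
setGeneric("orientationCode", function(x) standardGeneric("orientationCode"))

#' @rdname accessors
#' @export
setGeneric("voxelSizes", function(x) standardGeneric("voxelSizes"))

#' Canonicalize a volume's axis order
#'
#' Permutes and flips grid axes so that axis 1 is the right-left axis
#' (increasing toward the Right), axis 2 anterior-posterior (toward
#' Anterior) and axis 3 inferior-superior (toward Superior) - the RAS
#' convention. The affine is updated so every voxel keeps its physical
#' coordinate; no resampling takes place. Idempotent.
#'
#' @param x a [CordVolume-class].
#' @param tol_deg maximum allowed obliquity (angle between each grid axis
#'   and its nearest anatomical axis) in degrees; beyond it the volume
#'   cannot be canonicalized by permutation/flip alone and an error asks
#'   for resampling, which is outside this package's scope.
#' @return a canonical [CordVolume-class].
#' @export
setGeneric("canonicalize", function(x, tol_deg = 20) standardGeneric("canonicalize"))

#' @rdname accessors
#' @export
setGeneric("arcLength", function(x) standardGeneric("arcLength"))

#' @rdname accessors
#' @export
setGeneric("tangents", function(x) standardGeneric("tangents"))

#' @rdname accessors
#' @export
setGeneric("centerPoints", function(x) standardGeneric("centerPoints"))

#' @rdname accessors
#' @export
setGeneric("csaValue", function(x) standardGeneric("csaValue"))

#' @rdname accessors
#' @export
setGeneric("perSliceMetrics", function(x) standardGeneric("perSliceMetrics"))

#' @rdname accessors
#' @export
setGeneric("modelPredictors", function(x) standardGeneric("modelPredictors"))

#' @rdname accessors
#' @export
setGeneric("modelCoefficients", function(x) standardGeneric("modelCoefficients"))

#' @rdname accessors
#' @export
setGeneric("modelMeans", function(x) standardGeneric("modelMeans"))

#' @rdname accessors
#' @export
setGeneric("modelMu", function(x) standardGeneric("modelMu"))

#' @rdname accessors
#' @export
setGeneric("modelSigma", function(x) standardGeneric("modelSigma"))

#' Accessors for pmjcsa S4 objects
#'
#' Read-only accessors for the slots of [CordVolume-class],
#' [Centerline-class], [CsaResult-class] and [NormalizationModel-class].
#'
#' @param x the object.
#' @return the corresponding slot value.
#' @name accessors
NULL

setMethod("volumeData", "CordVolume", function(x) x@data)
setMethod("volumeAffine", "CordVolume", function(x) x@affine)
setMethod("orientationCode", "CordVolume", function(x) x@orientation)
setMethod("voxelSizes", "CordVolume",
          function(x) sqrt(colSums(x@affine[1:3, 1:3]^2)))
setMethod("arcLength", "Centerline", function(x) x@arcLength)
setMethod("tangents", "Centerline", function(x) x@tangents)
setMethod("centerPoints", "Centerline", function(x) x@points)
setMethod("csaValue", "CsaResult", function(x) x@value)
setMethod("perSliceMetrics", "CsaResult", function(x) x@perSlice)
setMethod("modelPredictors", "NormalizationModel", function(x) x@predictors)
setMethod("modelCoefficients", "NormalizationModel", function(x) x@coefficients)
setMethod("modelMeans", "NormalizationModel", function(x) x@means)
setMethod("modelMu", "NormalizationModel", function(x) x@muNorm)
setMethod("modelSigma", "NormalizationModel", function(x) x@sigmaNorm)
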