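# NIfTI I/O and coordinate plumbing. All downstream geometry works in
# physical millimetres; the only place voxel indices touch physical space
# is through the affine handled here.

.affineOrientation <- function(affine) {
  pos <- c("R", "A", "S"); neg <- c("L", "P", "I")
  code <- character(3)
  for (j in 1:3) {
    col <- affine[1:3, j]
    w <- which.max(abs(col))
    code[j] <- if (col[w] >= 0) pos[w] else neg[w]
  }
  paste(code, collapse = "")
}

.newCordVolume <- function(data, affine) {
  data <- array(as.double(data), dim(data))   # strip classes/attributes
  affine <- matrix(as.double(affine), 4, 4)
  new("CordVolume", data = data, affine = affine,
      orientation = .affineOrientation(affine))
}

#' Construct a CordVolume from an array and affine
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel (0-based) to physical mm transform; defaults to
#'   identity (1 mm isotropic voxels at the origin).
#' @return a [CordVolume-class].
#' @examples
#' v <- cordVolume(array(0, c(5, 5, 5)))
#' voxelSizes(v)
#' @export
cordVolume <- function(data, affine = diag(4)) .newCordVolume(data, affine)

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 file into a [CordVolume-class] without resampling; the
#' orientation code is derived from the affine.
#'
#' @param path path to a .nii or .nii.gz file.
#' @return a [CordVolume-class].
#' @seealso [writeVolume()], [canonicalize()]
#' @export
readVolume <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("readVolume: file not found: ", path)
  img <- RNifti::readNifti(path)
  dat <- as.array(img)
  dm <- dim(dat)
  if (length(dm) == 4L && dm[4] == 1L) { # trivially 4D files are common
    dat <- array(dat, dm[1:3])
    dm <- dim(dat)
  }
  if (length(dm) != 3L)
    stop("readVolume: image is not 3-dimensional (dims: ",
         paste(dm, collapse = "x"), "): ", path)
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = dim(aff))
  if (abs(det(aff[1:3, 1:3])) < 1e-12)
    stop("readVolume: affine is singular in ", path)
  .newCordVolume(dat, aff)
}

#' Write a CordVolume to a NIfTI file
#'
#' The affine is stored in the sform (code 2); data are written as float64
#' so a read-back is bit-identical.
#'
#' @param x a [CordVolume-class].
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path) {
  stopifnot(is(x, "CordVolume"))
  img <- RNifti::asNifti(x@data, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(x@affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Convert between voxel indices and physical coordinates
#'
#' `voxelToPhysical` applies the affine to 1-based R array indices (the -1
#' to the NIfTI 0-based convention happens internally); `physicalToVoxel`
#' inverts it and returns fractional 1-based indices.
#'
#' @param x a [CordVolume-class].
#' @param idx n x 3 matrix (or length-3 vector) of 1-based voxel indices.
#' @param pos n x 3 matrix (or length-3 vector) of physical mm coordinates.
#' @return n x 3 matrix of coordinates.
#' @export
voxelToPhysical <- function(x, idx) {
  idx <- rbind(idx)
  t(x@affine %*% rbind(t(idx) - 1, 1))[, 1:3, drop = FALSE]
}

#' @rdname voxelToPhysical
#' @export
physicalToVoxel <- function(x, pos) {
  pos <- rbind(pos)
  t(solve(x@affine) %*% rbind(t(pos), 1))[, 1:3, drop = FALSE] + 1
}

setMethod("canonicalize", "CordVolume", function(x, tol_deg = 20) {
  aff <- x@affine
  R <- aff[1:3, 1:3]
  cn <- sqrt(colSums(R^2))
  world <- integer(3); sgn <- numeric(3)
  for (j in 1:3) {
    w <- which.max(abs(R[, j]))
    cosang <- abs(R[w, j]) / cn[j]
    if (cosang < cos(tol_deg * pi / 180))
      stop("canonicalize: volume is oblique (grid axis ", j, " is ",
           sprintf("%.1f", acos(min(1, cosang)) * 180 / pi),
           " degrees from its nearest anatomical axis, tolerance ", tol_deg,
           "); resample the image before use")
    world[j] <- w
    sgn[j] <- sign(R[w, j])
  }
  if (anyDuplicated(world))
    stop("canonicalize: affine does not define three distinct anatomical axes")
  perm <- order(world)            # data axis to use for world axis 1,2,3
  dat <- aperm(x@data, perm)
  aff2 <- aff
  aff2[, 1:3] <- aff[, perm]
  sgn <- sgn[perm]
  for (k in 1:3) {
    if (sgn[k] < 0) {
      n <- dim(dat)[k]
      idx <- switch(k,
                    list(n:1, TRUE, TRUE),
                    list(TRUE, n:1, TRUE),
                    list(TRUE, TRUE, n:1))
      dat <- do.call(`[`, c(list(dat), idx, list(drop = FALSE)))
      aff2[, 4] <- aff2[, 4] + aff2[, k] * (n - 1)
      aff2[, k] <- -aff2[, k]
    }
  }
  .newCordVolume(dat, aff2)
})

#' Extract single-voxel point labels from a label volume
#'
#' A label volume is zero everywhere except isolated voxels carrying
#' integer codes (PMJ = 50; discs C1-C2 = 2, C2-C3 = 3, C3-C4 = 4 in the
#' SCT convention). Each distinct non-zero value must occupy exactly one
#' voxel; duplicates make the landmark ambiguous and raise an error.
#'
#' @param x a [CordVolume-class] containing non-negative integers.
#' @return a list of [PointLabel-class], sorted by label value.
#' @export
extractPointLabels <- function(x) {
  stopifnot(is(x, "CordVolume"))
  d <- x@data
  if (any(d < 0) || any(d != round(d)))
    stop("extractPointLabels: label volume must contain non-negative integers")
  vals <- sort(unique(d[d != 0]))
  out <- vector("list", length(vals))
  for (i in seq_along(vals)) {
    idx <- which(d == vals[i], arr.ind = TRUE)
    if (nrow(idx) > 1L)
      stop("extractPointLabels: label value ", vals[i], " occupies ",
           nrow(idx), " voxels; landmark is ambiguous")
    phys <- voxelToPhysical(x, idx[1, ])
    out[[i]] <- new("PointLabel", value = as.integer(vals[i]),
                    voxel = as.numeric(idx[1, ]) - 1,
                    physical = as.numeric(phys))
  }
  out
}

# find one label by code in a list of PointLabels
.findLabel <- function(labels, code) {
  for (l in labels) if (l@value == code) return(l)
  NULL
}
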