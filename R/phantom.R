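# Synthetic cord phantoms: curved tubes voxelized onto a grid with
# analytically known centerline, arc-length and per-slice CSA. These stand
# in for real segmentations so every geometric operation can be checked
# against closed forms.

#' Specify a tube phantom
#'
#' Defines a tubular "cord" around a parametric curve. The curve is
#' parameterized by height u in [0, extent_si] (u = extent_si is the
#' superior end), optionally tilted, and voxelized by voxel-center
#' membership: a voxel belongs to the mask iff its center lies within the
#' local tube radius of the curve. The PMJ sits at the superior end of the
#' curve; the mask (the "segmentation") only starts `pmj_offset` mm of arc
#' below it, mimicking real segmentations that stop short of the PMJ.
#'
#' Grid placement is deterministic: the mean in-plane curve position is
#' set 0.5 mm off the voxel-center lattice (avoids degenerate boundary
#' ties when the tube axis is grid-aligned) and a voxel center is aligned
#' with the curve's superior end in z.
#'
#' @param curve "straight", "arc" (circular arc of radius `arc_radius_mm`
#'   in the sagittal y-z plane) or "poly" (polynomial in-plane offsets).
#' @param radius_mm tube radius: a positive scalar or a function of
#'   arc-length from the PMJ (mm) returning mm.
#' @param extent_si_mm superior-inferior span of the curve (mm).
#' @param voxel_size_mm voxel size, scalar (isotropic) or length-3 triple.
#' @param tilt_deg length-2 rotation (degrees) about the x (right-left)
#'   then y (anterior-posterior) axis, applied to the whole curve around
#'   its midpoint.
#' @param pmj_offset_mm arc-length gap between the PMJ (curve top) and the
#'   first mask slice.
#' @param arc_radius_mm bend radius for `curve = "arc"`.
#' @param poly_x,poly_y polynomial coefficients (intercept first) for the
#'   lateral/anterior offsets as functions of height, for `curve = "poly"`.
#' @param disc_arcs_mm named numeric vector placing disc labels at given
#'   arc-lengths from the PMJ; names are integer label codes (e.g.
#'   `c("2" = 54, "4" = 74)`).
#' @param margin_vox in-plane grid margin around the tube, in voxels (>= 2).
#' @param grid_dim,grid_origin optional explicit grid (dimensions and
#'   physical position of the first voxel center); when given, the tube
#'   must fit inside with the margin or an error names the violation.
#' @param curve_step_mm spacing of the dense curve samples used for
#'   voxelization and ground truth.
#' @return a list of class `"phantomSpec"`.
#' @seealso [makeTubePhantom()]
#' @export
phantomSpec <- function(curve = c("straight", "arc", "poly"),
                        radius_mm = 5,
                        extent_si_mm = 120,
                        voxel_size_mm = 1,
                        tilt_deg = c(0, 0),
                        pmj_offset_mm = 5,
                        arc_radius_mm = 200,
                        poly_x = c(0, 0, 0, 0),
                        poly_y = c(0, 0, 0, 0),
                        disc_arcs_mm = NULL,
                        margin_vox = 3,
                        grid_dim = NULL,
                        grid_origin = NULL,
                        curve_step_mm = 0.1) {
  curve <- match.arg(curve)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3)
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            extent_si_mm > 0, pmj_offset_mm >= 0, margin_vox >= 2,
            length(tilt_deg) == 2L)
  rfun <- if (is.function(radius_mm)) radius_mm else {
    stopifnot(radius_mm > 0)
    local({ r0 <- radius_mm; function(s) rep(r0, length(s)) })
  }
  structure(list(curve = curve, radius = rfun, extent_si = extent_si_mm,
                 voxel_size = voxel_size_mm, tilt = tilt_deg,
                 pmj_offset = pmj_offset_mm, arc_radius = arc_radius_mm,
                 poly_x = poly_x, poly_y = poly_y,
                 disc_arcs = disc_arcs_mm, margin = margin_vox,
                 grid_dim = grid_dim, grid_origin = grid_origin,
                 step = curve_step_mm),
            class = "phantomSpec")
}

.polyEval <- function(coef, u) {
  out <- numeric(length(u))
  for (k in seq_along(coef)) out <- out + coef[k] * u^(k - 1)
  out
}

# dense curve samples, superior end first; returns matrix of points plus
# cumulative arc-length s from the superior end (the PMJ)
.phantomCurve <- function(spec) {
  u <- seq(spec$extent_si, 0, by = -spec$step)   # superior -> inferior
  pts <- switch(spec$curve,
    straight = cbind(0, 0, u),
    arc = {
      R <- spec$arc_radius
      stopifnot(R > spec$extent_si / 2)
      zc <- spec$extent_si / 2
      th <- asin(pmin(1, (u - zc) / R))
      cbind(0, R * (1 - cos(th)), zc + R * sin(th))
    },
    poly = cbind(.polyEval(spec$poly_x, u), .polyEval(spec$poly_y, u), u))
  if (any(spec$tilt != 0)) {
    a <- spec$tilt * pi / 180
    Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])),
                c(0, sin(a[1]), cos(a[1])))
    Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0),
                c(-sin(a[2]), 0, cos(a[2])))
    mid <- colMeans(pts)
    pts <- sweep(sweep(pts, 2, mid) %*% t(Ry %*% Rx), 2, mid, `+`)
  }
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  if (any(diff(pts[, 3]) >= 0))
    stop("makeTubePhantom: curve is not monotone in the superior-inferior ",
         "axis; reduce tilt or curvature")
  list(points = pts, s = s)
}

#' Generate a voxelized tube phantom with ground truth
#'
#' Builds the binary mask volume, a point-label volume (PMJ code 50 at the
#' curve's superior end, optional disc labels), and a ground-truth table
#' with, per axial slice, the true centerline point, unit tangent,
#' arc-length from the PMJ and true perpendicular CSA (pi * r(s)^2).
#'
#' @param spec a [phantomSpec()].
#' @return list with elements `mask` ([CordVolume-class]), `labels`
#'   ([CordVolume-class]), `truth` (data.frame: slice, x, y, z, tx, ty, tz,
#'   arc_length, true_csa) and `spec`.
#' @examples
#' ph <- makeTubePhantom(phantomSpec("straight", radius_mm = 5,
#'                                   extent_si_mm = 40))
#' sum(volumeData(ph$mask)[, , 20])  # ~ pi * 25 voxels
#' @export
makeTubePhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  cv <- .phantomCurve(spec)
  pts <- cv$points; s <- cv$s
  keep <- s >= spec$pmj_offset          # the segmented part of the cord
  if (sum(keep) < 2L)
    stop("makeTubePhantom: pmj_offset leaves no tube to voxelize")
  sub <- pts[keep, , drop = FALSE]
  ssub <- s[keep]
  r <- spec$radius(ssub)
  if (any(r <= 0)) stop("makeTubePhantom: radius_profile must be positive")
  rmax <- max(r)
  h <- spec$voxel_size

  lo <- apply(sub, 2, min) - rmax - spec$margin * h
  hi <- apply(sub, 2, max) + rmax + spec$margin * h
  if (is.null(spec$grid_origin)) {
    # align: in-plane mean axis 0.5 mm off voxel centers, z voxel center at
    # the curve's superior end (the PMJ)
    ctr <- colMeans(sub)
    org <- numeric(3)
    for (k in 1:2)
      org[k] <- ctr[k] - 0.5 - h[k] * ceiling((ctr[k] - 0.5 - lo[k]) / h[k])
    org[3] <- pts[1, 3] - h[3] * ceiling((pts[1, 3] - lo[3]) / h[3])
    dims <- ceiling((hi - org) / h) + 1
  } else {
    org <- spec$grid_origin
    dims <- spec$grid_dim
    if (is.null(dims)) stop("grid_origin requires grid_dim")
    bad <- lo < (org - h / 2) | hi > (org + (dims - 1) * h + h / 2)
    if (any(bad))
      stop("makeTubePhantom: tube (with margin) exits the grid along axis ",
           paste(which(bad), collapse = ", "),
           "; tube extent [", paste(sprintf("%.1f", lo), collapse = ", "),
           "] to [", paste(sprintf("%.1f", hi), collapse = ", "), "] mm")
  }
  dims <- as.integer(dims)
  affine <- diag(c(h, 1)); affine[1:3, 4] <- org

  xs <- org[1] + (seq_len(dims[1]) - 1) * h[1]
  ys <- org[2] + (seq_len(dims[2]) - 1) * h[2]
  zs <- org[3] + (seq_len(dims[3]) - 1) * h[3]
  px <- rep(xs, times = dims[2])
  py <- rep(ys, each = dims[1])

  mask <- array(0, dims)
  zrange <- range(sub[, 3])
  for (k in seq_len(dims[3])) {
    zk <- zs[k]
    if (zk < zrange[1] || zk > zrange[2]) next   # no end caps
    cand <- which(abs(sub[, 3] - zk) <= rmax + spec$step)
    if (!length(cand)) next
    best <- rep(Inf, dims[1] * dims[2])          # min of d^2 - r(s)^2
    for (j in cand) {
      d2 <- (px - sub[j, 1])^2 + (py - sub[j, 2])^2 + (zk - sub[j, 3])^2
      best <- pmin(best, d2 - r[j]^2)
    }
    mask[, , k] <- as.double(best <= 0)
  }

  vol <- .newCordVolume(mask, affine)

  # ground truth per slice crossed by the segmented curve
  ks <- which(zs >= zrange[1] & zs <= zrange[2])
  nearest <- vapply(zs[ks], function(z) which.min(abs(sub[, 3] - z)), 0L)
  tang <- .curveTangents(sub)
  truth <- data.frame(slice = ks,
                      x = sub[nearest, 1], y = sub[nearest, 2],
                      z = sub[nearest, 3],
                      tx = tang[nearest, 1], ty = tang[nearest, 2],
                      tz = tang[nearest, 3],
                      arc_length = ssub[nearest],
                      true_csa = pi * r[nearest]^2)

  labels <- array(0, dims)
  pmjVox <- round((pts[1, ] - org) / h) + 1
  labels[pmjVox[1], pmjVox[2], pmjVox[3]] <- 50
  if (!is.null(spec$disc_arcs)) {
    for (nm in names(spec$disc_arcs)) {
      tgt <- spec$disc_arcs[[nm]]
      j <- which.min(abs(s - tgt))
      dv <- round((pts[j, ] - org) / h) + 1
      labels[dv[1], dv[2], dv[3]] <- as.integer(nm)
    }
  }

  list(mask = vol, labels = .newCordVolume(labels, affine),
       truth = truth, spec = spec)
}

# unit tangents of an ordered polyline by central differences
.curveTangents <- function(pts) {
  n <- nrow(pts)
  tg <- matrix(0, n, 3)
  if (n >= 3) tg[2:(n - 1), ] <- pts[3:n, ] - pts[1:(n - 2), ]
  tg[1, ] <- pts[2, ] - pts[1, ]
  tg[n, ] <- pts[n, ] - pts[n - 1, ]
  tg / sqrt(rowSums(tg^2))
}
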