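# Shared fixtures. Phantom voxelization is the slow part of the suite, so
# standard phantoms are built once per run and cached.

.fixtures <- new.env(parent = emptyenv())

cachedPhantom <- function(key, spec) {
  if (!exists(key, envir = .fixtures))
    assign(key, makeTubePhantom(spec), envir = .fixtures)
  get(key, envir = .fixtures)
}

straightPhantom <- function() {
  cachedPhantom("straight_r5",
                phantomSpec("straight", radius_mm = 5, extent_si_mm = 120))
}

arcPhantom <- function() {
  cachedPhantom("arc_r4_R200",
                phantomSpec("arc", radius_mm = 4, extent_si_mm = 120,
                            arc_radius_mm = 200))
}

tiltedPhantom <- function(tilt) {
  cachedPhantom(paste0("tilt_", tilt),
                phantomSpec("straight", radius_mm = 5, extent_si_mm = 140,
                            tilt_deg = c(tilt, 0)))
}

pmjLabelOf <- function(ph) {
  labs <- extractPointLabels(ph$labels)
  for (l in labs) if (l@value == 50L) return(l)
  stop("fixture phantom has no PMJ label")
}

# a volume that is exactly mirror-symmetric about sagittal slice `center`,
# built by reflecting one half of a noisy tube-like pattern
mirroredVolume <- function(nx = 41, ny = 31, nz = 41, center = 21,
                           seed = 1) {
  set.seed(seed)
  d <- array(0, c(nx, ny, nz))
  half <- array(stats::runif(nx * ny * nz), c(nx, ny, nz))
  # smooth-ish structure so correlation has something to lock onto
  yc <- (ny + 1) / 2
  for (k in seq_len(nz)) {
    tube <- outer(seq_len(nx) - center, seq_len(ny) - yc,
                  function(i, j) as.numeric(i^2 + j^2 <= 36))
    d[, , k] <- tube + 0.1 * half[, , k]
  }
  for (off in 1:(min(center, nx - center) - 1))
    d[center - off, , ] <- d[center + off, , ]
  cordVolume(d)
}

pointLabelAt <- function(vol, vox1, value = 50L) {
  new("PointLabel", value = as.integer(value), voxel = as.numeric(vox1) - 1,
      physical = as.numeric(voxelToPhysical(vol, rbind(vox1))))
}
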