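# Shared fixtures: compact synthetic scenes (coarser voxels than the
# acquisition default so unit tests stay fast) and a hand-built Scene
# constructor for geometry edge cases.

smallSceneParams <- function(territories = list(), seed = 1L,
                             psfSigma = c(0.15, 0.15, 0.3), ...) {
  sceneParams(
    nucleusSemiaxes = c(3, 2.4, 1.8),
    voxelSize = c(0.15, 0.15, 0.3),
    psfSigma = psfSigma,
    territories = territories,
    seed = seed,
    ...
  )
}

cleanSceneParams <- function(territories = list(), seed = 1L, ...) {
  # no blur, no noise, no background: segmentation is exact
  smallSceneParams(territories = territories, seed = seed,
                   psfSigma = c(0, 0, 0), noiseModel = "none",
                   backgroundLevel = 0, ...)
}

# Scene wrapping an arbitrary blue-channel array (for constructed masks)
bareScene <- function(blue, voxelSize = c(0.2, 0.2, 0.4),
                      green = NULL, red = NULL) {
  d <- dim(blue)
  vox <- array(0, c(d, 3L))
  vox[, , , 1] <- blue
  if (!is.null(green)) vox[, , , 2] <- green
  if (!is.null(red)) vox[, , , 3] <- red
  methods::new("Scene",
    voxels = vox, voxelSize = voxelSize,
    channels = c("blue", "green", "red"),
    channelRoles = c(blue = "nucleus", green = "territory",
                     red = "territory"),
    bitDepth = 8L, truth = list(), metadata = list()
  )
}

# a solid ellipsoid intensity array centred in a given frame
ellipsoidArray <- function(dims, voxelSize, center, semiaxes,
                           level = 200) {
  xs <- (seq_len(dims[1]) - 0.5) * voxelSize[1]
  ys <- (seq_len(dims[2]) - 0.5) * voxelSize[2]
  zs <- (seq_len(dims[3]) - 0.5) * voxelSize[3]
  out <- array(0, dims)
  q2 <- outer(((xs - center[1]) / semiaxes[1])^2,
              ((ys - center[2]) / semiaxes[2])^2, `+`)
  for (k in seq_len(dims[3]))
    out[, , k] <- level * (q2 + ((zs[k] - center[3]) / semiaxes[3])^2 <= 1)
  out
}
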