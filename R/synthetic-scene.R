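# Synthetic fluorescence scene generator: ellipsoidal nuclei with
# territory blobs at controlled fractional radial positions, rendered
# under Gaussian PSF blur, background and noise, with exact geometric
# ground truth. The generator is a pure function of its parameters
# including the seed.

#' Parameters for a synthetic 3D scene
#'
#' Defaults emulate the acquisition geometry of a typical 63x confocal
#' 3D-FISH experiment: voxel size 0.105 x 0.105 x 0.34 um, 8-bit
#' channels, and a DLD-1-like nucleus of roughly 12 um diameter. The
#' nucleus is an axis-aligned ellipsoid (optionally rotated about z),
#' which keeps boundary geometry analytic so recovery can be tested
#' against an exact oracle.
#'
#' @param nucleusSemiaxes numeric length-3, ellipsoid semiaxes (um).
#' @param voxelSize numeric length-3, um per voxel (x, y, z).
#' @param frameShape integer length-3 voxel counts, or `NULL` to size
#'   the frame automatically around the nucleus plus a blur margin.
#' @param territories list of [territorySpec()] entries.
#' @param psfSigma numeric length-3, Gaussian PSF sigma per axis (um);
#'   zero disables blur.
#' @param noiseModel `"none"`, `"gaussian"` or `"poisson"`.
#' @param noiseSigma gaussian noise sd as a fraction of dynamic range.
#' @param poissonScale photon scale for poisson noise (expected counts
#'   at full dynamic range).
#' @param backgroundLevel background intensity fraction of dynamic range.
#' @param nucleusFill blue-channel fill intensity fraction.
#' @param rotationZ rotation of the nucleus about the z axis (radians).
#' @param bitDepth 8 or 16.
#' @param shrinkToFit if TRUE (default), territory blobs that would
#'   cross the nuclear boundary at high fractional positions are shrunk
#'   to fit and the applied size recorded in the truth; if FALSE such a
#'   placement is an error.
#' @param seed integer seed; the scene is a deterministic function of
#'   the full parameter set including the seed.
#' @return a validated list of class `SceneParams`.
#' @export
sceneParams <- function(nucleusSemiaxes = c(6, 4.5, 2.8),
                        voxelSize = c(0.105, 0.105, 0.34),
                        frameShape = NULL,
                        territories = list(),
                        psfSigma = c(0.2, 0.2, 0.4),
                        noiseModel = c("gaussian", "none", "poisson"),
                        noiseSigma = 0.02,
                        poissonScale = 200,
                        backgroundLevel = 0.05,
                        nucleusFill = 0.7,
                        rotationZ = 0,
                        bitDepth = 8L,
                        shrinkToFit = TRUE,
                        seed = 1L) {
  noiseModel <- match.arg(noiseModel)
  stopifnot(
    length(nucleusSemiaxes) == 3L, all(nucleusSemiaxes > 0),
    length(voxelSize) == 3L, all(voxelSize > 0),
    length(psfSigma) == 3L, all(psfSigma >= 0),
    noiseSigma >= 0, backgroundLevel >= 0, backgroundLevel < 1,
    bitDepth %in% c(8L, 16L)
  )
  if (is.null(frameShape)) {
    margin <- 4 * psfSigma + 1.0  # um beyond the nucleus on each side
    frameShape <- as.integer(ceiling(2 * (nucleusSemiaxes + margin) /
                                       voxelSize))
  }
  frameShape <- as.integer(frameShape)
  stopifnot(length(frameShape) == 3L, all(frameShape >= 1L))
  extent <- frameShape * voxelSize
  if (any(2 * nucleusSemiaxes >= extent))
    stop("nucleus does not fit inside the frame")
  p <- list(
    nucleusSemiaxes = as.numeric(nucleusSemiaxes),
    voxelSize = as.numeric(voxelSize),
    frameShape = frameShape,
    territories = territories,
    psfSigma = as.numeric(psfSigma),
    noiseModel = noiseModel,
    noiseSigma = noiseSigma,
    poissonScale = poissonScale,
    backgroundLevel = backgroundLevel,
    nucleusFill = nucleusFill,
    rotationZ = rotationZ,
    bitDepth = as.integer(bitDepth),
    shrinkToFit = isTRUE(shrinkToFit),
    seed = as.integer(seed)
  )
  class(p) <- "SceneParams"
  p
}

#' Specification of one territory blob
#'
#' @param channel `"green"` or `"red"`.
#' @param fractionalRD requested fractional radial position in `[0, 1]`
#'   (0 = nucleus centre, 1 = boundary). Defined through the same ray
#'   construction the measurement uses: the blob centre C is placed so
#'   that |NC| / |NB| equals this value, where B is the boundary point
#'   of the ray from the nucleus centre N through C.
#' @param direction unit direction of the placement ray, or `"random"`
#'   (drawn from the scene seed).
#' @param blobSemiaxes numeric length-3, blob ellipsoid semiaxes (um).
#' @param peakIntensity intensity fraction of dynamic range.
#' @return a list of class `TerritorySpec`.
#' @export
territorySpec <- function(channel = c("green", "red"),
                          fractionalRD,
                          direction = "random",
                          blobSemiaxes = c(1.2, 1.2, 1.0),
                          peakIntensity = 0.8) {
  channel <- match.arg(channel)
  stopifnot(
    is.numeric(fractionalRD), length(fractionalRD) == 1L,
    fractionalRD >= 0, fractionalRD <= 1,
    length(blobSemiaxes) == 3L, all(blobSemiaxes > 0),
    peakIntensity > 0, peakIntensity <= 1
  )
  if (!identical(direction, "random")) {
    direction <- as.numeric(direction)
    stopifnot(length(direction) == 3L)
    nrm <- sqrt(sum(direction^2))
    if (nrm == 0) stop("direction must be a non-zero vector or 'random'")
    direction <- direction / nrm
  }
  structure(
    list(channel = channel, fractionalRD = fractionalRD,
         direction = direction, blobSemiaxes = as.numeric(blobSemiaxes),
         peakIntensity = peakIntensity),
    class = "TerritorySpec"
  )
}

# rotate a point/direction about z
.rotZ <- function(v, theta) {
  if (theta == 0) return(v)
  c(cos(theta) * v[1] - sin(theta) * v[2],
    sin(theta) * v[1] + cos(theta) * v[2], v[3])
}

# distance from the ellipsoid centre to its surface along unit u,
# with the ellipsoid rotated by theta about z
.ellipsoidRayLength <- function(semiaxes, u, theta = 0) {
  ub <- .rotZ(u, -theta)  # into the ellipsoid's body frame
  1 / sqrt(sum((ub / semiaxes)^2))
}

# quadratic form value of point p for the nucleus (<= 1 means inside)
.nucleusQ <- function(p, center, semiaxes, theta = 0) {
  d <- .rotZ(p - center, -theta)
  sum((d / semiaxes)^2)
}

# largest scale s <= 1 such that an axis-aligned blob ellipsoid with
# semiaxes s*b centred at C stays inside the nucleus; checked over a
# fixed set of surface directions (deterministic, seed-independent)
.blobFitScale <- function(C, b, center, semiaxes, theta = 0) {
  ang <- seq(0, pi, length.out = 13)
  azi <- seq(0, 2 * pi, length.out = 25)[-25]
  dirs <- unique(rbind(
    c(0, 0, 1), c(0, 0, -1),
    do.call(rbind, lapply(ang[-c(1, 13)], function(ph)
      t(vapply(azi, function(th)
        c(sin(ph) * cos(th), sin(ph) * sin(th), cos(ph)), numeric(3)))))
  ))
  smin <- 1
  for (i in seq_len(nrow(dirs))) {
    v <- dirs[i, ]
    # q(s) = sum(((C - N + s * b*v) rotated / a)^2), quadratic in s
    d0 <- .rotZ(C - center, -theta) / semiaxes
    d1 <- .rotZ(b * v, -theta) / semiaxes
    A <- sum(d1^2); B <- 2 * sum(d0 * d1); C0 <- sum(d0^2) - 1
    if (A < 1e-12) next
    disc <- B^2 - 4 * A * C0
    if (disc < 0) return(0)  # centre itself outside
    s <- (-B + sqrt(disc)) / (2 * A)
    if (s < smin) smin <- max(s, 0)
  }
  min(smin, 1)
}

#' Render a synthetic multichannel scene with ground truth
#'
#' Builds a 3-channel stack (blue = nucleus fill, green/red = territory
#' blobs placed at their requested fractional radial positions), then
#' applies Gaussian PSF blur, adds background and noise, and quantizes
#' to the requested bit depth (clipping to `[0, 2^bitDepth - 1]`). The
#' returned `Scene` carries the pre-blur geometric ground truth in its
#' `truth` slot. Identical parameters (including seed) give
#' bit-identical output.
#'
#' @param params a [sceneParams()] object.
#' @return a [`Scene`][Scene-class] object.
#' @export
renderScene <- function(params) {
  stopifnot(inherits(params, "SceneParams"))
  withr::with_seed(params$seed, .renderSceneImpl(params))
}

.renderSceneImpl <- function(p) {
  dims <- p$frameShape
  vs <- p$voxelSize
  dyn <- 2^p$bitDepth - 1
  center <- dims * vs / 2
  xs <- (seq_len(dims[1]) - 0.5) * vs[1]
  ys <- (seq_len(dims[2]) - 0.5) * vs[2]
  zs <- (seq_len(dims[3]) - 0.5) * vs[3]

  # nucleus mask: rotated ellipsoid quadratic form on the grid
  th <- p$rotationZ
  dx <- xs - center[1]; dy <- ys - center[2]; dz <- zs - center[3]
  if (th == 0) {
    qx <- (dx / p$nucleusSemiaxes[1])^2
    qy <- (dy / p$nucleusSemiaxes[2])^2
  } else {
    # body-frame coordinates for every (x, y) pair
    XB <- outer(dx, dy, function(a, b) cos(th) * a + sin(th) * b)
    YB <- outer(dx, dy, function(a, b) -sin(th) * a + cos(th) * b)
    qxy <- (XB / p$nucleusSemiaxes[1])^2 + (YB / p$nucleusSemiaxes[2])^2
  }
  qz <- (dz / p$nucleusSemiaxes[3])^2
  nucMask <- array(FALSE, dims)
  for (k in seq_len(dims[3])) {
    if (th == 0)
      nucMask[, , k] <- outer(qx, qy, `+`) + qz[k] <= 1
    else
      nucMask[, , k] <- qxy + qz[k] <= 1
  }

  channels <- c("blue", "green", "red")
  vox <- array(0, c(dims, 3L))
  vox[, , , 1L][nucMask] <- p$nucleusFill

  # place territories
  tt <- lapply(p$territories, function(spec) {
    u <- spec$direction
    if (identical(u, "random")) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
    }
    tstar <- .ellipsoidRayLength(p$nucleusSemiaxes, u, th)
    C <- center + spec$fractionalRD * tstar * u
    s <- .blobFitScale(C, spec$blobSemiaxes, center, p$nucleusSemiaxes, th)
    if (s < 1 - 1e-9 && !p$shrinkToFit)
      stop("territory does not fit inside the nucleus at fractional ",
           "position ", spec$fractionalRD, " (shrinkToFit is FALSE)")
    if (s <= 0)
      stop("territory centre lies outside the nucleus; cannot place blob")
    applied <- spec$blobSemiaxes * s
    list(channel = spec$channel, center = C, fractionalRD = spec$fractionalRD,
         requestedSemiaxes = spec$blobSemiaxes, appliedSemiaxes = applied,
         peakIntensity = spec$peakIntensity, direction = u)
  })

  for (t in tt) {
    ci <- match(t$channel, channels)
    bb <- t$appliedSemiaxes
    # restrict to the blob's bounding box for speed
    lo <- pmax(1L, as.integer(floor((t$center - bb) / vs - 0.5)) + 1L)
    hi <- pmin(dims, as.integer(ceiling((t$center + bb) / vs + 0.5)))
    bx <- (seq(lo[1], hi[1]) - 0.5) * vs[1] - t$center[1]
    by <- (seq(lo[2], hi[2]) - 0.5) * vs[2] - t$center[2]
    bz <- (seq(lo[3], hi[3]) - 0.5) * vs[3] - t$center[3]
    qb <- outer((bx / bb[1])^2, (by / bb[2])^2, `+`)
    for (k in seq_along(bz)) {
      inside <- qb + (bz[k] / bb[3])^2 <= 1
      sl <- vox[lo[1]:hi[1], lo[2]:hi[2], lo[3] + k - 1L, ci]
      sl[inside] <- pmax(sl[inside], t$peakIntensity)
      vox[lo[1]:hi[1], lo[2]:hi[2], lo[3] + k - 1L, ci] <- sl
    }
  }

  # PSF blur (per channel), background, noise, quantization
  sigVox <- p$psfSigma / vs
  for (ci in 1:3) {
    ch <- vox[, , , ci]
    if (any(sigVox > 0))
      ch <- array(cpp_gauss_blur3d(as.numeric(ch), dims, sigVox), dims)
    ch <- ch + p$backgroundLevel
    if (p$noiseModel == "gaussian" && p$noiseSigma > 0) {
      ch <- ch + stats::rnorm(length(ch), 0, p$noiseSigma)
    } else if (p$noiseModel == "poisson") {
      ch <- stats::rpois(length(ch), pmax(ch, 0) * p$poissonScale) /
        p$poissonScale
    }
    vox[, , , ci] <- round(pmin(pmax(ch, 0), 1) * dyn)
  }

  truth <- list(
    nucleusCenter = center,
    nucleusSemiaxes = p$nucleusSemiaxes,
    rotationZ = th,
    nucleusMask = nucMask,
    territories = if (length(tt)) data.frame(
      channel = vapply(tt, `[[`, character(1), "channel"),
      cx = vapply(tt, function(t) t$center[1], numeric(1)),
      cy = vapply(tt, function(t) t$center[2], numeric(1)),
      cz = vapply(tt, function(t) t$center[3], numeric(1)),
      fractionalRD = vapply(tt, `[[`, numeric(1), "fractionalRD"),
      appliedA = vapply(tt, function(t) t$appliedSemiaxes[1], numeric(1)),
      appliedB = vapply(tt, function(t) t$appliedSemiaxes[2], numeric(1)),
      appliedC = vapply(tt, function(t) t$appliedSemiaxes[3], numeric(1)),
      shrunk = vapply(tt, function(t)
        any(t$appliedSemiaxes < t$requestedSemiaxes - 1e-9), logical(1))
    ) else data.frame()
  )

  methods::new("Scene",
    voxels = vox, voxelSize = vs, channels = channels,
    channelRoles = c(blue = "nucleus", green = "territory",
                     red = "territory"),
    bitDepth = p$bitDepth, truth = truth,
    metadata = list(seed = p$seed)
  )
}
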