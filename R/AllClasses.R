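#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib ctRadial, .registration = TRUE
NULL

#' Scene: a multichannel 3D confocal stack with physical voxel size
#'
#' A `Scene` holds the raw voxel data the pipeline consumes: a 4D numeric
#' array indexed `[x, y, z, channel]` in digital numbers (0 ..
#' 2^bitDepth - 1), the physical voxel size in micrometres, and the role
#' of each channel (one nucleus counterstain channel, one or more
#' territory paint channels). Scenes produced by [renderScene()] carry
#' their geometric ground truth in the `truth` slot; scenes read from
#' disk carry whatever the sidecar recorded.
#'
#' Physical coordinates are in micrometres with the origin at the stack
#' corner; the centre of voxel `(i, j, k)` (1-based) is at
#' `(i - 0.5, j - 0.5, k - 0.5) * voxelSize`. All distances downstream
#' are Euclidean in micrometres, so the anisotropic z spacing is handled
#' by the coordinate conversion, never by voxel counting.
#'
#' @slot voxels numeric 4D array, `[x, y, z, channel]`.
#' @slot voxelSize numeric length-3, micrometres per voxel along x, y, z.
#' @slot channels character, channel names (e.g. `"blue"`, `"green"`,
#'   `"red"`), one per slice of the 4th dimension.
#' @slot channelRoles named character mapping channel name to
#'   `"nucleus"` or `"territory"`.
#' @slot bitDepth integer, 8 or 16.
#' @slot truth list, geometric ground truth for synthetic scenes (empty
#'   otherwise); see [sceneTruth()].
#' @slot metadata list, free-form (scene id, seed, provenance).
#' @export
setClass("Scene",
  slots = c(
    voxels = "array",
    voxelSize = "numeric",
    channels = "character",
    channelRoles = "character",
    bitDepth = "integer",
    truth = "list",
    metadata = "list"
  )
)

setValidity("Scene", function(object) {
  msg <- character()
  d <- dim(object@voxels)
  if (length(d) != 4L)
    msg <- c(msg, "voxels must be a 4D array [x, y, z, channel]")
  else {
    if (any(d[1:3] < 1L)) msg <- c(msg, "all spatial dimensions must be >= 1")
    if (d[4L] != length(object@channels))
      msg <- c(msg, "4th dimension must match length(channels)")
  }
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive lengths (micrometres)")
  if (!all(object@channelRoles %in% c("nucleus", "territory")))
    msg <- c(msg, "channelRoles must be 'nucleus' or 'territory'")
  if (!all(names(object@channelRoles) %in% object@channels))
    msg <- c(msg, "channelRoles names must be declared channels")
  if (!(object@bitDepth %in% c(8L, 16L)))
    msg <- c(msg, "bitDepth must be 8 or 16")
  if (length(msg)) msg else TRUE
})

#' NucleusMask: segmented nucleus with its geometric centre
#'
#' Result of [extractNucleus()]: the largest connected component of the
#' thresholded counterstain channel after 3D hole filling, its unweighted
#' centroid in physical micrometres (the geometric centre N of the
#' radial-distance construction), and its volume.
#'
#' @slot mask logical 3D array.
#' @slot center numeric length-3, centroid in micrometres.
#' @slot voxelSize numeric length-3, micrometres.
#' @slot volume numeric, micrometres^3.
#' @slot truncated logical, TRUE when the mask touches a frame face (the
#'   nucleus may be cut by the field of view).
#' @export
setClass("NucleusMask",
  slots = c(
    mask = "array",
    center = "numeric",
    voxelSize = "numeric",
    volume = "numeric",
    truncated = "logical"
  )
)

setValidity("NucleusMask", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3L) msg <- c(msg, "mask must be 3D")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (length(object@center) != 3L) msg <- c(msg, "center must be length 3")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive lengths")
  if (length(msg)) msg else TRUE
})

#' RDSummary: per condition x chromosome radial-distance distribution
#'
#' Collects the pooled percent radial distance values of one chromosome
#' territory under one condition, with sample size, sample median and
#' the 20-percent-wide bin frequencies used for distribution plots
#' (bins `[0,20) [20,40) [40,60) [60,80) [80,100]`, left-closed with the
#' final bin closed at 100).
#'
#' @slot condition character scalar.
#' @slot chromosome character scalar (e.g. `"CT18"`).
#' @slot values numeric, pooled percent radial distances.
#' @slot n integer, number of territories.
#' @slot median numeric, sample median (mean of middle pair for even n).
#' @slot binFrequencies numeric length-5, frequencies summing to 1.
#' @export
setClass("RDSummary",
  slots = c(
    condition = "character",
    chromosome = "character",
    values = "numeric",
    n = "integer",
    median = "numeric",
    binFrequencies = "numeric"
  )
)

setValidity("RDSummary", function(object) {
  msg <- character()
  if (object@n != length(object@values))
    msg <- c(msg, "n must equal length(values)")
  if (length(object@binFrequencies) != 5L)
    msg <- c(msg, "binFrequencies must have length 5")
  if (object@n > 0 && abs(sum(object@binFrequencies) - 1) > 1e-9)
    msg <- c(msg, "binFrequencies must sum to 1")
  if (any(object@values < 0 | object@values > 100))
    msg <- c(msg, "percent radial distances must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Section: a 2D nuclear mid-section with its mask
#'
#' One mid-optical section used for envelope line-scan profiling: the
#' intensity image, the isotropic pixel size, the nucleus mask and the
#' condition label.
#'
#' @slot image numeric matrix.
#' @slot pixelSize numeric, micrometres per pixel.
#' @slot mask logical matrix, nucleus mask.
#' @slot condition character scalar.
#' @export
setClass("Section",
  slots = c(
    image = "matrix",
    pixelSize = "numeric",
    mask = "matrix",
    condition = "character"
  )
)

setValidity("Section", function(object) {
  msg <- character()
  if (!all(dim(object@image) == dim(object@mask)))
    msg <- c(msg, "image and mask dimensions must agree")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a positive scalar")
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
  if (length(msg)) msg else TRUE
})

#' LineProfile: intensity profile across a nucleus on a normalized axis
#'
#' Intensities sampled by bilinear interpolation at evenly spaced points
#' along a line through the nucleus centroid, between the two boundary
#' crossings; positions are rescaled to `[0, 1]` so profiles from nuclei
#' of different diameters can be averaged (0 and 1 are the opposite
#' boundary crossings, 0.5 the centroid).
#'
#' @slot positions numeric, strictly increasing in `[0, 1]`.
#' @slot intensities numeric, same length.
#' @export
setClass("LineProfile",
  slots = c(positions = "numeric", intensities = "numeric")
)

setValidity("LineProfile", function(object) {
  msg <- character()
  if (length(object@positions) != length(object@intensities))
    msg <- c(msg, "positions and intensities must have equal length")
  if (length(object@positions) > 1 && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' ProfileSummary: averaged line profiles normalized to a reference
#'
#' Pointwise mean profiles across nuclei for a test and a reference
#' condition, both divided by the reference condition's mean peripheral
#' intensity (mean of the two endpoint samples of the reference mean
#' profile), so the reference periphery maps to exactly 1.0.
#'
#' @slot positions numeric, common `[0, 1]` axis.
#' @slot meanProfile numeric, normalized mean profile of the test
#'   condition.
#' @slot referenceProfile numeric, normalized mean profile of the
#'   reference condition.
#' @slot normConstant numeric, the reference peripheral intensity used
#'   as divisor (original units).
#' @slot nProfiles integer, nuclei in the test condition.
#' @slot nReference integer, nuclei in the reference condition.
#' @export
setClass("ProfileSummary",
  slots = c(
    positions = "numeric",
    meanProfile = "numeric",
    referenceProfile = "numeric",
    normConstant = "numeric",
    nProfiles = "integer",
    nReference = "integer"
  )
)
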