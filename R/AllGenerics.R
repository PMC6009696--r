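# Accessors and show methods for the core classes.

#' Voxel size accessor
#' @param x a `Scene` or `NucleusMask`.
#' @return numeric length-3, micrometres per voxel along x, y, z.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "Scene", function(x) x@voxelSize)

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "NucleusMask", function(x) x@voxelSize)

#' Channel names of a Scene
#' @param x a `Scene`.
#' @return character vector of channel names.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname channelNames
#' @export
setMethod("channelNames", "Scene", function(x) x@channels)

#' Channel roles of a Scene
#' @param x a `Scene`.
#' @return named character vector mapping channel to role.
#' @export
setGeneric("channelRoles", function(x) standardGeneric("channelRoles"))

#' @rdname channelRoles
#' @export
setMethod("channelRoles", "Scene", function(x) x@channelRoles)

#' Ground truth of a synthetic Scene
#'
#' For scenes produced by [renderScene()]: a list with `nucleusCenter`
#' (micrometres), `nucleusMask` (logical array, pre-blur), and
#' `territories` (data.frame with channel, requested and applied blob
#' semiaxes, true centre and true fractional radial distance). Empty
#' for scenes without recorded truth.
#'
#' @param x a `Scene`.
#' @return list (possibly empty).
#' @export
setGeneric("sceneTruth", function(x) standardGeneric("sceneTruth"))

#' @rdname sceneTruth
#' @export
setMethod("sceneTruth", "Scene", function(x) x@truth)

#' Extract one channel of a Scene as a 3D array
#' @param x a `Scene`.
#' @param channel channel name.
#' @return numeric 3D array.
#' @export
setGeneric("channelArray", function(x, channel) standardGeneric("channelArray"))

#' @rdname channelArray
#' @export
setMethod("channelArray", "Scene", function(x, channel) {
  i <- match(channel, x@channels)
  if (is.na(i)) stop("unknown channel: ", channel)
  x@voxels[, , , i, drop = TRUE]
})

#' Nucleus centre accessor
#' @param x a `NucleusMask`.
#' @return numeric length-3, micrometres.
#' @export
setGeneric("nucleusCenter", function(x) standardGeneric("nucleusCenter"))

#' @rdname nucleusCenter
#' @export
setMethod("nucleusCenter", "NucleusMask", function(x) x@center)

setMethod("show", "Scene", function(object) {
  d <- dim(object@voxels)
  cat("Scene:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "channel(s)\n")
  cat("  voxel size (um):", paste(signif(object@voxelSize, 4),
                                  collapse = " x "), "\n")
  cat("  channels:", paste0(object@channels, " (",
      object@channelRoles[object@channels], ")", collapse = ", "), "\n")
  cat("  bit depth:", object@bitDepth,
      if (length(object@truth)) " | ground truth attached" else "", "\n")
})

setMethod("show", "NucleusMask", function(object) {
  cat("NucleusMask:", sum(object@mask), "voxels, volume",
      signif(object@volume, 5), "um^3\n")
  cat("  centre (um):", paste(signif(object@center, 5), collapse = ", "),
      if (object@truncated) " [truncated at frame edge]" else "", "\n")
})

setMethod("show", "RDSummary", function(object) {
  cat("RDSummary:", object@chromosome, "|", object@condition,
      "| n =", object@n, "\n")
  cat("  median %RD:", signif(object@median, 4), "\n")
  cat("  bin frequencies [0-20,20-40,40-60,60-80,80-100]:",
      paste(signif(object@binFrequencies, 3), collapse = " "), "\n")
})

setMethod("show", "Section", function(object) {
  cat("Section:", paste(dim(object@image), collapse = " x "), "px,",
      "pixel", signif(object@pixelSize, 4), "um, condition",
      object@condition, "\n")
})

setMethod("show", "LineProfile", function(object) {
  cat("LineProfile:", length(object@positions), "samples on [0, 1]\n")
})

setMethod("show", "ProfileSummary", function(object) {
  cat("ProfileSummary:", object@nProfiles, "profile(s) vs",
      object@nReference, "reference profile(s)\n")
  cat("  normalization constant:", signif(object@normConstant, 5), "\n")
})
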