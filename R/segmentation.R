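# Segmentation of nucleus and territory objects from a multichannel
# stack: per-channel thresholding (global Otsu by default), 3D
# connected components, hole filling (nucleus only) and unweighted
# centroids in physical micrometres.

# global Otsu threshold on a 256-bin histogram
.otsuThreshold <- function(x, dyn) {
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("degenerate threshold: channel has constant intensity")
  breaks <- seq(0, dyn, length.out = 257)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), 256)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  muT <- mu[256]
  sigmaB <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigmaB[!is.finite(sigmaB)] <- -Inf
  mids[which.max(sigmaB)]
}

.centroidUm <- function(idx, dims, voxelSize, weights = NULL) {
  # idx: linear indices of voxels; centroid of voxel centres in um,
  # optionally intensity-weighted
  i <- arrayInd(idx, dims)
  m <- if (is.null(weights)) colMeans(i)
       else colSums(i * weights) / sum(weights)
  (m - 0.5) * voxelSize
}

#' Threshold one channel of a scene
#'
#' @param scene a [`Scene`][Scene-class].
#' @param channel channel name.
#' @param method `"otsu"` (global Otsu on a 256-bin histogram, the
#'   default), `"fixed"` (absolute threshold `value`) or
#'   `"fractionOfMax"` (threshold at `value` times the channel
#'   maximum). A voxel is foreground when its intensity is strictly
#'   greater than the threshold.
#' @param value threshold parameter for `"fixed"` / `"fractionOfMax"`.
#' @return logical 3D array, same shape as one channel.
#' @export
thresholdChannel <- function(scene, channel,
                             method = c("otsu", "fixed", "fractionOfMax"),
                             value = NULL) {
  method <- match.arg(method)
  ch <- channelArray(scene, channel)
  dyn <- 2^scene@bitDepth - 1
  if (all(ch == 0)) stop("channel '", channel, "' is all zero")
  thr <- switch(method,
    otsu = .otsuThreshold(as.numeric(ch), dyn),
    fixed = {
      if (is.null(value)) stop("method 'fixed' needs a threshold value")
      if (value < 0 || value > dyn)
        stop("fixed threshold outside dynamic range [0, ", dyn, "]")
      value
    },
    fractionOfMax = {
      if (is.null(value) || value < 0 || value > 1)
        stop("method 'fractionOfMax' needs a fraction in [0, 1]")
      value * max(ch)
    }
  )
  structure(ch > thr, threshold = thr)
}

#' Extract the nucleus mask and its geometric centre
#'
#' Thresholds the nucleus (counterstain) channel, keeps the largest 3D
#' connected component, fills interior cavities, and computes the
#' unweighted centroid of the mask voxels in physical micrometres. A
#' `truncated` flag is set when the mask touches a frame face.
#'
#' @param scene a [`Scene`][Scene-class].
#' @param method,value passed to [thresholdChannel()].
#' @param channel nucleus channel name; defaults to the channel with
#'   role `"nucleus"`.
#' @param weighted use the intensity-weighted centroid instead of the
#'   default unweighted (geometric-centre) one.
#' @return a [`NucleusMask`][NucleusMask-class].
#' @export
extractNucleus <- function(scene, method = "otsu", value = NULL,
                           channel = NULL, weighted = FALSE) {
  if (is.null(channel)) {
    channel <- names(scene@channelRoles)[scene@channelRoles == "nucleus"][1]
    if (is.na(channel)) stop("scene declares no nucleus channel")
  }
  bin <- thresholdChannel(scene, channel, method, value)
  dims <- dim(bin)
  if (!any(bin)) stop("segmentation error: empty mask after thresholding")
  labels <- cpp_label3d(as.logical(bin), dims)
  nlab <- attr(labels, "max_label")
  counts <- tabulate(labels, nlab)
  keep <- which.max(counts)
  mask <- array(labels == keep, dims)
  mask <- array(cpp_fill_holes3d(as.logical(mask), dims), dims)
  idx <- which(mask)
  vs <- scene@voxelSize
  w <- if (weighted) as.numeric(channelArray(scene, channel)[idx])
  center <- .centroidUm(idx, dims, vs, w)
  touching <- any(mask[1, , ]) || any(mask[dims[1], , ]) ||
    any(mask[, 1, ]) || any(mask[, dims[2], ]) ||
    any(mask[, , 1]) || any(mask[, , dims[3]])
  if (touching)
    warning("nucleus mask touches the frame edge; flagged truncated")
  methods::new("NucleusMask",
    mask = mask, center = center, voxelSize = vs,
    volume = length(idx) * prod(vs), truncated = touching
  )
}

#' Extract territory objects from a paint channel
#'
#' Thresholds a territory channel, optionally clips to the nucleus
#' mask, labels 3D connected components, discards objects below
#' `minVolume`, sorts by volume descending and keeps at most
#' `maxObjects` (default 2: one per homolog in a diploid nucleus).
#' Centroids are unweighted voxel-centre means in micrometres.
#'
#' The default threshold is half the channel maximum
#' (full-width-half-maximum segmentation): paint signals occupy a tiny
#' voxel fraction, for which Otsu degenerates to splitting the
#' background noise. Otsu remains available via `method = "otsu"`.
#'
#' @param scene a [`Scene`][Scene-class].
#' @param channel territory channel name.
#' @param maxObjects maximum number of objects returned.
#' @param minVolume minimum object volume in um^3 (suppresses noise
#'   speckles).
#' @param nucleusMask optional [`NucleusMask`][NucleusMask-class]; when
#'   supplied and `clip = TRUE`, territory voxels outside the nucleus
#'   are discarded before labelling.
#' @param clip clip territory voxels to the nucleus mask (default TRUE).
#' @param minContrast objects whose mean intensity is below
#'   `minContrast` times the channel's median intensity are discarded
#'   as background artefacts (Otsu on a channel containing only noise
#'   otherwise promotes the noise itself to an object). Ignored when
#'   the channel median is 0.
#' @param method,value passed to [thresholdChannel()].
#' @param weighted use intensity-weighted centroids instead of the
#'   default unweighted (geometric-centre) ones.
#' @return data.frame with one row per object: `channel`, `cx`, `cy`,
#'   `cz` (um), `volume` (um^3), `voxelCount`; zero rows when nothing
#'   survives.
#' @export
extractTerritories <- function(scene, channel, maxObjects = 2L,
                               minVolume = 0.5, nucleusMask = NULL,
                               clip = TRUE, minContrast = 2,
                               method = "fractionOfMax", value = 0.5,
                               weighted = FALSE) {
  role <- scene@channelRoles[channel]
  if (is.na(role) || role != "territory")
    stop("'", channel, "' is not a territory channel")
  ch <- channelArray(scene, channel)
  bg <- stats::median(ch)
  empty <- data.frame(channel = character(), cx = numeric(),
                      cy = numeric(), cz = numeric(), volume = numeric(),
                      voxelCount = integer())
  if (all(ch == 0)) return(empty)  # nothing to segment, not an error here
  bin <- thresholdChannel(scene, channel, method, value)
  dims <- dim(bin)
  if (clip && !is.null(nucleusMask)) bin <- bin & nucleusMask@mask
  if (!any(bin)) return(empty)
  labels <- cpp_label3d(as.logical(bin), dims)
  nlab <- attr(labels, "max_label")
  counts <- tabulate(labels, nlab)
  vs <- scene@voxelSize
  vols <- counts * prod(vs)
  keep <- which(vols >= minVolume)
  if (bg > 0 && length(keep)) {
    means <- vapply(keep, function(l) mean(ch[labels == l]), numeric(1))
    keep <- keep[means >= minContrast * bg]
  }
  if (!length(keep)) return(empty)
  keep <- keep[order(vols[keep], decreasing = TRUE)]
  keep <- keep[seq_len(min(length(keep), maxObjects))]
  cent <- t(vapply(keep, function(l) {
    li <- which(labels == l)
    .centroidUm(li, dims, vs,
                if (weighted) as.numeric(ch[li]))
  }, numeric(3)))
  data.frame(
    channel = channel,
    cx = cent[, 1], cy = cent[, 2], cz = cent[, 3],
    volume = vols[keep], voxelCount = counts[keep]
  )
}
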