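# Synthetic 2D nuclear mid-sections with controlled peripheral (rim)
# versus nucleoplasmic staining, for testing envelope line-scan
# profiling.

#' Parameters for envelope-section simulation
#'
#' Each simulated nucleus is a disk of radius `nucleusRadius` whose
#' outer annulus of width `rimWidth` has intensity
#' `rimToInteriorRatio` times the interior intensity (before noise),
#' emulating envelope-enriched versus nucleoplasmic protein staining.
#'
#' @param sectionShape integer length-2, image size in pixels.
#' @param pixelSize um per pixel (isotropic).
#' @param nucleusRadius disk radius (um).
#' @param rimWidth rim annulus width (um), must be < `nucleusRadius`.
#' @param rimToInteriorRatio rim / interior intensity ratio (>= 0).
#' @param interiorIntensity interior intensity level (arbitrary units).
#' @param noiseSigma gaussian noise sd (same units), 0 for none.
#' @param centerJitter sd of the nucleus centre offset (um) per nucleus.
#' @param nNuclei number of sections to simulate.
#' @param condition condition label attached to each section.
#' @param seed integer seed.
#' @return a list of class `EnvelopeSimParams`.
#' @export
envelopeSimParams <- function(sectionShape = c(128L, 128L),
                              pixelSize = 0.105,
                              nucleusRadius = 5,
                              rimWidth = 0.5,
                              rimToInteriorRatio = 3,
                              interiorIntensity = 100,
                              noiseSigma = 2,
                              centerJitter = 0.2,
                              nNuclei = 10L,
                              condition = "glass",
                              seed = 1L) {
  stopifnot(
    length(sectionShape) == 2L, all(sectionShape >= 8L),
    pixelSize > 0, nucleusRadius > 0,
    rimWidth > 0, rimWidth < nucleusRadius,
    rimToInteriorRatio >= 0, interiorIntensity > 0,
    noiseSigma >= 0, centerJitter >= 0, nNuclei >= 0
  )
  if (nucleusRadius + 4 * centerJitter >=
      min(sectionShape) * pixelSize / 2)
    stop("nucleus does not fit inside the section")
  p <- list(
    sectionShape = as.integer(sectionShape), pixelSize = pixelSize,
    nucleusRadius = nucleusRadius, rimWidth = rimWidth,
    rimToInteriorRatio = rimToInteriorRatio,
    interiorIntensity = interiorIntensity, noiseSigma = noiseSigma,
    centerJitter = centerJitter, nNuclei = as.integer(nNuclei),
    condition = condition, seed = as.integer(seed)
  )
  class(p) <- "EnvelopeSimParams"
  p
}

#' Simulate envelope-stained nuclear mid-sections
#'
#' @param params an [envelopeSimParams()] object.
#' @return list of [`Section`][Section-class] objects (empty when
#'   `nNuclei = 0`); each carries its ground-truth nucleus mask.
#' @export
simulateEnvelopeSections <- function(params) {
  stopifnot(inherits(params, "EnvelopeSimParams"))
  withr::with_seed(params$seed, {
    lapply(seq_len(params$nNuclei), function(i) .renderSection(params))
  })
}

.renderSection <- function(p) {
  nx <- p$sectionShape[1]; ny <- p$sectionShape[2]
  xs <- (seq_len(nx) - 0.5) * p$pixelSize
  ys <- (seq_len(ny) - 0.5) * p$pixelSize
  ctr <- c(nx, ny) * p$pixelSize / 2 + stats::rnorm(2, 0, p$centerJitter)
  r <- sqrt(outer((xs - ctr[1])^2, (ys - ctr[2])^2, `+`))
  mask <- r <= p$nucleusRadius
  img <- matrix(0, nx, ny)
  interior <- r <= p$nucleusRadius - p$rimWidth
  rim <- mask & !interior
  img[interior] <- p$interiorIntensity
  img[rim] <- p$rimToInteriorRatio * p$interiorIntensity
  if (p$noiseSigma > 0)
    img <- img + matrix(stats::rnorm(nx * ny, 0, p$noiseSigma), nx, ny)
  methods::new("Section", image = img, pixelSize = p$pixelSize,
               mask = mask, condition = p$condition)
}
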