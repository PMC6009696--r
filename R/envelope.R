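# Nuclear-envelope line-scan profiling of 2D mid-sections: intensity
# profiles across the nucleus on a normalized [0, 1] axis, averaging
# with normalization to the reference condition's peripheral intensity,
# a peripheral-enrichment ratio, area-normalized total intensity and
# the two-sample t comparison.

.bilinear <- function(img, x, y) {
  # sample img (matrix indexed [ix, iy], pixel centres at (i - 0.5)) at
  # continuous pixel coordinates (x, y)
  nx <- nrow(img); ny <- ncol(img)
  fx <- pmin(pmax(x - 0.5, 0), nx - 1)
  fy <- pmin(pmax(y - 0.5, 0), ny - 1)
  x0 <- pmin(floor(fx) + 1, nx); x1 <- pmin(x0 + 1, nx)
  y0 <- pmin(floor(fy) + 1, ny); y1 <- pmin(y0 + 1, ny)
  wx <- fx - (x0 - 1); wy <- fy - (y0 - 1)
  img[cbind(x0, y0)] * (1 - wx) * (1 - wy) +
    img[cbind(x1, y0)] * wx * (1 - wy) +
    img[cbind(x0, y1)] * (1 - wx) * wy +
    img[cbind(x1, y1)] * wx * wy
}

.maskCentroidPx <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty mask")
  colMeans(idx) - 0.5
}

.majorAxisAngle <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cc <- sweep(idx, 2, colMeans(idx))
  ev <- eigen(stats::cov(cc), symmetric = TRUE)$vectors[, 1]
  atan2(ev[2], ev[1])
}

# march from the centroid along +/- u (pixel units) until leaving the
# mask; returns signed distances of the two boundary crossings
.lineCrossings <- function(mask, ctr, u, step = 0.5) {
  insideAt <- function(t) {
    p <- ctr + t * u
    i <- floor(p) + 1
    if (any(i < 1) || i[1] > nrow(mask) || i[2] > ncol(mask)) return(FALSE)
    mask[i[1], i[2]]
  }
  if (!insideAt(0))
    stop("geometry error: mask centroid lies outside the mask")
  maxT <- sqrt(nrow(mask)^2 + ncol(mask)^2)
  bound <- function(sgn) {
    t <- 0
    repeat {
      tn <- t + step
      if (!insideAt(sgn * tn)) return(sgn * (t + step / 2))
      t <- tn
      if (t > maxT) stop("line never left the mask")
    }
  }
  c(bound(-1), bound(1))
}

#' Extract a line-scan intensity profile across a nucleus
#'
#' Draws a line through the mask centroid at the given angle, finds the
#' two boundary crossings, and samples the image by bilinear
#' interpolation at `nSamples` evenly spaced points between them;
#' positions are rescaled to `[0, 1]` (0 and 1 at the crossings). The
#' end samples are inset from the interpolated crossings by 1.5 pixels
#' (at most a quarter of the chord) so that they are supported entirely
#' by nuclear pixels: the profile then reports the peripheral signal
#' itself rather than the mixing of envelope and background at the
#' mask edge.
#'
#' @param section a [`Section`][Section-class].
#' @param angle line angle in radians, `"major"` (the mask's major
#'   axis, the default) or `"random"` (uses the R RNG).
#' @param nSamples number of samples (default 101).
#' @return a [`LineProfile`][LineProfile-class].
#' @export
extractLineProfile <- function(section, angle = "major", nSamples = 101L) {
  stopifnot(methods::is(section, "Section"), nSamples >= 2L)
  if (identical(angle, "major")) {
    angle <- .majorAxisAngle(section@mask)
  } else if (identical(angle, "random")) {
    angle <- stats::runif(1, 0, pi)
  }
  stopifnot(is.numeric(angle), length(angle) == 1L)
  u <- c(cos(angle), sin(angle))
  ctr <- .maskCentroidPx(section@mask)
  tt <- .lineCrossings(section@mask, ctr, u)
  inset <- min(1.5, (tt[2] - tt[1]) / 4)
  ts <- seq(tt[1] + inset, tt[2] - inset, length.out = nSamples)
  px <- ctr[1] + ts * u[1]
  py <- ctr[2] + ts * u[2]
  methods::new("LineProfile",
    positions = seq(0, 1, length.out = nSamples),
    intensities = .bilinear(section@image, px, py)
  )
}

#' Average line profiles and normalize to a reference periphery
#'
#' Pointwise mean over nuclei for a test and a reference set of
#' profiles; both means are divided by the reference condition's mean
#' peripheral intensity (mean of the two endpoint samples of the
#' reference mean profile), so the reference periphery maps to exactly
#' 1.0.
#'
#' @param profiles list of [`LineProfile`][LineProfile-class] (test
#'   condition); may be the same list as `referenceProfiles`.
#' @param referenceProfiles list of profiles of the reference
#'   condition.
#' @return a [`ProfileSummary`][ProfileSummary-class].
#' @export
averageProfiles <- function(profiles, referenceProfiles = profiles) {
  if (!length(profiles) || !length(referenceProfiles))
    stop("profile lists must be non-empty")
  allp <- c(profiles, referenceProfiles)
  ns <- vapply(allp, function(p) length(p@positions), integer(1))
  if (length(unique(ns)) != 1)
    stop("all profiles must share the same number of samples")
  meanOf <- function(ps)
    rowMeans(vapply(ps, function(p) p@intensities,
                    numeric(length(ps[[1]]@intensities))))
  m <- meanOf(profiles)
  mr <- meanOf(referenceProfiles)
  norm <- mean(c(mr[1], mr[length(mr)]))
  if (norm == 0) stop("reference peripheral intensity is zero")
  methods::new("ProfileSummary",
    positions = profiles[[1]]@positions,
    meanProfile = m / norm,
    referenceProfile = mr / norm,
    normConstant = norm,
    nProfiles = length(profiles),
    nReference = length(referenceProfiles)
  )
}

#' Peripheral-to-interior intensity ratio of a profile
#'
#' Mean intensity over the outer `rimFraction` of positions at both
#' ends, divided by the mean over the central band
#' (`rimFraction < position < 1 - rimFraction`). A flat profile gives
#' 1; envelope-enriched staining gives values above 1.
#'
#' @param profile a [`LineProfile`][LineProfile-class] with at least 10
#'   samples.
#' @param rimFraction fraction of the axis counted as rim at each end,
#'   in (0, 0.5).
#' @return numeric scalar.
#' @export
peripheralRatio <- function(profile, rimFraction = 0.1) {
  stopifnot(methods::is(profile, "LineProfile"))
  if (rimFraction <= 0 || rimFraction >= 0.5)
    stop("rimFraction must lie in (0, 0.5)")
  if (length(profile@positions) < 10)
    stop("profile needs at least 10 samples")
  pos <- profile@positions
  rim <- pos <= rimFraction | pos >= 1 - rimFraction
  core <- !rim
  if (!any(core)) stop("no central band at this rimFraction")
  mean(profile@intensities[rim]) / mean(profile@intensities[core])
}

#' Total intensity per unit nuclear area
#'
#' Sum of intensities within the nucleus mask divided by the mask area
#' in um^2 (pixel count times pixel area).
#'
#' @param section a [`Section`][Section-class] with a non-empty mask.
#' @return intensity per um^2.
#' @export
totalIntensityPerArea <- function(section) {
  stopifnot(methods::is(section, "Section"))
  n <- sum(section@mask)
  if (n == 0) stop("empty nucleus mask")
  sum(section@image[section@mask]) / (n * section@pixelSize^2)
}

#' Two-sample t comparison of intensity statistics
#'
#' Two-sided two-sample Student's t-test (pooled variance by default,
#' Welch behind the `welch` flag) as used for fluorescence-intensity
#' comparisons. Two constant equal groups give `p = 1`.
#'
#' @param valuesA,valuesB numeric vectors, n >= 2 each.
#' @param welch use the Welch (unequal-variance) variant.
#' @return list with `t`, `p.value`, `df` and `method`.
#' @export
compareConditions <- function(valuesA, valuesB, welch = FALSE) {
  stopifnot(length(valuesA) >= 2L, length(valuesB) >= 2L)
  if (stats::sd(valuesA) == 0 && stats::sd(valuesB) == 0) {
    if (mean(valuesA) == mean(valuesB))
      return(list(t = 0, p.value = 1, df = NA_real_,
                  method = "degenerate: both groups constant and equal"))
    return(list(t = Inf, p.value = 0, df = NA_real_,
                method = "degenerate: both groups constant, means differ"))
  }
  tt <- stats::t.test(valuesA, valuesB, var.equal = !welch)
  list(t = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter), method = tt$method)
}
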