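# The percent radial distance statistic: the ray from the nucleus
# centre N through the territory centre C is extended to the nuclear
# boundary point B; %RD = 100 * |NC| / |NB|, so 0% is the nuclear
# centre and 100% the periphery.

.insideMask <- function(point, mask, voxelSize) {
  dims <- dim(mask)
  i <- floor(point / voxelSize) + 1
  if (any(i < 1) || any(i > dims)) return(FALSE)
  mask[i[1], i[2], i[3]]
}

#' Boundary intersection of the centre-to-territory ray
#'
#' Marches from the nucleus centre `N` along the direction
#' `(C - N) / |C - N|` in physical-space increments of `step`
#' (default half the smallest voxel dimension) until the sampled point
#' leaves the mask, then returns the midpoint of the last-inside and
#' first-outside samples as a sub-voxel estimate of the boundary point
#' B. Leaving the frame counts as leaving the mask.
#'
#' @param mask a [`NucleusMask`][NucleusMask-class].
#' @param N nucleus centre (um), must lie inside the mask.
#' @param C territory centre (um), distinct from `N`.
#' @param step march increment in um; default `min(voxelSize) / 2`.
#' @return numeric length-3: the boundary point B (um), with
#'   `|NB| >= |NC|` whenever `C` itself is inside the mask.
#' @export
boundaryIntersection <- function(mask, N, C, step = NULL) {
  stopifnot(methods::is(mask, "NucleusMask"),
            length(N) == 3L, length(C) == 3L)
  if (is.null(step)) step <- min(mask@voxelSize) / 2
  d <- C - N
  len <- sqrt(sum(d^2))
  if (len == 0) stop("undefined direction: C coincides with N")
  if (!.insideMask(N, mask@mask, mask@voxelSize))
    stop("geometry error: N lies outside the nucleus mask")
  u <- d / len
  maxT <- sqrt(sum((dim(mask@mask) * mask@voxelSize)^2))
  t <- 0
  repeat {
    tNext <- t + step
    if (!.insideMask(N + tNext * u, mask@mask, mask@voxelSize)) break
    t <- tNext
    if (t > maxT) stop("ray never left the mask (mask fills the frame?)")
  }
  N + (t + step / 2) * u
}

#' Percent radial distance of a territory
#'
#' `100 * |NC| / |NB|`, clamped to `[0, 100]`: a centroid pushed
#' marginally beyond the interpolated boundary by blur is reported as
#' 100 (with a warning), never above.
#'
#' @param N nucleus centre (um).
#' @param C territory centre (um).
#' @param B boundary point on the ray from `N` through `C` (um).
#' @return numeric scalar in `[0, 100]`.
#' @export
percentRD <- function(N, C, B) {
  stopifnot(length(N) == 3L, length(C) == 3L, length(B) == 3L)
  R <- sqrt(sum((C - N)^2))
  Y <- sqrt(sum((B - N)^2))
  if (Y == 0) stop("degenerate geometry: B coincides with N")
  if (R > 0 && Y > 0) {
    cosang <- sum((C - N) * (B - N)) / (R * Y)
    if (cosang < 1 - 1e-6)
      warning("B is not collinear with N and C (cos angle = ",
              signif(cosang, 4), ")")
  }
  v <- 100 * R / Y
  if (v > 100) {
    warning("territory centre beyond interpolated boundary; clamped to 100")
    v <- 100
  }
  max(v, 0)
}

#' Measure percent radial distance for every territory in a scene
#'
#' Runs segmentation (nucleus + each territory channel) and the
#' ray-boundary construction, returning one row per territory object.
#' Territories whose centroid falls outside the nucleus mask are
#' skipped with a warning.
#'
#' @param scene a [`Scene`][Scene-class].
#' @param sceneId identifier recorded in the output.
#' @param channels territory channels to measure; defaults to all
#'   channels with role `"territory"`.
#' @param maxObjects,minVolume,clip passed to [extractTerritories()].
#' @param method,value nucleus threshold settings.
#' @param territoryMethod,territoryValue territory threshold settings
#'   (default half-maximum; see [extractTerritories()]).
#' @param step march increment for [boundaryIntersection()].
#' @return data.frame with columns `scene_id`, `channel`, N/C/B
#'   coordinates (`nx..bz`, um), `R`, `Y` (um) and `percent_rd`.
#' @export
measureScene <- function(scene, sceneId = "scene", channels = NULL,
                         maxObjects = 2L, minVolume = 0.5, clip = TRUE,
                         method = "otsu", value = NULL,
                         territoryMethod = "fractionOfMax",
                         territoryValue = 0.5, step = NULL) {
  nuc <- extractNucleus(scene, method = method, value = value)
  if (is.null(channels))
    channels <- names(scene@channelRoles)[scene@channelRoles == "territory"]
  out <- list()
  for (ch in channels) {
    terr <- extractTerritories(scene, ch, maxObjects = maxObjects,
                               minVolume = minVolume, nucleusMask = nuc,
                               clip = clip, method = territoryMethod,
                               value = territoryValue)
    for (i in seq_len(nrow(terr))) {
      C <- c(terr$cx[i], terr$cy[i], terr$cz[i])
      if (!.insideMask(C, nuc@mask, nuc@voxelSize)) {
        warning("territory centroid outside nucleus mask in ", sceneId,
                " (", ch, "); measurement skipped")
        next
      }
      N <- nuc@center
      if (sqrt(sum((C - N)^2)) == 0) {
        # centroid exactly at the centre: %RD is 0 by definition
        out[[length(out) + 1L]] <- data.frame(
          scene_id = sceneId, channel = ch,
          nx = N[1], ny = N[2], nz = N[3],
          cx = C[1], cy = C[2], cz = C[3],
          bx = NA_real_, by = NA_real_, bz = NA_real_,
          R = 0, Y = NA_real_, percent_rd = 0
        )
        next
      }
      B <- boundaryIntersection(nuc, N, C, step = step)
      out[[length(out) + 1L]] <- data.frame(
        scene_id = sceneId, channel = ch,
        nx = N[1], ny = N[2], nz = N[3],
        cx = C[1], cy = C[2], cz = C[3],
        bx = B[1], by = B[2], bz = B[3],
        R = sqrt(sum((C - N)^2)), Y = sqrt(sum((B - N)^2)),
        percent_rd = percentRD(N, C, B)
      )
    }
  }
  if (!length(out))
    return(data.frame(scene_id = character(), channel = character(),
                      nx = numeric(), ny = numeric(), nz = numeric(),
                      cx = numeric(), cy = numeric(), cz = numeric(),
                      bx = numeric(), by = numeric(), bz = numeric(),
                      R = numeric(), Y = numeric(),
                      percent_rd = numeric()))
  do.call(rbind, out)
}

#' Summarize pooled percent radial distances
#'
#' Sample median plus the 20-percent-bin frequency distribution
#' (`[0,20) [20,40) [40,60) [60,80) [80,100]`; a value of exactly 20
#' falls in the second bin, 100 in the last).
#'
#' @param values numeric vector of percent radial distances (pooled
#'   across replicates).
#' @param condition condition label.
#' @param chromosome chromosome label.
#' @return an [`RDSummary`][RDSummary-class].
#' @export
summarizeRD <- function(values, condition, chromosome) {
  if (length(values) == 0) stop("no values to summarize")
  if (any(!is.finite(values)) || any(values < 0 | values > 100))
    stop("percent radial distances must be finite and in [0, 100]")
  counts <- tabulate(findInterval(values, c(0, 20, 40, 60, 80)), 5)
  methods::new("RDSummary",
    condition = condition, chromosome = chromosome,
    values = as.numeric(values), n = length(values),
    median = stats::median(values),
    binFrequencies = counts / length(values)
  )
}

#' Mann-Whitney comparison of two radial-distance distributions
#'
#' Two-sided Mann-Whitney-Wilcoxon rank-sum test via
#' [stats::wilcox.test()]: exact enumeration for small untied samples,
#' tie-corrected normal approximation otherwise. The U statistic
#' follows the convention that counts pairs `(a_i, b_j)` with
#' `a_i > b_j` (plus half the ties), so `a = 1,2,3` versus
#' `b = 4,5,6` gives U = 0.
#'
#' @param a,b [`RDSummary`][RDSummary-class] objects or numeric vectors.
#' @param exact force exact enumeration (TRUE), the normal
#'   approximation (FALSE), or choose automatically (NULL, the
#'   default: exact for untied samples with `n_a + n_b <= 50`).
#' @return list with `U`, `p.value`, `n.a`, `n.b` and `method`.
#' @export
compareRD <- function(a, b, exact = NULL) {
  va <- if (methods::is(a, "RDSummary")) a@values else as.numeric(a)
  vb <- if (methods::is(b, "RDSummary")) b@values else as.numeric(b)
  if (!length(va) || !length(vb)) stop("both samples must be non-empty")
  ties <- any(duplicated(c(va, vb)))
  if (is.null(exact)) exact <- !ties && (length(va) + length(vb) <= 50)
  wt <- suppressWarnings(stats::wilcox.test(
    va, vb, alternative = "two.sided", exact = exact, correct = !exact
  ))
  list(U = unname(wt$statistic), p.value = wt$p.value,
       n.a = length(va), n.b = length(vb), method = wt$method)
}

#' Median shift table across conditions
#'
#' For every condition and chromosome, the shift
#' `delta = median(condition) - median(reference)` in percentage
#' points, with the sign convention `+` = movement towards the nuclear
#' periphery and `-` = towards the centre; optionally the
#' between-chromosome shift `delta_pair = median(chrA) - median(chrB)`
#' within each condition.
#'
#' @param summaries either a list of [`RDSummary`][RDSummary-class]
#'   objects or a data.frame with columns `condition`, `chromosome`,
#'   `median`.
#' @param reference reference condition label (its shift is 0).
#' @param pair optional character length-2 `c(chrA, chrB)` for the
#'   per-condition between-chromosome shift column.
#' @return data.frame with one row per condition x chromosome:
#'   `condition`, `chromosome`, `median`, `delta`, and (when `pair` is
#'   given) `delta_pair` repeated within the condition.
#' @export
shiftTable <- function(summaries, reference, pair = NULL) {
  if (is.data.frame(summaries)) {
    df <- summaries
    need <- c("condition", "chromosome", "median")
    if (!all(need %in% names(df)))
      stop("data.frame input needs columns: ",
           paste(need, collapse = ", "))
    df <- df[, need]
  } else if (is.list(summaries)) {
    stopifnot(all(vapply(summaries, methods::is, logical(1), "RDSummary")))
    df <- data.frame(
      condition = vapply(summaries, function(s) s@condition, character(1)),
      chromosome = vapply(summaries, function(s) s@chromosome, character(1)),
      median = vapply(summaries, function(s) s@median, numeric(1))
    )
  } else stop("summaries must be a list of RDSummary or a data.frame")
  if (!reference %in% df$condition)
    stop("reference condition '", reference, "' not present")
  if (anyDuplicated(df[, c("condition", "chromosome")]))
    stop("duplicated condition x chromosome entries")
  refMed <- df$median[df$condition == reference]
  names(refMed) <- df$chromosome[df$condition == reference]
  if (any(!df$chromosome %in% names(refMed)))
    stop("reference condition lacks some chromosomes")
  df$delta <- df$median - refMed[df$chromosome]
  if (!is.null(pair)) {
    stopifnot(length(pair) == 2L)
    dp <- vapply(unique(df$condition), function(cond) {
      m <- df$median[df$condition == cond]
      names(m) <- df$chromosome[df$condition == cond]
      if (!all(pair %in% names(m))) return(NA_real_)
      unname(m[pair[1]] - m[pair[2]])
    }, numeric(1))
    df$delta_pair <- dp[df$condition]
  }
  rownames(df) <- NULL
  df
}
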