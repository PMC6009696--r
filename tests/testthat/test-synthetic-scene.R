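# Synthetic generators: ground-truth fidelity, determinism, noise-free
# exactness, and the planted structure of expression and section
# simulators.

test_that("requested fractional radial position is recorded exactly", {
  for (f in c(0, 0.25, 0.6, 0.95)) {
    p <- cleanSceneParams(list(territorySpec("green", f,
                                             direction = c(1, 0, 0))),
                          seed = 7)
    s <- renderScene(p)
    expect_identical(sceneTruth(s)$territories$fractionalRD, f)
    # truth centre sits at f times the analytic boundary distance
    tr <- sceneTruth(s)
    a <- tr$nucleusSemiaxes[1]
    expect_equal(tr$territories$cx - tr$nucleusCenter[1], f * a,
                 tolerance = 1e-12)
  }
})

test_that("noise-free blue channel thresholds to the exact truth mask", {
  s <- renderScene(cleanSceneParams(seed = 3))
  truthMask <- sceneTruth(s)$nucleusMask
  peak <- max(channelArray(s, "blue"))
  for (t in c(1, peak / 2, peak - 1)) {
    got <- thresholdChannel(s, "blue", method = "fixed", value = t)
    expect_identical(as.logical(got), as.logical(truthMask))
  }
})

test_that("rendering is a pure function of its parameters", {
  p <- smallSceneParams(list(territorySpec("green", 0.5)), seed = 42)
  s1 <- renderScene(p)
  s2 <- renderScene(p)
  expect_identical(s1@voxels, s2@voxels)
  p2 <- smallSceneParams(list(territorySpec("green", 0.5)), seed = 43)
  expect_false(identical(renderScene(p2)@voxels, s1@voxels))
})

test_that("render does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(renderScene(smallSceneParams(seed = 5)))
  expect_identical(.Random.seed, before)
})

test_that("blobs that cannot fit are shrunk by default and error in strict mode", {
  big <- territorySpec("green", 0.9, direction = c(1, 0, 0),
                       blobSemiaxes = c(1.5, 1.5, 1.2))
  s <- renderScene(cleanSceneParams(list(big), seed = 1))
  tr <- sceneTruth(s)$territories
  expect_true(tr$shrunk)
  expect_lt(tr$appliedA, 1.5)
  expect_error(
    renderScene(cleanSceneParams(list(big), seed = 1, shrinkToFit = FALSE)),
    "does not fit"
  )
})

test_that("scene parameter invariants are enforced", {
  expect_error(sceneParams(nucleusSemiaxes = c(-1, 2, 2)))
  expect_error(sceneParams(bitDepth = 12L))
  expect_error(sceneParams(frameShape = c(20L, 20L, 10L)),
               "does not fit")
  expect_error(territorySpec("green", 1.2))
  expect_error(territorySpec("green", 0.5, direction = c(0, 0, 0)))
})

test_that("expression simulator honours silent fraction and plants calls binomially", {
  chroms <- c(chr1 = 400L, chr2 = 400L)
  allSilent <- simulateExpression(expressionSimParams(
    chroms, fractionSilent = 1, seed = 2))
  expect_identical(unname(transcribingCounts(allSilent, "glass")),
                   c(0L, 0L))

  p <- expressionSimParams(c(chrA = 1000L), fractionSilent = 0,
                           upFraction = 0.1, downFraction = 0.05,
                           seed = 11)
  tab <- simulateExpression(p)
  calls <- callDeregulated(tab, "soft")
  nUp <- sum(calls == "up")
  # planted Bernoulli(0.1) over 1000 genes: 100 +/- 4 binomial sd
  expect_lt(abs(nUp - 100), 4 * sqrt(1000 * 0.1 * 0.9))
  # calls recover the planted labels exactly (effects clear the threshold)
  expect_identical(unname(calls), tab$planted_soft)
  expect_identical(simulateExpression(p), tab)
})

test_that("expression simulator rejects empty or malformed chromosome maps", {
  expect_error(expressionSimParams(integer(0)))
  expect_error(expressionSimParams(c(100L)), "named")
})

test_that("envelope sections realize the requested rim-to-interior ratio", {
  flat <- simulateEnvelopeSections(envelopeSimParams(
    rimToInteriorRatio = 1, noiseSigma = 0, nNuclei = 1, seed = 4,
    centerJitter = 0))[[1]]
  vals <- flat@image[flat@mask]
  expect_true(all(vals == vals[1]))

  p3 <- envelopeSimParams(rimToInteriorRatio = 3, noiseSigma = 0,
                          nNuclei = 1, seed = 4, centerJitter = 0)
  sec <- simulateEnvelopeSections(p3)[[1]]
  nx <- nrow(sec@image)
  xs <- (seq_len(nx) - 0.5) * sec@pixelSize
  ys <- (seq_len(ncol(sec@image)) - 0.5) * sec@pixelSize
  ctr <- c(nx, ncol(sec@image)) * sec@pixelSize / 2
  r <- sqrt(outer((xs - ctr[1])^2, (ys - ctr[2])^2, `+`))
  rim <- sec@mask & r > p3$nucleusRadius - p3$rimWidth
  interior <- r <= p3$nucleusRadius - p3$rimWidth
  expect_equal(mean(sec@image[rim]) / mean(sec@image[interior]), 3,
               tolerance = 1e-12)

  expect_identical(
    simulateEnvelopeSections(envelopeSimParams(nNuclei = 0, seed = 1)),
    list())
  expect_error(envelopeSimParams(rimWidth = 6, nucleusRadius = 5))
})

test_that("downstream recovery error grows with blur and noise", {
  recoveryErr <- function(psf, noise) {
    errs <- vapply(1:4, function(sd) {
      p <- sceneParams(
        nucleusSemiaxes = c(3, 2.4, 1.8), voxelSize = c(0.15, 0.15, 0.3),
        psfSigma = psf, noiseModel = "gaussian", noiseSigma = noise,
        territories = list(territorySpec("green", 0.5)), seed = sd
      )
      m <- suppressWarnings(measureScene(renderScene(p), "x"))
      if (nrow(m)) abs(m$percent_rd[1] - 50) else NA_real_
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }
  e1 <- recoveryErr(c(0, 0, 0), 0)
  e2 <- recoveryErr(c(0.2, 0.2, 0.4), 0.02)
  e3 <- recoveryErr(c(0.5, 0.5, 0.8), 0.05)
  expect_lte(e1, e2 + 0.5)  # allow half a point of sampling slack
  expect_lte(e2, e3 + 0.5)
  expect_lt(e1, 1.5)
})
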