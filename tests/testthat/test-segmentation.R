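# Thresholding, connected components, centroids and their geometric
# contracts.

test_that("noise-free segmentation reproduces the truth mask and centre", {
  s <- renderScene(cleanSceneParams(seed = 5))
  nuc <- extractNucleus(s)
  expect_identical(nuc@mask, sceneTruth(s)$nucleusMask)
  # analytic centroid: nucleus is centred in the frame
  expect_lt(max(abs(nuc@center - sceneTruth(s)$nucleusCenter)),
            max(voxelSize(s)) / 2)
  expect_equal(nuc@volume, sum(nuc@mask) * prod(voxelSize(s)))
  expect_false(nuc@truncated)
})

test_that("degenerate channels are rejected with informative errors", {
  s <- renderScene(cleanSceneParams(seed = 5))
  expect_error(thresholdChannel(s, "green"), "all zero")
  const <- bareScene(array(7, c(8, 8, 4)))
  expect_error(thresholdChannel(const, "blue", "otsu"), "constant")
  expect_error(thresholdChannel(s, "missing"), "unknown channel")
})

test_that("fixed threshold below the minimum keeps every voxel", {
  s <- renderScene(smallSceneParams(seed = 5, noiseModel = "none",
                                    backgroundLevel = 0.2))
  blue <- channelArray(s, "blue")
  expect_gt(min(blue), 0)
  got <- thresholdChannel(s, "blue", "fixed", value = min(blue) - 1)
  expect_true(all(got))
})

test_that("centroid equals the mean of voxel-centre coordinates", {
  # brute-force oracle on a constructed 3-voxel territory
  g <- array(0, c(10, 10, 6))
  g[3, 4, 2] <- 200; g[4, 4, 2] <- 200; g[3, 5, 2] <- 200
  s <- bareScene(array(0, c(10, 10, 6)), green = g,
                 voxelSize = c(0.25, 0.25, 0.5))
  terr <- extractTerritories(s, "green", minVolume = 0)
  vc <- rbind(c(3, 4, 2), c(4, 4, 2), c(3, 5, 2))
  expected <- colMeans(sweep(vc, 2, 0.5) *
                         matrix(c(0.25, 0.25, 0.5), 3, 3, byrow = TRUE))
  expect_equal(unlist(terr[1, c("cx", "cy", "cz")], use.names = FALSE),
               expected, tolerance = 1e-12)
})

test_that("intensity weighting shifts the centroid toward bright voxels", {
  g <- array(0, c(10, 10, 6))
  g[3, 4, 2] <- 60; g[4, 4, 2] <- 240   # asymmetric brightness
  s <- bareScene(array(0, c(10, 10, 6)), green = g,
                 voxelSize = c(0.25, 0.25, 0.5))
  un <- extractTerritories(s, "green", minVolume = 0,
                           method = "fixed", value = 10)
  wt <- extractTerritories(s, "green", minVolume = 0, weighted = TRUE,
                           method = "fixed", value = 10)
  expect_equal(un$cx, mean(c(2.5, 3.5)) * 0.25, tolerance = 1e-12)
  expect_equal(wt$cx, (2.5 * 60 + 3.5 * 240) / 300 * 0.25,
               tolerance = 1e-12)
  expect_identical(un$cy, wt$cy)
})

test_that("largest connected component wins and truncation is flagged", {
  blue <- array(0, c(20, 12, 8))
  blue[2:5, 2:5, 2:4] <- 150        # 48 voxels
  blue[10:17, 2:7, 2:5] <- 150      # 192 voxels
  s <- bareScene(blue)
  nuc <- extractNucleus(s, method = "fixed", value = 100)
  expect_equal(sum(nuc@mask), 192)
  expect_false(nuc@truncated)

  edge <- array(0, c(12, 12, 6))
  edge[1:6, 3:8, 2:4] <- 150        # touches the x = 1 face
  expect_warning(
    nucE <- extractNucleus(bareScene(edge), method = "fixed", value = 100),
    "truncated")
  expect_true(nucE@truncated)
})

test_that("interior cavities are filled in the nucleus mask", {
  blue <- array(0, c(14, 14, 8))
  blue[3:12, 3:12, 2:7] <- 150
  blue[7:8, 7:8, 4:5] <- 0          # cavity
  nuc <- extractNucleus(bareScene(blue), method = "fixed", value = 100)
  expect_true(all(nuc@mask[7:8, 7:8, 4:5]))
})

test_that("territory extraction respects volume floor, cap, and clipping", {
  # homologs far enough apart that their blobs stay disjoint
  s <- renderScene(cleanSceneParams(
    list(territorySpec("green", 0.6, direction = c(1, 0, 0)),
         territorySpec("green", 0.6, direction = c(-1, 0, 0))),
    seed = 8))
  nuc <- extractNucleus(s)
  terr <- extractTerritories(s, "green", nucleusMask = nuc)
  expect_equal(nrow(terr), 2L)
  tr <- sceneTruth(s)$territories
  # each homolog centre within half a voxel of the planted truth
  for (i in 1:2) {
    expect_lt(min(pmax(abs(terr$cx[i] - tr$cx),
                       abs(terr$cy[i] - tr$cy),
                       abs(terr$cz[i] - tr$cz))), max(voxelSize(s)) / 2)
  }
  expect_identical(nrow(extractTerritories(s, "green",
                                           minVolume = 1e3)), 0L)
  expect_identical(nrow(extractTerritories(s, "green", maxObjects = 1L)),
                   1L)
  expect_error(extractTerritories(s, "blue"), "not a territory")
})

test_that("sub-volume speckles are excluded by the volume floor", {
  g <- array(0, c(20, 20, 10))
  g[5:12, 5:12, 3:7] <- 200                  # real object, 320 voxels
  g[18, 18, 9] <- 200                        # single-voxel speckle
  s <- bareScene(array(0, c(20, 20, 10)), green = g,
                 voxelSize = c(0.2, 0.2, 0.4))
  terr <- extractTerritories(s, "green", minVolume = 0.5, maxObjects = 5L)
  expect_equal(nrow(terr), 1L)
  expect_equal(terr$voxelCount, 320L)
})

test_that("physical scaling multiplies centres without changing voxels", {
  s1 <- renderScene(cleanSceneParams(seed = 9))
  s2 <- s1
  s2@voxelSize <- s1@voxelSize * 3
  n1 <- extractNucleus(s1)
  n2 <- extractNucleus(s2)
  expect_equal(n2@center, n1@center * 3, tolerance = 1e-12)
  expect_equal(n2@volume, n1@volume * 27, tolerance = 1e-9)
})

test_that("nucleus centre follows a 90-degree rotation about z", {
  p <- cleanSceneParams(seed = 10)
  s <- renderScene(p)
  rot <- s
  d <- dim(s@voxels)
  # (x, y) -> (y, nx + 1 - x); requires square xy voxels, so permute
  rot@voxels <- aperm(s@voxels, c(2, 1, 3, 4))[, rev(seq_len(d[1])), , ,
                                               drop = FALSE]
  rot@voxelSize <- s@voxelSize[c(2, 1, 3)]
  n1 <- extractNucleus(s)
  n2 <- extractNucleus(rot)
  mapped <- c(n1@center[2], d[1] * s@voxelSize[1] - n1@center[1],
              n1@center[3])
  expect_lt(max(abs(n2@center - mapped)), max(s@voxelSize) / 2)
})
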