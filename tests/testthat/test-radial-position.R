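# Ray-boundary geometry, the percent radial distance statistic, its
# summaries, the rank-sum comparison and the shift-table arithmetic.

sphereMask <- function(r = 8, voxel = 0.5, pad = 2) {
  n <- ceiling(2 * (r + pad) / voxel)
  dims <- c(n, n, n)
  ctr <- dims * voxel / 2
  blue <- ellipsoidArray(dims, rep(voxel, 3), ctr, rep(r, 3))
  nuc <- extractNucleus(bareScene(blue, voxelSize = rep(voxel, 3)),
                        method = "fixed", value = 100)
  list(nuc = nuc, ctr = ctr, r = r, step = voxel / 2)
}

test_that("boundary intersection matches the analytic sphere and ellipsoid", {
  sm <- sphereMask()
  for (u in list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1) / sqrt(3))) {
    B <- boundaryIntersection(sm$nuc, sm$ctr, sm$ctr + u)
    expect_lt(abs(sqrt(sum((B - sm$ctr)^2)) - sm$r),
              sm$step + max(voxelSize(sm$nuc)) / 2)
  }
  # axis-aligned ellipsoid: |NB| equals each semiaxis along that axis
  dims <- c(60, 44, 30)
  vs <- c(0.4, 0.4, 0.4)
  ctr <- dims * vs / 2
  ax <- c(10, 7, 5)
  blue <- ellipsoidArray(dims, vs, ctr, ax)
  nuc <- extractNucleus(bareScene(blue, voxelSize = vs),
                        method = "fixed", value = 100)
  for (i in 1:3) {
    u <- c(0, 0, 0); u[i] <- 1
    B <- boundaryIntersection(nuc, ctr, ctr + u)
    expect_lt(abs(sqrt(sum((B - ctr)^2)) - ax[i]), 0.2 + vs[i] / 2)
  }
})

test_that("degenerate ray geometry is rejected", {
  sm <- sphereMask()
  expect_error(boundaryIntersection(sm$nuc, sm$ctr, sm$ctr),
               "undefined direction")
  outside <- sm$ctr + c(sm$r + 1.5, 0, 0)
  expect_error(boundaryIntersection(sm$nuc, outside, sm$ctr),
               "outside")
})

test_that("percent radial distance hits its definitional endpoints", {
  N <- c(5, 5, 5)
  B <- c(13, 5, 5)
  expect_identical(percentRD(N, N, B), 0)
  expect_identical(percentRD(N, B, B), 100)
  expect_equal(percentRD(N, c(11, 5, 5), c(15, 5, 5)), 60)
  expect_error(percentRD(N, B, N), "degenerate")
  expect_warning(v <- percentRD(N, c(14, 5, 5), B), "clamped")
  expect_identical(v, 100)
  expect_warning(percentRD(N, c(11, 8, 5), B), "collinear")
})

test_that("measured %RD recovers the planted position on clean scenes", {
  p <- cleanSceneParams(list(territorySpec("green", 0.6),
                             territorySpec("red", 0.3)), seed = 21)
  m <- measureScene(renderScene(p), "clean")
  expect_equal(nrow(m), 2L)
  expect_lt(abs(m$percent_rd[m$channel == "green"] - 60), 1)
  expect_lt(abs(m$percent_rd[m$channel == "red"] - 30), 1)
  expect_true(all(m$Y >= m$R))

  empty <- measureScene(renderScene(cleanSceneParams(seed = 2)), "none")
  expect_identical(nrow(empty), 0L)
})

test_that("%RD is exactly invariant under uniform voxel rescaling", {
  p <- smallSceneParams(list(territorySpec("green", 0.45)), seed = 30)
  s1 <- renderScene(p)
  s2 <- s1
  s2@voxelSize <- s1@voxelSize * 2.5
  m1 <- measureScene(s1, "a")
  m2 <- measureScene(s2, "b")
  expect_equal(m2$percent_rd, m1$percent_rd, tolerance = 1e-12)
})

test_that("%RD changes by under a point under 90-degree rotation", {
  p <- smallSceneParams(list(territorySpec("green", 0.55)), seed = 31)
  s <- renderScene(p)
  rot <- s
  d <- dim(s@voxels)
  rot@voxels <- aperm(s@voxels, c(2, 1, 3, 4))[, rev(seq_len(d[1])), , ,
                                               drop = FALSE]
  rot@voxelSize <- s@voxelSize[c(2, 1, 3)]
  m1 <- measureScene(s, "a")
  m2 <- measureScene(rot, "b")
  expect_equal(nrow(m1), nrow(m2))
  expect_lt(abs(m1$percent_rd - m2$percent_rd), 1)
})

test_that("summaries bin at 20-point edges with the stated conventions", {
  s <- summarizeRD(c(10, 30, 50, 70, 90), "glass", "CT18")
  expect_equal(s@binFrequencies, rep(0.2, 5))
  expect_equal(s@median, 50)
  expect_equal(s@n, 5L)

  sEdge <- summarizeRD(c(20), "glass", "CT18")
  expect_equal(sEdge@binFrequencies, c(0, 1, 0, 0, 0))
  sTop <- summarizeRD(c(100, 100), "glass", "CT18")
  expect_equal(sTop@binFrequencies, c(0, 0, 0, 0, 1))
  expect_error(summarizeRD(numeric(0), "glass", "CT18"), "no values")
  expect_error(summarizeRD(c(50, 101), "glass", "CT18"))
})

test_that("rank-sum comparison follows the documented U convention", {
  r <- compareRD(c(1, 2, 3), c(4, 5, 6))
  expect_identical(r$U, 0)
  same <- compareRD(c(10, 20, 30, 40), c(10, 20, 30, 40))
  expect_gt(same$p.value, 0.99)
  # exact and approximate p agree to within 0.05 at n = 5 + 5
  set.seed(7)
  a <- rnorm(5); b <- rnorm(5, 1)
  pe <- compareRD(a, b, exact = TRUE)$p.value
  pa <- compareRD(a, b, exact = FALSE)$p.value
  expect_lt(abs(pe - pa), 0.05)
})

test_that("rank-sum p agrees with exhaustive enumeration", {
  set.seed(12)
  for (na in c(2, 4, 6)) for (nb in c(3, 5)) {
    a <- rnorm(na); b <- rnorm(nb, 0.8)
    got <- compareRD(a, b)
    oracle <- mwEnumerate(a, b)
    expect_equal(got$U, oracle$U)
    expect_equal(got$p.value, oracle$p, tolerance = 1e-10)
  }
})

test_that("shift table arithmetic, sign convention and pair column", {
  med <- data.frame(
    condition = rep(c("2kPa", "glass"), each = 2),
    chromosome = rep(c("CT18", "CT19"), 2),
    median = c(56.56, 49.40, 66.38, 54.73)
  )
  st <- shiftTable(med, reference = "2kPa", pair = c("CT18", "CT19"))
  expect_equal(st$delta[st$condition == "2kPa"], c(0, 0))
  expect_equal(st$delta[st$condition == "glass" &
                          st$chromosome == "CT18"], 9.82,
               tolerance = 1e-9)
  expect_equal(unique(st$delta_pair[st$condition == "2kPa"]), 7.16,
               tolerance = 1e-9)
  expect_error(shiftTable(med, reference = "55kPa"), "not present")
  expect_error(shiftTable(med[med$chromosome == "CT18", ][0, ],
                          reference = "2kPa"))
})

test_that("shift table accepts RDSummary lists", {
  ss <- list(summarizeRD(c(40, 50, 60), "soft", "CT18"),
             summarizeRD(c(60, 70, 80), "glass", "CT18"))
  st <- shiftTable(ss, reference = "soft")
  expect_equal(st$delta[st$condition == "glass"], 20)
})
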