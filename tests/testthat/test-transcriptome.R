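# Deregulation summaries: transcribing filter, fold-change calls,
# normalizations and overlap arithmetic.

toyTable <- function() {
  data.frame(
    gene_id = paste0("g", 1:6),
    chromosome = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
    fpkm_glass = c(0.5, 1.0, 2.0, 5, 8, 0.2),
    fpkm_soft = c(0.5, 4.0, 8.0, 5, 0.1, 0.2),
    log2fc_soft = c(0, 2.0, -1.9, 0.4, -6.3, NA)
  )
}

test_that("transcribing filter is strictly greater than the threshold", {
  tab <- toyTable()
  # FPKM 0.5, 1.0, 2.0 on chr1: only 2.0 passes FPKM > 1
  expect_identical(transcribingCounts(tab, "glass", "chr1"), 1L)
  expect_identical(unname(transcribingCounts(tab, "glass")), c(1L, 2L))
  expect_identical(unname(transcribingCounts(tab, "glass", fpkmMin = 0)),
                   c(3L, 3L))
  # any-condition anchor picks up genes induced on soft
  expect_identical(transcribingCounts(tab, c("glass", "soft"), "chr1"),
                   2L)
  expect_error(transcribingCounts(tab, "glass", "chrX"), "unknown")
})

test_that("deregulation calls are inclusive at the fold-change boundary", {
  tab <- toyTable()
  expect_warning(calls <- callDeregulated(tab, "soft"), "skipped")
  expect_identical(unname(calls[1:5]),
                   c("none", "up", "none", "none", "down"))
  expect_true(is.na(calls[6]))
})

test_that("percent deregulation normalizes calls to transcribing genes", {
  tab <- data.frame(
    gene_id = paste0("g", 1:12),
    chromosome = rep("chr1", 12),
    fpkm_glass = c(rep(10, 10), 0.5, 0.5),
    fpkm_soft = rep(10, 12),
    log2fc_soft = c(3, -2.5, rep(0, 10))
  )
  pd <- percentDeregulation(tab, "soft", reference = "glass")
  expect_equal(unname(pd), 20)  # 2 of 10 transcribing

  none <- tab; none$log2fc_soft <- 0
  expect_equal(unname(percentDeregulation(none, "soft",
                                          reference = "glass")), 0)
  silent <- tab; silent$fpkm_glass <- 0.5
  expect_true(is.na(percentDeregulation(silent, "soft",
                                        reference = "glass")))
})

test_that("pooling over conditions counts a gene once", {
  tab <- data.frame(
    gene_id = paste0("g", 1:10),
    chromosome = rep("chr1", 10),
    fpkm_glass = rep(10, 10),
    fpkm_a = rep(10, 10), fpkm_b = rep(10, 10),
    log2fc_a = c(3, 3, rep(0, 8)),
    log2fc_b = c(3, 0, -4, rep(0, 7))
  )
  pd <- percentDeregulation(tab, c("a", "b"), reference = "glass")
  expect_equal(unname(pd), 30)  # union of {g1, g2} and {g1, g3}
})

test_that("enrichment sums to 100 percent per direction", {
  tab <- data.frame(
    gene_id = paste0("g", 1:8),
    chromosome = c(rep("chr1", 2), rep("chr2", 2), rep("chr3", 2),
                   rep("chr4", 2)),
    fpkm_glass = rep(10, 8), fpkm_soft = rep(10, 8),
    log2fc_soft = rep(c(2.5, -0.1), 4)
  )
  en <- deregEnrichment(tab, "soft", "up")
  expect_equal(unname(en), rep(25, 4))
  expect_equal(sum(en), 100, tolerance = 1e-9)
  one <- tab; one$log2fc_soft <- ifelse(one$chromosome == "chr2",
                                        3, 0)
  enOne <- deregEnrichment(one, "soft", "up")
  expect_equal(unname(enOne[c("chr1", "chr2")]), c(0, 100))
  expect_error(deregEnrichment(tab, "soft", "down"), "no down")
})

test_that("fold-change bins are left-closed and total the call count", {
  tab <- data.frame(
    gene_id = paste0("g", 1:4),
    chromosome = "chr1",
    fpkm_glass = 10, fpkm_soft = 10,
    log2fc_soft = c(2.5, 5, 10, 2.0)
  )
  bins <- foldChangeBins(tab, "soft", "up", edges = c(2, 4, 8))
  expect_identical(unname(bins), c(2L, 1L, 1L))
  expect_identical(sum(bins),
                   sum(callDeregulated(tab, "soft") == "up"))
  expect_identical(unname(foldChangeBins(tab, "soft", "down",
                                         edges = c(2, 4, 8))),
                   c(0L, 0L, 0L))
  expect_error(foldChangeBins(tab, "soft", "up", edges = c(4, 2)),
               "increasing")
})

test_that("overlap counts satisfy the set identities", {
  set.seed(3)
  genes <- paste0("g", 1:200)
  mk <- function(upSet) {
    calls <- setNames(rep("none", 200), genes)
    calls[upSet] <- "up"
    calls
  }
  aUp <- sample(genes, 60); bUp <- sample(genes, 45)
  ov <- overlapCounts(mk(aUp), mk(bUp), "up")
  expect_identical(ov$common, length(intersect(aUp, bUp)))
  expect_identical(ov$total_a, ov$unique_a + ov$common)
  expect_identical(ov$total_b, ov$unique_b + ov$common)
  # union counted once each
  expect_identical(ov$unique_a + ov$unique_b + ov$common,
                   length(union(aUp, bUp)))
  disjoint <- overlapCounts(mk(genes[1:10]), mk(genes[11:30]), "up")
  expect_identical(disjoint$common, 0L)
  expect_error(overlapCounts(mk(aUp)[1:100], mk(bUp), "up"),
               "universe")
})

test_that("overlap arithmetic from totals enforces consistency", {
  ov <- overlapFromCounts(783, 649, 670, 536)
  expect_identical(ov$common, 113)
  expect_error(overlapFromCounts(783, 649, 670, 540), "inconsistent")
})

test_that("planted per-chromosome fractions are recovered on simulation", {
  fracs <- c(chr1 = 0.16, chr2 = 0.09, chr3 = 0.09)
  p <- expressionSimParams(
    nGenesPerChromosome = c(chr1 = 500L, chr2 = 500L, chr3 = 500L),
    fractionSilent = 0,
    upFraction = as.list(fracs / 2), downFraction = as.list(fracs / 2),
    seed = 77
  )
  tab <- simulateExpression(p)
  pd <- percentDeregulation(tab, "soft", reference = "glass")
  for (ch in names(fracs)) {
    se <- sqrt(500 * fracs[[ch]] * (1 - fracs[[ch]])) / 500
    expect_lt(abs(pd[[ch]] / 100 - fracs[[ch]]), 2 * se)
  }
})
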