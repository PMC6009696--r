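# Gene-level deregulation summaries over an expression table:
# transcribing-gene filter (FPKM strictly > 1 by default), fold-change
# calls (|log2FC| >= 2 by default), per-chromosome percent
# deregulation, per-chromosome enrichment of deregulated genes, bins of
# increasing fold change, and up/down overlap arithmetic between two
# substrate comparisons.

.fpkmCol <- function(table, condition) {
  col <- paste0("fpkm_", condition)
  if (!col %in% names(table))
    stop("no FPKM column for condition '", condition, "'")
  col
}

.lfcCol <- function(table, condition) {
  col <- paste0("log2fc_", condition)
  if (!col %in% names(table))
    stop("no log2 fold-change column for condition '", condition, "'")
  col
}

#' Count transcribing genes per chromosome
#'
#' A gene is transcribing when its FPKM is strictly greater than
#' `fpkmMin` (default 1.0) in the anchor condition(s): by default the
#' single condition given; with several conditions, in any of them.
#'
#' @param table expression data.frame (`gene_id`, `chromosome`,
#'   `fpkm_<condition>` columns).
#' @param condition condition name(s) anchoring the filter.
#' @param chromosome optional single chromosome; when given, returns
#'   one count (error if the chromosome is absent from the table's
#'   declared set).
#' @param fpkmMin strict FPKM threshold (default 1.0).
#' @return named integer vector of counts per chromosome, or a single
#'   count when `chromosome` is given.
#' @export
transcribingCounts <- function(table, condition, chromosome = NULL,
                               fpkmMin = 1.0) {
  cols <- vapply(condition, function(cc) .fpkmCol(table, cc), character(1))
  expr <- Reduce(`|`, lapply(cols, function(cl) table[[cl]] > fpkmMin))
  chroms <- unique(table$chromosome)
  if (!is.null(chromosome)) {
    if (!chromosome %in% chroms)
      stop("unknown chromosome: ", chromosome)
    return(sum(expr & table$chromosome == chromosome))
  }
  counts <- vapply(chroms, function(ch)
    sum(expr & table$chromosome == ch), integer(1))
  names(counts) <- chroms
  counts
}

#' Call per-gene deregulation from log2 fold change
#'
#' `"up"` when `log2fc >= log2fcMin`, `"down"` when
#' `log2fc <= -log2fcMin` (thresholds inclusive), else `"none"`. Genes
#' with missing fold change are skipped with a warning and called `NA`.
#'
#' @param table expression data.frame.
#' @param condition non-reference condition whose `log2fc_<condition>`
#'   column is used.
#' @param log2fcMin call threshold on the log2 scale (default 2).
#' @return character vector (`"up"`, `"down"`, `"none"` or `NA`) named
#'   by `gene_id`.
#' @export
callDeregulated <- function(table, condition, log2fcMin = 2) {
  lfc <- table[[.lfcCol(table, condition)]]
  calls <- ifelse(lfc >= log2fcMin, "up",
                  ifelse(lfc <= -log2fcMin, "down", "none"))
  if (anyNA(lfc)) {
    warning(sum(is.na(lfc)), " gene(s) with missing fold change skipped")
    calls[is.na(lfc)] <- NA_character_
  }
  names(calls) <- table$gene_id
  calls
}

#' Percent transcriptional deregulation per chromosome
#'
#' 100 x (deregulated genes on the chromosome) / (transcribing genes on
#' the chromosome). With several `conditions`, deregulated genes are
#' pooled as the union of the per-condition call sets (a gene counted
#' once however many conditions deregulate it). Chromosomes with zero
#' transcribing genes are reported as `NA` (undefined), not 0.
#'
#' @param table expression data.frame.
#' @param conditions one or more non-reference conditions to pool.
#' @param reference condition anchoring the transcribing filter
#'   (default the first `fpkm_` column's condition).
#' @param anyCondition when TRUE the transcribing filter uses FPKM >
#'   `fpkmMin` in any of `c(reference, conditions)` instead of the
#'   reference alone.
#' @param log2fcMin,fpkmMin thresholds.
#' @param strict when TRUE, deregulated genes must also pass the
#'   transcribing filter; by default they need not (the two counts are
#'   computed independently and one normalized by the other).
#' @return named numeric vector, percent per chromosome.
#' @export
percentDeregulation <- function(table, conditions, reference = NULL,
                                anyCondition = FALSE, log2fcMin = 2,
                                fpkmMin = 1.0, strict = FALSE) {
  if (is.null(reference)) {
    fcols <- grep("^fpkm_", names(table), value = TRUE)
    if (!length(fcols)) stop("table has no fpkm_ columns")
    reference <- sub("^fpkm_", "", fcols[1])
  }
  anchor <- if (anyCondition) c(reference, conditions) else reference
  transcribing <- transcribingCounts(table, anchor, fpkmMin = fpkmMin)
  dereg <- Reduce(`|`, lapply(conditions, function(cc) {
    calls <- callDeregulated(table, cc, log2fcMin)
    !is.na(calls) & calls != "none"
  }))
  if (strict) {
    cols <- vapply(anchor, function(cc) .fpkmCol(table, cc), character(1))
    expr <- Reduce(`|`, lapply(cols, function(cl) table[[cl]] > fpkmMin))
    dereg <- dereg & expr
  }
  chroms <- names(transcribing)
  out <- vapply(chroms, function(ch) {
    tr <- transcribing[[ch]]
    if (tr == 0) return(NA_real_)
    100 * sum(dereg & table$chromosome == ch) / tr
  }, numeric(1))
  names(out) <- chroms
  out
}

#' Per-chromosome enrichment of deregulated genes
#'
#' 100 x (deregulated genes on the chromosome, in the given direction)
#' / (total deregulated genes in that direction); sums to 100 percent
#' over chromosomes.
#'
#' @param table expression data.frame.
#' @param condition non-reference condition.
#' @param direction `"up"` or `"down"`.
#' @param log2fcMin call threshold.
#' @return named numeric vector summing to 100.
#' @export
deregEnrichment <- function(table, condition, direction = c("up", "down"),
                            log2fcMin = 2) {
  direction <- match.arg(direction)
  calls <- callDeregulated(table, condition, log2fcMin)
  hit <- !is.na(calls) & calls == direction
  total <- sum(hit)
  if (total == 0)
    stop("no ", direction, "-regulated genes in condition '", condition, "'")
  chroms <- unique(table$chromosome)
  out <- vapply(chroms, function(ch)
    100 * sum(hit & table$chromosome == ch) / total, numeric(1))
  names(out) <- chroms
  out
}

#' Histogram of deregulated genes by fold-change magnitude
#'
#' Counts deregulated genes (given direction) in left-closed bins of
#' |log2 fold change|; `edges` are the left edges with an implicit
#' final edge at infinity, so the default `c(2, 4, 8)` gives bins
#' `[2,4) [4,8) [8,Inf)`. Totals equal the direction's call count when
#' `edges[1] == log2fcMin`.
#'
#' @param table expression data.frame.
#' @param condition non-reference condition.
#' @param direction `"up"` or `"down"`.
#' @param edges strictly increasing left bin edges.
#' @param log2fcMin call threshold.
#' @return named integer vector of bin counts.
#' @export
foldChangeBins <- function(table, condition, direction = c("up", "down"),
                           edges = c(2, 4, 8), log2fcMin = 2) {
  direction <- match.arg(direction)
  if (length(edges) < 1 || any(diff(edges) <= 0))
    stop("edges must be strictly increasing")
  calls <- callDeregulated(table, condition, log2fcMin)
  hit <- !is.na(calls) & calls == direction
  mag <- abs(table[[.lfcCol(table, condition)]][hit])
  counts <- tabulate(findInterval(mag, edges), length(edges))
  names(counts) <- paste0("[", edges, ",",
                          c(edges[-1], "Inf"), ")")
  counts
}

#' Overlap of deregulated gene sets between two comparisons
#'
#' Given per-gene calls from two substrate comparisons over the same
#' gene universe, counts genes deregulated (in the given direction) in
#' both, and uniquely in each.
#'
#' @param callsA,callsB named call vectors from [callDeregulated()]
#'   over the same gene universe.
#' @param direction `"up"` or `"down"`.
#' @return list with `total_a`, `total_b`, `unique_a`, `unique_b`,
#'   `common` satisfying `total = unique + common` on each side.
#' @export
overlapCounts <- function(callsA, callsB, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(callsA) != length(callsB) ||
      !setequal(names(callsA), names(callsB)))
    stop("call vectors cover different gene universes")
  callsB <- callsB[names(callsA)]
  a <- names(callsA)[!is.na(callsA) & callsA == direction]
  b <- names(callsB)[!is.na(callsB) & callsB == direction]
  common <- length(intersect(a, b))
  list(total_a = length(a), total_b = length(b),
       unique_a = length(a) - common, unique_b = length(b) - common,
       common = common)
}

#' Overlap arithmetic from printed totals and unique counts
#'
#' Reconstructs the common count from reported totals and unique
#' counts of two deregulated gene sets (`common = total - unique`,
#' which must agree between the two sides).
#'
#' @param totalA,totalB total deregulated genes in each comparison.
#' @param uniqueA,uniqueB genes unique to each comparison.
#' @return list as in [overlapCounts()].
#' @export
overlapFromCounts <- function(totalA, totalB, uniqueA, uniqueB) {
  stopifnot(totalA >= uniqueA, totalB >= uniqueB)
  commonA <- totalA - uniqueA
  commonB <- totalB - uniqueB
  if (commonA != commonB)
    stop("inconsistent counts: total - unique differs between sides (",
         commonA, " vs ", commonB, ")")
  list(total_a = totalA, total_b = totalB,
       unique_a = uniqueA, unique_b = uniqueB, common = commonA)
}
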