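# Synthetic gene-level expression tables with planted per-chromosome
# deregulation structure, emulating an FPKM + log2 fold-change matrix
# from a two-or-three-condition substrate-stiffness comparison.

#' Parameters for expression-table simulation
#'
#' Genes are assigned a baseline FPKM in the reference condition from a
#' log-normal; a `fractionSilent` subset is silent (FPKM <= 1 in every
#' condition). Within each non-reference condition, transcribing genes
#' on each chromosome are independently planted as up- or down-regulated
#' with the requested per-chromosome fractions; planted genes receive a
#' |log2 fold change| of `log2fcMin` plus an exponential excess (so they
#' always clear the call threshold), unplanted genes receive small
#' Gaussian log2 fold-change noise.
#'
#' @param nGenesPerChromosome named integer vector, chromosome -> count.
#' @param conditions character, condition names; the first is the
#'   reference (fold changes are relative to it).
#' @param meanlog,sdlog log-normal parameters of baseline FPKM for
#'   transcribing genes.
#' @param fractionSilent fraction of genes silent in all conditions.
#' @param upFraction,downFraction per-chromosome planted deregulation
#'   fractions; either a single number recycled over chromosomes or a
#'   named list/vector keyed first by condition then chromosome (a named
#'   numeric keyed by chromosome applies to every non-reference
#'   condition). up + down must be <= 1 per chromosome.
#' @param log2fcMin minimum |log2FC| of planted deregulated genes.
#' @param effectRate rate of the exponential excess above `log2fcMin`.
#' @param noiseSd sd of the log2FC noise of unplanted genes.
#' @param seed integer seed.
#' @return a list of class `ExpressionSimParams`.
#' @export
expressionSimParams <- function(nGenesPerChromosome,
                                conditions = c("glass", "soft"),
                                meanlog = 3, sdlog = 1.2,
                                fractionSilent = 0.25,
                                upFraction = 0.05,
                                downFraction = 0.05,
                                log2fcMin = 2,
                                effectRate = 1,
                                noiseSd = 0.2,
                                seed = 1L) {
  if (length(nGenesPerChromosome) == 0)
    stop("nGenesPerChromosome must name at least one chromosome")
  if (is.null(names(nGenesPerChromosome)) ||
      any(!nzchar(names(nGenesPerChromosome))))
    stop("nGenesPerChromosome must be a named vector")
  stopifnot(
    all(nGenesPerChromosome >= 0),
    length(conditions) >= 2,
    fractionSilent >= 0, fractionSilent <= 1,
    log2fcMin >= 0, effectRate > 0, noiseSd >= 0
  )
  p <- list(
    nGenesPerChromosome = nGenesPerChromosome,
    conditions = conditions,
    meanlog = meanlog, sdlog = sdlog,
    fractionSilent = fractionSilent,
    upFraction = upFraction, downFraction = downFraction,
    log2fcMin = log2fcMin, effectRate = effectRate,
    noiseSd = noiseSd, seed = as.integer(seed)
  )
  class(p) <- "ExpressionSimParams"
  p
}

# resolve a fraction spec to a value for (condition, chromosome)
.resolveFraction <- function(spec, condition, chromosome) {
  v <- spec
  if (is.list(v) && condition %in% names(v)) v <- v[[condition]]
  if (!is.null(names(v)) && chromosome %in% names(v)) v <- v[[chromosome]]
  v <- as.numeric(v)[1]
  if (is.na(v) || v < 0 || v > 1)
    stop("deregulation fraction for ", condition, "/", chromosome,
         " must be in [0, 1]")
  v
}

#' Simulate a gene-level expression table
#'
#' @param params an [expressionSimParams()] object.
#' @return data.frame with columns `gene_id`, `chromosome`,
#'   `planted_<condition>` (the planted label, for oracle checks),
#'   `fpkm_<condition>` for every condition and `log2fc_<condition>` for
#'   every non-reference condition.
#' @export
simulateExpression <- function(params) {
  stopifnot(inherits(params, "ExpressionSimParams"))
  withr::with_seed(params$seed, .simulateExpressionImpl(params))
}

.simulateExpressionImpl <- function(p) {
  chroms <- names(p$nGenesPerChromosome)
  ref <- p$conditions[1]
  nonref <- p$conditions[-1]
  rows <- list()
  gi <- 0L
  for (chr in chroms) {
    n <- p$nGenesPerChromosome[[chr]]
    if (n == 0) next
    silent <- stats::runif(n) < p$fractionSilent
    fpkmRef <- ifelse(silent,
                      stats::runif(n, 0, 1),
                      1 + stats::rlnorm(n, p$meanlog, p$sdlog))
    df <- data.frame(
      gene_id = sprintf("%s_g%05d", chr, gi + seq_len(n)),
      chromosome = chr,
      stringsAsFactors = FALSE
    )
    gi <- gi + n
    df[[paste0("fpkm_", ref)]] <- fpkmRef
    for (cond in nonref) {
      fu <- .resolveFraction(p$upFraction, cond, chr)
      fd <- .resolveFraction(p$downFraction, cond, chr)
      if (fu + fd > 1)
        stop("up + down fraction exceeds 1 for ", cond, "/", chr)
      u <- stats::runif(n)
      planted <- ifelse(silent, "none",
                        ifelse(u < fu, "up",
                               ifelse(u < fu + fd, "down", "none")))
      lfc <- stats::rnorm(n, 0, p$noiseSd)
      k <- planted == "up"
      lfc[k] <- p$log2fcMin + stats::rexp(sum(k), p$effectRate)
      k <- planted == "down"
      lfc[k] <- -(p$log2fcMin + stats::rexp(sum(k), p$effectRate))
      fpkm <- fpkmRef * 2^lfc
      fpkm[silent] <- pmin(fpkm[silent], 1)
      df[[paste0("planted_", cond)]] <- planted
      df[[paste0("fpkm_", cond)]] <- fpkm
      df[[paste0("log2fc_", cond)]] <- lfc
    }
    rows[[chr]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
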