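# End-to-end pipeline: configuration validation, deterministic
# per-scene seeding, simulate -> measure -> summarize -> shift-table
# (plus expression and line-scan stages), CSV outputs and a run
# manifest.

.allowedKeys <- list(
  top = c("seed", "stages", "reference", "pair", "scene", "segmentation",
          "conditions", "expression", "linescan", "write_scenes"),
  scene = c("n_per_condition", "nucleus_semiaxes", "voxel_size",
            "frame_shape", "psf_sigma", "noise_model", "noise_sigma",
            "background", "nucleus_fill", "bit_depth", "blob_semiaxes",
            "peak_intensity"),
  segmentation = c("method", "value", "territory_method",
                   "territory_value", "max_objects", "min_volume", "clip"),
  condition = c("name", "territories"),
  territory = c("chromosome", "channel", "frd", "sd"),
  expression = c("n_genes_per_chromosome", "conditions", "fraction_silent",
                 "up_fraction", "down_fraction", "log2fc_min", "fpkm_min",
                 "meanlog", "sdlog"),
  linescan = c("n_nuclei", "rim_to_interior_ratio", "noise_sigma",
               "nucleus_radius", "rim_width", "conditions", "reference")
)

.checkKeys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown config key(s) in ", where, ": ",
         paste(bad, collapse = ", "))
}

#' Default pipeline configuration
#'
#' A small two-condition demonstration: softer-matrix versus glass
#' placements for a peripheral (CT18-like, green) and an interior
#' (CT19-like, red) territory, a handful of nuclei per condition, and
#' the default acquisition geometry. Conditions' `frd` values are the
#' mean fractional radial positions territories are planted at (each
#' territory jittered per nucleus by `sd`).
#'
#' @param nPerCondition nuclei per condition.
#' @param seed global seed; per-scene seeds are derived from it
#'   deterministically.
#' @return nested list accepted by [runPipeline()].
#' @export
defaultPipelineConfig <- function(nPerCondition = 6L, seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = c("simulate", "measure", "summarize", "shift_table"),
    reference = "soft",
    pair = c("CT18", "CT19"),
    write_scenes = FALSE,
    scene = list(
      n_per_condition = as.integer(nPerCondition),
      nucleus_semiaxes = c(6, 4.5, 2.8),
      voxel_size = c(0.105, 0.105, 0.34),
      psf_sigma = c(0.2, 0.2, 0.4),
      noise_model = "gaussian",
      noise_sigma = 0.02,
      background = 0.05,
      nucleus_fill = 0.7,
      bit_depth = 8L,
      blob_semiaxes = c(1.2, 1.2, 1.0),
      peak_intensity = 0.8
    ),
    segmentation = list(method = "otsu", max_objects = 2L,
                        min_volume = 0.5, clip = TRUE),
    conditions = list(
      list(name = "soft", territories = list(
        list(chromosome = "CT18", channel = "green", frd = 0.57, sd = 0.08),
        list(chromosome = "CT19", channel = "red", frd = 0.49, sd = 0.08)
      )),
      list(name = "glass", territories = list(
        list(chromosome = "CT18", channel = "green", frd = 0.66, sd = 0.08),
        list(chromosome = "CT19", channel = "red", frd = 0.55, sd = 0.08)
      ))
    )
  )
}

.validateConfig <- function(config) {
  .checkKeys(config, .allowedKeys$top, "top level")
  if (is.null(config$seed)) stop("config must set a seed")
  if (is.null(config$stages) || !length(config$stages))
    stop("config must select at least one stage")
  known <- c("simulate", "measure", "summarize", "shift_table",
             "dereg", "linescan")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!is.null(config$scene))
    .checkKeys(config$scene, .allowedKeys$scene, "scene")
  if (!is.null(config$segmentation))
    .checkKeys(config$segmentation, .allowedKeys$segmentation,
               "segmentation")
  imaging <- any(c("simulate", "measure", "summarize", "shift_table")
                 %in% config$stages)
  if (imaging) {
    if (is.null(config$conditions) || !length(config$conditions))
      stop("imaging stages need a conditions block")
    condNames <- vapply(config$conditions, function(cc) {
      .checkKeys(cc, .allowedKeys$condition, "conditions entry")
      for (t in cc$territories)
        .checkKeys(t, .allowedKeys$territory, "territory entry")
      cc$name
    }, character(1))
    if ("shift_table" %in% config$stages) {
      if (is.null(config$reference))
        stop("shift_table stage needs a reference condition")
      if (!config$reference %in% condNames)
        stop("reference condition '", config$reference,
             "' is not among the configured conditions")
    }
  }
  if ("dereg" %in% config$stages) {
    if (is.null(config$expression)) stop("dereg stage needs an expression block")
    .checkKeys(config$expression, .allowedKeys$expression, "expression")
  }
  if ("linescan" %in% config$stages && !is.null(config$linescan))
    .checkKeys(config$linescan, .allowedKeys$linescan, "linescan")
  invisible(config)
}

# deterministic per-scene seed expansion from the global seed
.sceneSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483647L)
}

.fmt2 <- function(x) sprintf("%.2f", x)

#' Run the full pipeline from a configuration
#'
#' Executes the selected stages (`simulate`, `measure`, `summarize`,
#' `shift_table`, `dereg`, `linescan`), writes CSV outputs and a JSON
#' run manifest into `outDir`. %RD columns in rendered CSVs are
#' formatted to 2 decimals with full-precision companion columns.
#' Reruns with the same configuration produce identical CSVs.
#'
#' @param config nested list (see [defaultPipelineConfig()]) or path
#'   to a YAML file with the same structure.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the in-memory results
#'   (`measurements`, `summaries`, `shift_table`, `dereg`, `linescan`
#'   as applicable) and the manifest.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  config <- .validateConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "ctRadial",
    version = as.character(utils::packageVersion("ctRadial")),
    started = format(Sys.time(), tz = "UTC"),
    config = config,
    scenes = list()
  )
  results <- list()
  sc <- config$scene
  seg <- config$segmentation
  if (is.null(seg)) seg <- list()
  segDefaults <- list(method = "otsu", value = NULL,
                      territory_method = "fractionOfMax",
                      territory_value = 0.5, max_objects = 2L,
                      min_volume = 0.5, clip = TRUE)
  seg <- utils::modifyList(segDefaults, seg)

  if (any(c("simulate", "measure", "summarize", "shift_table") %in%
            config$stages)) {
    meas <- list()
    idx <- 0L
    for (cond in config$conditions) {
      for (i in seq_len(sc$n_per_condition)) {
        idx <- idx + 1L
        sid <- sprintf("%s_%03d", cond$name, i)
        seed <- .sceneSeed(config$seed, idx)
        specs <- withr::with_seed(.sceneSeed(config$seed, idx + 100000L), {
          lapply(cond$territories, function(t) {
            lapply(1:2, function(h) {  # two homologs per chromosome
              f <- min(max(stats::rnorm(1, t$frd, t$sd), 0.02), 0.98)
              territorySpec(channel = t$channel, fractionalRD = f,
                            direction = "random",
                            blobSemiaxes = sc$blob_semiaxes,
                            peakIntensity = sc$peak_intensity)
            })
          })
        })
        specs <- unlist(specs, recursive = FALSE)
        params <- sceneParams(
          nucleusSemiaxes = sc$nucleus_semiaxes,
          voxelSize = sc$voxel_size,
          frameShape = sc$frame_shape,
          territories = specs,
          psfSigma = sc$psf_sigma,
          noiseModel = if (is.null(sc$noise_model)) "gaussian"
                       else sc$noise_model,
          noiseSigma = sc$noise_sigma,
          backgroundLevel = sc$background,
          nucleusFill = if (is.null(sc$nucleus_fill)) 0.7
                        else sc$nucleus_fill,
          bitDepth = if (is.null(sc$bit_depth)) 8L else sc$bit_depth,
          seed = seed
        )
        scene <- renderScene(params)
        if (isTRUE(config$write_scenes))
          writeScene(scene, file.path(outDir, sid))
        m <- suppressWarnings(measureScene(
          scene, sceneId = sid,
          maxObjects = seg$max_objects, minVolume = seg$min_volume,
          clip = seg$clip, method = seg$method, value = seg$value,
          territoryMethod = seg$territory_method,
          territoryValue = seg$territory_value
        ))
        if (nrow(m)) {
          m$condition <- cond$name
          chmap <- stats::setNames(
            vapply(cond$territories, `[[`, character(1), "chromosome"),
            vapply(cond$territories, `[[`, character(1), "channel"))
          m$chromosome <- unname(chmap[m$channel])
        }
        manifest$scenes[[sid]] <- list(
          scene_id = sid, seed = seed, condition = cond$name,
          n_territories_found = nrow(m)
        )
        meas[[sid]] <- m
      }
    }
    measurements <- do.call(rbind, meas)
    rownames(measurements) <- NULL
    if (is.null(measurements) || nrow(measurements) == 0)
      stop("pipeline produced zero territory measurements")
    results$measurements <- measurements
    out <- measurements
    out$percent_rd_full <- out$percent_rd
    out$percent_rd <- .fmt2(out$percent_rd_full)
    utils::write.csv(out, file.path(outDir, "measurements.csv"),
                     row.names = FALSE)
  }

  if ("summarize" %in% config$stages) {
    m <- results$measurements
    keys <- unique(m[, c("condition", "chromosome")])
    summaries <- lapply(seq_len(nrow(keys)), function(i) {
      v <- m$percent_rd[m$condition == keys$condition[i] &
                          m$chromosome == keys$chromosome[i]]
      summarizeRD(v, keys$condition[i], keys$chromosome[i])
    })
    results$summaries <- summaries
    sdf <- data.frame(
      condition = vapply(summaries, function(s) s@condition, character(1)),
      chromosome = vapply(summaries, function(s) s@chromosome, character(1)),
      n = vapply(summaries, function(s) s@n, integer(1)),
      median = .fmt2(vapply(summaries, function(s) s@median, numeric(1))),
      median_full = vapply(summaries, function(s) s@median, numeric(1))
    )
    bf <- t(vapply(summaries, function(s) s@binFrequencies, numeric(5)))
    colnames(bf) <- c("bin_0_20", "bin_20_40", "bin_40_60", "bin_60_80",
                      "bin_80_100")
    sdf <- cbind(sdf, as.data.frame(bf))
    utils::write.csv(sdf, file.path(outDir, "summaries.csv"),
                     row.names = FALSE)
  }

  if ("shift_table" %in% config$stages) {
    st <- shiftTable(results$summaries, reference = config$reference,
                     pair = config$pair)
    results$shift_table <- st
    out <- st
    for (col in c("median", "delta",
                  intersect("delta_pair", names(out)))) {
      out[[paste0(col, "_full")]] <- out[[col]]
      out[[col]] <- .fmt2(out[[col]])
    }
    utils::write.csv(out, file.path(outDir, "shift_table.csv"),
                     row.names = FALSE)
  }

  if ("dereg" %in% config$stages) {
    ex <- config$expression
    conds <- if (is.null(ex$conditions)) c("glass", "soft") else ex$conditions
    ngpc <- unlist(ex$n_genes_per_chromosome)
    p <- expressionSimParams(
      nGenesPerChromosome = ngpc,
      conditions = conds,
      fractionSilent = if (is.null(ex$fraction_silent)) 0.25
                       else ex$fraction_silent,
      upFraction = if (is.null(ex$up_fraction)) 0.05 else ex$up_fraction,
      downFraction = if (is.null(ex$down_fraction)) 0.05
                     else ex$down_fraction,
      log2fcMin = if (is.null(ex$log2fc_min)) 2 else ex$log2fc_min,
      seed = .sceneSeed(config$seed, 999983L)
    )
    tab <- simulateExpression(p)
    writeExpressionTable(tab, file.path(outDir, "expression.tsv"))
    lfm <- if (is.null(ex$log2fc_min)) 2 else ex$log2fc_min
    fpm <- if (is.null(ex$fpkm_min)) 1.0 else ex$fpkm_min
    nonref <- conds[-1]
    pd <- percentDeregulation(tab, nonref, reference = conds[1],
                              log2fcMin = lfm, fpkmMin = fpm)
    dd <- data.frame(
      chromosome = names(pd),
      transcribing = as.integer(
        transcribingCounts(tab, conds[1], fpkmMin = fpm)[names(pd)]),
      percent_deregulation = unname(pd)
    )
    for (cc in nonref) {
      calls <- callDeregulated(tab, cc, lfm)
      dd[[paste0("up_", cc)]] <- vapply(dd$chromosome, function(ch)
        sum(calls == "up" & tab$chromosome == ch, na.rm = TRUE), integer(1))
      dd[[paste0("down_", cc)]] <- vapply(dd$chromosome, function(ch)
        sum(calls == "down" & tab$chromosome == ch, na.rm = TRUE),
        integer(1))
    }
    results$dereg <- dd
    utils::write.csv(dd, file.path(outDir, "dereg.csv"), row.names = FALSE)
  }

  if ("linescan" %in% config$stages) {
    ls <- config$linescan
    if (is.null(ls)) ls <- list()
    ratios <- if (is.null(ls$rim_to_interior_ratio)) c(glass = 3, soft = 1.5)
              else unlist(ls$rim_to_interior_ratio)
    nn <- if (is.null(ls$n_nuclei)) 8L else ls$n_nuclei
    refName <- if (is.null(ls$reference)) names(ratios)[1] else ls$reference
    secs <- lapply(names(ratios), function(nm) {
      simulateEnvelopeSections(envelopeSimParams(
        rimToInteriorRatio = ratios[[nm]], nNuclei = nn, condition = nm,
        noiseSigma = if (is.null(ls$noise_sigma)) 2 else ls$noise_sigma,
        seed = .sceneSeed(config$seed, 888887L + match(nm, names(ratios)))
      ))
    })
    names(secs) <- names(ratios)
    profs <- lapply(secs, function(ss) lapply(ss, extractLineProfile))
    rows <- lapply(names(profs), function(nm) {
      summ <- averageProfiles(profs[[nm]], profs[[refName]])
      data.frame(
        condition = nm,
        n_nuclei = summ@nProfiles,
        mean_peripheral_ratio = mean(vapply(profs[[nm]], peripheralRatio,
                                            numeric(1))),
        norm_constant = summ@normConstant
      )
    })
    lsdf <- do.call(rbind, rows)
    results$linescan <- lsdf
    utils::write.csv(lsdf, file.path(outDir, "linescan.csv"),
                     row.names = FALSE)
  }

  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  results$manifest <- manifest
  invisible(results)
}
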