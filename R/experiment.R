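# End-to-end experiment orchestration: generate -> score by both routes ->
# statistics -> report bundle, reproducible under one master seed.

#' Build an experiment configuration
#'
#' @param conditions preset names to run (must exist in [presetTable()]).
#' @param replicates replicates per condition (the classical design uses 3).
#' @param fieldsPerReplicate widefield fields per replicate.
#' @param tilesPerCondition single-cell tiles per condition for the flow
#'   route (0 disables the flow route).
#' @param masterSeed master seed; per-condition/replicate streams are
#'   derived deterministically and independently via [childSeed()].
#' @param nCellsTarget untreated cells per field (see [presetTable()]).
#' @param shape field shape in px.
#' @param nc,mmc names of the negative and positive control conditions used
#'   for relative effects.
#' @param microscopyCfg a [microscopyConfig()].
#' @param flowCfg a [flowConfig()].
#' @param gateCfg a [gateConfig()].
#' @param outputDir optional directory for CSV/JSON reports.
#' @return list of class `ExperimentConfig`.
#' @export
experimentConfig <- function(conditions = c("NC", "MMC-0.025"),
                             replicates = 3L, fieldsPerReplicate = 4L,
                             tilesPerCondition = 0L, masterSeed = 1L,
                             shape = c(1800L, 1800L), nCellsTarget = 100L,
                             nc = "NC", mmc = "MMC-0.025",
                             microscopyCfg = microscopyConfig(),
                             flowCfg = flowConfig(),
                             gateCfg = gateConfig(),
                             outputDir = NULL) {
  stopIfNot(replicates >= 1, "replicate count must be >= 1")
  pt <- presetTable(nCellsTarget)
  missing <- setdiff(conditions, names(pt))
  if (length(missing))
    stop("unknown presets: ", paste(missing, collapse = ", "))
  cfg <- list(conditions = conditions, replicates = as.integer(replicates),
              fieldsPerReplicate = as.integer(fieldsPerReplicate),
              tilesPerCondition = as.integer(tilesPerCondition),
              masterSeed = as.integer(masterSeed), shape = as.integer(shape),
              nCellsTarget = as.integer(nCellsTarget),
              nc = nc, mmc = mmc, microscopyCfg = microscopyCfg,
              flowCfg = flowCfg, gateCfg = gateCfg, outputDir = outputDir)
  class(cfg) <- "ExperimentConfig"
  cfg
}

#' Read an experiment configuration from YAML
#'
#' Recognised keys mirror the [experimentConfig()] arguments (snake_case
#' accepted); pipeline blocks `microscopy`, `flow` and `gates` override the
#' respective config defaults by name.
#'
#' @param path YAML file.
#' @return an `ExperimentConfig`.
#' @export
readExperimentConfig <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(...) {
    for (k in c(...)) if (!is.null(y[[k]])) return(y[[k]])
    NULL
  }
  args <- list()
  if (!is.null(v <- pick("conditions"))) args$conditions <- unlist(v)
  if (!is.null(v <- pick("replicates"))) args$replicates <- v
  if (!is.null(v <- pick("fieldsPerReplicate", "fields_per_replicate")))
    args$fieldsPerReplicate <- v
  if (!is.null(v <- pick("tilesPerCondition", "tiles_per_condition")))
    args$tilesPerCondition <- v
  if (!is.null(v <- pick("masterSeed", "master_seed"))) args$masterSeed <- v
  if (!is.null(v <- pick("shape"))) args$shape <- unlist(v)
  if (!is.null(v <- pick("nc"))) args$nc <- v
  if (!is.null(v <- pick("mmc"))) args$mmc <- v
  if (!is.null(v <- pick("outputDir", "output_dir"))) args$outputDir <- v
  if (!is.null(v <- pick("microscopy")))
    args$microscopyCfg <- do.call(microscopyConfig, v)
  if (!is.null(v <- pick("flow"))) args$flowCfg <- do.call(flowConfig, v)
  if (!is.null(v <- pick("gates"))) args$gateCfg <- do.call(gateConfig, v)
  do.call(experimentConfig, args)
}

#' Run an end-to-end experiment
#'
#' For every condition and replicate, generates widefield fields, scores
#' them with the microscopy pipeline, optionally generates and gates
#' single-cell tiles (flow route), then assembles the per-condition summary:
#' percent cytotoxicity by both methods, percent binucleated, micronucleus
#' frequency by both routes, fold change versus the negative control,
#' percent reduction versus the positive control, and ANOVA/Tukey
#' comparisons of the per-replicate microscopy MN frequencies. A
#' ground-truth-versus-measured recovery table flags conditions whose
#' measured MN frequency lies within 3 binomial standard errors of the
#' generative truth. Deterministic given the master seed.
#'
#' @param cfg an [experimentConfig()].
#' @return list with `summary`, `replicates`, `recovery`, `comparison`
#'   (NULL with < 2 replicates or < 2 conditions), and `manifest`. If
#'   `outputDir` is set, CSVs and a JSON manifest are written there.
#' @export
runExperiment <- function(cfg) {
  stopIfNot(inherits(cfg, "ExperimentConfig"), "cfg must be an ExperimentConfig")
  pt <- presetTable(cfg$nCellsTarget)
  ncCounts <- NULL
  repRows <- list()
  flowRows <- list()
  for (cond in cfg$conditions) {
    preset <- pt[[cond]]
    for (rep in seq_len(cfg$replicates)) {
      fields <- lapply(seq_len(cfg$fieldsPerReplicate), function(k)
        generateField(preset, cfg$shape,
                      seed = childSeed(cfg$masterSeed, cond, rep, k)))
      scored <- tryCatch(
        runMicroscopyPipeline(fields, cfg$microscopyCfg),
        error = function(e)
          stop("condition ", cond, " replicate ", rep, ": ",
               conditionMessage(e), call. = FALSE))
      s <- scored$scores
      truth <- do.call(rbind,
                       lapply(fields, function(f) as.data.frame(f$truth$totals)))
      repRows[[length(repRows) + 1L]] <- data.frame(
        condition = cond, replicate = rep,
        N1 = sum(s$N1), N2 = sum(s$N2), N3 = sum(s$N3),
        n_rejected = sum(s$n_rejected),
        n_bi_with_mn = sum(s$n_bi_with_mn),
        n_cells = sum(s$N1) + sum(s$N2) + sum(s$N3),
        truth_N2 = sum(truth$N2),
        truth_bi_with_mn = sum(truth$n_bi_with_mn),
        truth_cells = sum(truth$n_cells))
    }
    if (cfg$tilesPerCondition > 0) {
      ts <- generateTileSet(preset, cfg$tilesPerCondition,
                            seed = childSeed(cfg$masterSeed, cond, "tiles"))
      feats <- scoreTiles(ts, cfg$flowCfg)
      pop <- applyGates(feats, cfg$gateCfg)
      flowRows[[length(flowRows) + 1L]] <- data.frame(
        condition = cond, bnc = sum(pop$mn_hist),
        flow_freq_pct = pop$mn_freq_pct)
    }
  }
  reps <- do.call(rbind, repRows)
  flow <- if (length(flowRows)) do.call(rbind, flowRows) else NULL

  summaryRows <- lapply(split(reps, reps$condition)[unique(reps$condition)],
                        function(d) {
    data.frame(condition = d$condition[1],
               n_cells = sum(d$n_cells),
               pct_bn = 100 * sum(d$N2) / sum(d$n_cells),
               freq_pct = mnFrequency(d)$freq_pct)
  })
  summary <- do.call(rbind, summaryRows)
  rownames(summary) <- NULL
  if (cfg$nc %in% summary$condition) {
    ncRep <- reps[reps$condition == cfg$nc, ]
    ncC <- c(sum(ncRep$N1), sum(ncRep$N2), sum(ncRep$N3))
    summary$pct_cytotox_cn <- vapply(summary$condition, function(cond) {
      d <- reps[reps$condition == cond, ]
      cytotoxicityCN(sum(ncRep$n_cells), sum(d$n_cells))
    }, 0)
    summary$pct_cytotox_cbpi <- vapply(summary$condition, function(cond) {
      d <- reps[reps$condition == cond, ]
      cytotoxicityCBPI(c(sum(d$N1), sum(d$N2), sum(d$N3)), ncC)
    }, 0)
  }
  if (!is.null(flow))
    summary <- merge(summary, flow, by = "condition", all.x = TRUE,
                     sort = FALSE)
  if (cfg$nc %in% summary$condition) {
    fNC <- summary$freq_pct[summary$condition == cfg$nc][1]
    fMMC <- if (cfg$mmc %in% summary$condition)
      summary$freq_pct[summary$condition == cfg$mmc][1] else NA_real_
    # the control is its own reference (fold 1) even at zero frequency
    summary$fold_vs_NC <- if (fNC > 0) summary$freq_pct / fNC else
      ifelse(summary$condition == cfg$nc, 1, NA_real_)
    if (!is.na(fMMC) && fMMC > 0)
      summary$pct_reduction_vs_MMC <-
        100 * (fMMC - summary$freq_pct) / fMMC
  }

  # recovery: measured vs generative truth, within 3 binomial SE
  recovery <- do.call(rbind, lapply(split(reps, reps$condition)
                                    [unique(reps$condition)], function(d) {
    pTruth <- sum(d$truth_bi_with_mn) / max(sum(d$truth_N2), 1)
    pMeas <- sum(d$n_bi_with_mn) / max(sum(d$N2), 1)
    se <- sqrt(max(pTruth * (1 - pTruth), 1e-12) / max(sum(d$N2), 1))
    data.frame(condition = d$condition[1],
               truth_freq_pct = 100 * pTruth, measured_freq_pct = 100 * pMeas,
               se_pct = 100 * se,
               within_3se = abs(pMeas - pTruth) <= 3 * se + 1e-12)
  }))
  rownames(recovery) <- NULL

  comparison <- NULL
  if (cfg$replicates >= 2 && length(unique(reps$condition)) >= 2 &&
      cfg$nc %in% reps$condition) {
    perRep <- data.frame(condition = reps$condition,
                         value = 100 * reps$n_bi_with_mn / pmax(reps$N2, 1))
    comparison <- compareGroups(perRep, control = cfg$nc)
  }

  manifest <- list(master_seed = cfg$masterSeed, conditions = cfg$conditions,
                   replicates = cfg$replicates,
                   fields_per_replicate = cfg$fieldsPerReplicate,
                   tiles_per_condition = cfg$tilesPerCondition,
                   shape = cfg$shape)
  out <- list(summary = summary, replicates = reps, recovery = recovery,
              comparison = comparison, manifest = manifest)
  if (!is.null(cfg$outputDir)) {
    dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(cfg$outputDir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(reps, file.path(cfg$outputDir, "replicates.csv"),
                     row.names = FALSE)
    utils::write.csv(recovery, file.path(cfg$outputDir, "recovery.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(cfg$outputDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
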