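## Orchestrated end-to-end run over synthetic data:
## simulate -> normalize -> differential expression -> gene-set enrichment
## -> PCR quantification -> dosimetry report, with a run log recording every
## seed, parameter and filtering decision. Given the same configuration the
## output tables are byte-identical.

#' Pipeline configuration
#'
#' Validated parameter list for [runPipeline]. Every stochastic stage has an
#' explicit seed derived deterministically from the single `seed`.
#'
#' @param seed Master integer seed.
#' @param sim A [SimConfig] for the synthetic experiment (its own seed is
#'   overridden by `seed`).
#' @param span LOWESS span for normalization.
#' @param nPerm Permutations for the Fs test.
#' @param nResample Resamples per gene set and method.
#' @param nRand Randomizations for the REST test.
#' @param alpha Adjusted-p significance threshold.
#' @param stages Named logical vector switching stages on/off:
#'   `normalize`, `de`, `gsea`, `pcr`, `dose`.
#' @param dose Named list of dosimetry parameters (`days`, `hoursPerDay`,
#'   `concentration`, `inhaledVolumePerHour`, `fractions`, `lungMassMg`,
#'   `ssaM2PerG`, optional `measuredMgKg`, `predictedMgKg`).
#' @return A validated configuration list of class `"toxarrayConfig"`.
#' @examples
#' cfg <- pipelineConfig(seed = 7, nPerm = 100, nResample = 100)
#' @export
pipelineConfig <- function(seed = 1L,
                           sim = simConfig(),
                           span = 0.4, nPerm = 500L, nResample = 500L,
                           nRand = 1000L, alpha = 0.05,
                           stages = c(normalize = TRUE, de = TRUE,
                                      gsea = TRUE, pcr = TRUE, dose = TRUE),
                           dose = list(days = 11, hoursPerDay = 1,
                                       concentration = 42.4,
                                       inhaledVolumePerHour = 0.0018,
                                       fractions = c(
                                         pulmonary = 72.5 / 840,
                                         tracheobronchial = 48 / 840,
                                         gastrointestinal = 356 / 840,
                                         head = 267 / 840),
                                       lungMassMg = 274,
                                       ssaM2PerG = 107.7,
                                       measuredMgKg = NULL,
                                       predictedMgKg = NULL)) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  need <- c("normalize", "de", "gsea", "pcr", "dose")
  st <- stats::setNames(rep(TRUE, length(need)), need)
  st[names(stages)] <- stages
  sim@seed <- as.integer(seed)
  methods::validObject(sim)
  cfg <- list(seed = as.integer(seed), sim = sim, span = span,
              nPerm = as.integer(nPerm), nResample = as.integer(nResample),
              nRand = as.integer(nRand), alpha = alpha, stages = st,
              dose = dose)
  class(cfg) <- "toxarrayConfig"
  cfg
}

.writeTsv <- function(d, path) {
  d <- as.data.frame(d)
  for (j in seq_along(d))
    if (is.numeric(d[[j]]))
      d[[j]] <- formatC(d[[j]], digits = 15, format = "g")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  path
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate, normalize (LOWESS), differential expression
#' (Fs + permutation + FDR + LS-mean fold changes), gene-set enrichment
#' (both tests), PCR quantification (comparative Ct + REST) and the
#' dosimetry report, writing one TSV per stage plus `run_log.txt` into a
#' fresh output directory. Input files are never mutated; all tables are
#' deterministic functions of the configuration.
#'
#' @param config A configuration from [pipelineConfig].
#' @param outDir Output directory; created, must not already contain a run.
#' @return Invisibly, a list with the per-stage objects, file paths and the
#'   run log.
#' @examples
#' cfg <- pipelineConfig(seed = 1, sim = simConfig(nGenes = 200),
#'                       nPerm = 100, nResample = 100, nRand = 1000)
#' res <- runPipeline(cfg, file.path(tempdir(), "demo_run"))
#' res$paths
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "toxarrayConfig"))
  if (dir.exists(outDir) && length(list.files(outDir)))
    stop("output directory exists and is not empty: ", outDir)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  log <- character(0)
  note <- function(...) {
    entry <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ",
                    paste0(...))
    log <<- c(log, entry)
    invisible(entry)
  }
  paths <- list(); out <- list()
  note("run started; master seed = ", config$seed)

  sim <- simulateTwoColor(config$sim)
  out$sim <- sim
  note("simulated two-color experiment: ", nrow(sim$experiment), " probes x ",
       ncol(sim$experiment), " arrays; ",
       length(trueEffects(sim$truth)), " true DE genes")

  y <- sim$experiment
  if (config$stages[["normalize"]]) {
    y <- lowessNormalize(sim$experiment, span = config$span)
    dropped <- S4Vectors::metadata(y)$droppedNonPositive
    note("lowess normalization (span = ", config$span, "): rows_in = ",
         nrow(sim$experiment), ", rows_out = ", nrow(y),
         ", values dropped (non-positive channel) = ", sum(dropped))
    paths$normalized <- .writeTsv(
      data.frame(probe = rownames(y),
                 SummarizedExperiment::assay(y, "M"), check.names = FALSE),
      file.path(outDir, "normalized_M.tsv"))
  } else note("stage 'normalize' skipped")

  de <- NULL
  if (config$stages[["de"]]) {
    de <- runDE(y, statistic = "fs", nPerm = config$nPerm,
                seed = config$seed + 101L, alpha = config$alpha)
    tab <- as.data.frame(deTable(de))
    note("differential expression (Fs, ", config$nPerm,
         " permutations, seed = ", config$seed + 101L, "): ",
         length(significantGenes(de)), " genes at adjusted p < ",
         config$alpha)
    paths$de <- .writeTsv(tab, file.path(outDir, "de_results.tsv"))
    out$de <- de
  } else note("stage 'de' skipped")

  if (config$stages[["gsea"]]) {
    enr <- runEnrichment(y, config$sim@geneSets, de,
                         method = "both", nResample = config$nResample,
                         seed = config$seed + 202L, alpha = config$alpha)
    note("gene-set enrichment (both methods, ", config$nResample,
         " resamples, seed = ", config$seed + 202L, "): ",
         nrow(enr), " sets tested")
    paths$enrichment <- .writeTsv(as.data.frame(enr),
                                  file.path(outDir, "enrichment.tsv"))
    out$enrichment <- enr
  } else note("stage 'gsea' skipped")

  if (config$stages[["pcr"]]) {
    ct <- simulateCtTable(config$sim)
    rep <- pcrReport(ct$ct, nRand = config$nRand,
                     seed = config$seed + 303L)
    note("pcr quantification (REST, ", config$nRand,
         " randomizations, seed = ", config$seed + 303L, "): ",
         nrow(rep), " genes")
    paths$pcr <- .writeTsv(rep, file.path(outDir, "pcr_results.tsv"))
    out$pcr <- rep
  } else note("stage 'pcr' skipped")

  if (config$stages[["dose"]]) {
    d <- config$dose
    rep <- doseReport(d$days, d$hoursPerDay, d$concentration,
                      d$inhaledVolumePerHour, d$fractions, d$lungMassMg,
                      d$ssaM2PerG, d$measuredMgKg, d$predictedMgKg)
    note("dosimetry report: ", nrow(rep), " quantities")
    paths$dose <- .writeTsv(rep, file.path(outDir, "dosimetry.tsv"))
    out$dose <- rep
  } else note("stage 'dose' skipped")

  note("run finished")
  writeLines(log, file.path(outDir, "run_log.txt"))
  paths$log <- file.path(outDir, "run_log.txt")
  invisible(c(out, list(paths = paths, log = log)))
}
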