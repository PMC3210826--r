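#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData assayNames
NULL

# ---------------------------------------------------------------------------
# ArrayExperiment
# ---------------------------------------------------------------------------

#' Container for expression-array intensities
#'
#' `ArrayExperiment` extends [SummarizedExperiment::SummarizedExperiment] and
#' holds probe-by-sample intensities. Two-color reference-design data carry
#' paired `"red"` (experimental, Cy5) and `"green"` (common reference, Cy3)
#' assays on the raw intensity scale; single-channel data carry one assay.
#' Probe annotations live in `rowData()`: a logical `negativeControl` column
#' flags background-only control probes and a character `target` column maps
#' technical-replicate probes to their target. Per-sample metadata (treatment
#' `group`, `array`, `dye`) live in `colData()`.
#'
#' @slot .Data See [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("ArrayExperiment", contains = "SummarizedExperiment")

.validArrayExperiment <- function(object) {
  msg <- NULL
  for (nm in SummarizedExperiment::assayNames(object)) {
    a <- SummarizedExperiment::assay(object, nm)
    if (!is.numeric(a)) msg <- c(msg, sprintf("assay '%s' is not numeric", nm))
  }
  rd <- SummarizedExperiment::rowData(object)
  if ("negativeControl" %in% colnames(rd) && !is.logical(rd$negativeControl))
    msg <- c(msg, "rowData column 'negativeControl' must be logical")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "probe identifiers (rownames) must be unique")
  if (is.null(msg)) TRUE else msg
}
setValidity("ArrayExperiment", .validArrayExperiment)

#' Construct an ArrayExperiment
#'
#' @param assays Named list of probe-by-sample numeric matrices (e.g.
#'   `list(red = ..., green = ...)` for two-color data).
#' @param rowData,colData Optional [S4Vectors::DataFrame]s of probe and sample
#'   annotations.
#' @param metadata Optional list of experiment-level metadata.
#' @return An `ArrayExperiment`.
#' @examples
#' m <- matrix(rexp(20, 1 / 500), 5, 4,
#'             dimnames = list(paste0("p", 1:5), paste0("s", 1:4)))
#' ae <- ArrayExperiment(list(exprs = m),
#'                       colData = S4Vectors::DataFrame(
#'                         group = rep(c("control", "treated"), each = 2)))
#' ae
#' @export
ArrayExperiment <- function(assays, rowData = NULL, colData = NULL,
                            metadata = list()) {
  args <- list(assays = assays, metadata = metadata)
  if (!is.null(rowData)) args$rowData <- rowData
  if (!is.null(colData)) args$colData <- colData
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  methods::new("ArrayExperiment", se)
}

#' Probe annotation accessors
#'
#' `negativeControls()` returns the logical negative-control flag (all
#' `FALSE` when unannotated); `probeTargets()` the probe-to-target map
#' (`NA` where unannotated).
#'
#' @param x An `ArrayExperiment`.
#' @return A vector of length `nrow(x)`.
#' @export
negativeControls <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if ("negativeControl" %in% colnames(rd)) rd$negativeControl
  else rep(FALSE, nrow(x))
}

#' @rdname negativeControls
#' @export
probeTargets <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if ("target" %in% colnames(rd)) as.character(rd$target)
  else rep(NA_character_, nrow(x))
}

setMethod("show", "ArrayExperiment", function(object) {
  methods::callNextMethod()
  nc <- sum(negativeControls(object))
  if (nc > 0) cat("negative-control probes:", nc, "\n")
})

# ---------------------------------------------------------------------------
# GeneSetList
# ---------------------------------------------------------------------------

#' Named collection of gene sets
#'
#' A lightweight GMT-backed container: a named list of character vectors of
#' member gene identifiers plus an optional description per set. Identifiers
#' are opaque, case-sensitive strings; matching against expression matrices
#' is exact.
#'
#' @slot sets Named list of character vectors.
#' @slot description Character vector parallel to `sets`.
#' @export
setClass("GeneSetList",
         representation(sets = "list", description = "character"))

.validGeneSetList <- function(object) {
  msg <- NULL
  if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
    msg <- c(msg, "set names must be present and unique")
  if (!all(vapply(object@sets, is.character, logical(1))))
    msg <- c(msg, "all sets must be character vectors of gene identifiers")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "empty gene sets are not allowed")
  if (length(object@description) != length(object@sets))
    msg <- c(msg, "description must be parallel to sets")
  if (is.null(msg)) TRUE else msg
}
setValidity("GeneSetList", .validGeneSetList)

#' @param sets Named list of character vectors of gene identifiers.
#' @param description Optional character vector of set descriptions.
#' @return A `GeneSetList`.
#' @rdname GeneSetList-class
#' @examples
#' gs <- GeneSetList(list(pathwayA = c("g1", "g2"), pathwayB = c("g3")))
#' names(gs); lengths(geneSets(gs))
#' @export
GeneSetList <- function(sets, description = NULL) {
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(description)) description <- rep("", length(sets))
  methods::new("GeneSetList", sets = sets, description = description)
}

#' @param x A `GeneSetList`.
#' @rdname GeneSetList-class
#' @export
geneSets <- function(x) x@sets

#' @rdname GeneSetList-class
#' @export
setDescriptions <- function(x) stats::setNames(x@description, names(x@sets))

setMethod("length", "GeneSetList", function(x) length(x@sets))
setMethod("names", "GeneSetList", function(x) names(x@sets))
setMethod("[[", "GeneSetList", function(x, i) x@sets[[i]])
setMethod("show", "GeneSetList", function(object) {
  cat("GeneSetList with", length(object@sets), "sets;",
      "member counts:", paste(utils::head(lengths(object@sets), 5),
                              collapse = ", "),
      if (length(object@sets) > 5) "..." else "", "\n")
})

# ---------------------------------------------------------------------------
# GeneFits
# ---------------------------------------------------------------------------

#' Per-gene two-group linear model fits
#'
#' Holds, for every gene, the least-square group means, the treatment mean
#' square, the residual mean square with its degrees of freedom, and both the
#' full-model and null-model residual matrices needed for residual-shuffling
#' resampling.
#'
#' @slot lsMeans Genes-by-2 matrix of group least-square means.
#' @slot msTreat Numeric vector, treatment mean square (1 df, two groups).
#' @slot residMS Numeric vector, residual mean square.
#' @slot df Numeric vector, residual degrees of freedom per gene.
#' @slot residuals Genes-by-samples matrix of full-model residuals.
#' @slot nullResiduals Genes-by-samples matrix of residuals from the
#'   no-treatment (grand mean) fit, the unit shuffled during permutation.
#' @slot group Factor of sample group labels (2 levels).
#' @export
setClass("GeneFits",
         representation(lsMeans = "matrix", msTreat = "numeric",
                        residMS = "numeric", df = "numeric",
                        residuals = "matrix", nullResiduals = "matrix",
                        group = "factor"))

setMethod("show", "GeneFits", function(object) {
  cat("GeneFits:", length(object@msTreat), "genes,",
      length(object@group), "samples in groups",
      paste(levels(object@group), collapse = " vs "), "\n")
})

# ---------------------------------------------------------------------------
# DEResult
# ---------------------------------------------------------------------------

#' Differential-expression results
#'
#' One row per gene: test statistic (Fs or F1), raw p-value, FDR-adjusted
#' p-value (Benjamini-Hochberg) and the signed linear fold change computed
#' from least-square means (negative values denote downregulation; `|FC| >=
#' 1` always).
#'
#' @slot results A [S4Vectors::DataFrame] with columns `gene`, `statistic`,
#'   `pvalue`, `fdr`, `foldChange`, `log2FoldChange`.
#' @slot method Character, `"fs-permutation"` or `"f1-parametric"`.
#' @slot alpha Significance threshold used by [significantGenes()].
#' @export
setClass("DEResult",
         representation(results = "DataFrame", method = "character",
                        alpha = "numeric"))

.validDEResult <- function(object) {
  msg <- NULL
  need <- c("gene", "statistic", "pvalue", "fdr", "foldChange")
  if (!all(need %in% colnames(object@results)))
    msg <- c(msg, paste("results must contain columns:",
                        paste(need, collapse = ", ")))
  else {
    p <- object@results$pvalue; q <- object@results$fdr
    ok <- !is.na(p) & !is.na(q)
    if (any(q[ok] + 1e-12 < p[ok])) msg <- c(msg, "adjusted p must be >= raw p")
    if (any(q[ok] < 0 | q[ok] > 1)) msg <- c(msg, "adjusted p must be in [0,1]")
    fc <- object@results$foldChange
    if (any(abs(fc[!is.na(fc)]) < 1 - 1e-12))
      msg <- c(msg, "|fold change| must be >= 1 under the signed convention")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("DEResult", .validDEResult)

#' @param object A `DEResult`.
#' @return `deTable()` returns the per-gene results `DataFrame`;
#'   `significantGenes()` the identifiers with adjusted p below `alpha`.
#' @rdname DEResult-class
#' @export
deTable <- function(object) object@results

#' @param alpha Significance threshold on the adjusted p-value.
#' @rdname DEResult-class
#' @export
significantGenes <- function(object, alpha = object@alpha) {
  r <- object@results
  as.character(r$gene[!is.na(r$fdr) & r$fdr < alpha])
}

setMethod("show", "DEResult", function(object) {
  r <- object@results
  cat("DEResult (", object@method, "): ", nrow(r), " genes, ",
      sum(!is.na(r$fdr) & r$fdr < object@alpha),
      " significant at adjusted p < ", object@alpha, "\n", sep = "")
})

# ---------------------------------------------------------------------------
# CtTable
# ---------------------------------------------------------------------------

#' qPCR threshold-cycle table
#'
#' Long-format Ct measurements: one row per well with sample id, treatment
#' group, gene, Ct value (cycles) and technical-replicate index. Technical
#' replicates of a well are averaged before any analysis. One or more
#' housekeeping genes must be measured in every sample; amplification
#' efficiency defaults to 2.0 per cycle (perfect doubling) and may be
#' overridden per gene via a named vector.
#'
#' @slot data data.frame with columns `sample`, `group`, `gene`, `ct`,
#'   `replicate`.
#' @slot housekeeping Character vector of housekeeping gene names.
#' @slot efficiency Numeric: a single efficiency or a named per-gene vector.
#' @export
setClass("CtTable",
         representation(data = "data.frame", housekeeping = "character",
                        efficiency = "numeric"))

.validCtTable <- function(object) {
  msg <- NULL
  need <- c("sample", "group", "gene", "ct", "replicate")
  if (!all(need %in% colnames(object@data)))
    msg <- c(msg, paste("data must contain columns:",
                        paste(need, collapse = ", ")))
  else {
    if (any(object@data$ct <= 0)) msg <- c(msg, "all Ct values must be > 0")
    if (length(object@housekeeping) < 1L)
      msg <- c(msg, "at least one housekeeping gene is required")
    absent <- setdiff(object@housekeeping, object@data$gene)
    if (length(absent))
      msg <- c(msg, paste("housekeeping gene(s) not measured:",
                          paste(absent, collapse = ", ")))
    # samples missing individual housekeeping wells are dropped (with a
    # warning) at analysis time, not rejected here
  }
  if (any(object@efficiency <= 0))
    msg <- c(msg, "amplification efficiencies must be > 0")
  if (is.null(msg)) TRUE else msg
}
setValidity("CtTable", .validCtTable)

#' @param data data.frame of wells (see slots).
#' @param housekeeping Character vector of housekeeping gene names.
#' @param efficiency Amplification efficiency per cycle (scalar or named
#'   per-gene vector), default 2.
#' @return A `CtTable`.
#' @rdname CtTable-class
#' @export
CtTable <- function(data, housekeeping, efficiency = 2) {
  if (!"replicate" %in% colnames(data)) data$replicate <- 1L
  methods::new("CtTable", data = as.data.frame(data),
               housekeeping = as.character(housekeeping),
               efficiency = efficiency)
}

setMethod("show", "CtTable", function(object) {
  d <- object@data
  cat("CtTable:", length(unique(d$gene)), "genes x",
      length(unique(d$sample)), "samples;",
      "housekeeping:", paste(object@housekeeping, collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# SimConfig & SyntheticTruth
# ---------------------------------------------------------------------------

#' Configuration of the synthetic-data generator
#'
#' Defines the simulated study: a two-group reference-design experiment with
#' `nPerGroup` samples per group and `nGenes` genes, gene sets with optional
#' equicorrelated within-set noise, treatment shifts on chosen sets, an
#' intensity-dependent dye-bias curve for the two-color channel model, a
#' right-skewed (scaled inverse-chi-square) gene-wise variance distribution,
#' negative-control probes and technical replicates for the single-channel
#' model, and a Ct-table model for qPCR. All randomness flows from the single
#' integer `seed`.
#'
#' @slot nGenes,nPerGroup,nGroups Counts (two groups supported).
#' @slot geneSets A [GeneSetList] over the generated gene identifiers.
#' @slot perturbedSets Named numeric: log2 treatment shift delta per set.
#' @slot fracDeGenes Fraction of genes outside perturbed sets that receive an
#'   independent treatment effect of size `deEffect` (random sign).
#' @slot deEffect Log2 effect size for independent DE genes.
#' @slot dyeBias Coefficients `c(b0, b1, b2)` of the additive log-ratio bias
#'   `b0 + b1 z + b2 z^2`, `z = A - baselineMean`.
#' @slot varDf,varScale Parameters of the scaled inverse-chi-square gene
#'   variance law `sigma^2_g = varDf * varScale / chisq(varDf)`.
#' @slot rhoWithinSet Equicorrelation of noise among genes of a set, `[0,1)`.
#' @slot baselineMean,baselineSD Mean log2 intensity distribution (A scale).
#' @slot aNoiseSD SD of per-array jitter of A around the gene baseline.
#' @slot nNegativeControls,nReplicates Single-channel layout: number of
#'   background-only control probes and technical replicates per target.
#' @slot backgroundMean,backgroundSD Log2 background distribution for
#'   negative controls (and probe-level noise of signal probes).
#' @slot signalMargin Log2 margin of signal probes above background.
#' @slot targetSpread SD of per-target expression around the signal level.
#' @slot ctGenes Named numeric: true linear fold changes of qPCR targets.
#' @slot ctHousekeeping Names of simulated housekeeping genes (no effect).
#' @slot ctBaseline,ctNoiseSD,nCtReplicates Ct model: mean baseline cycle,
#'   well noise SD (cycles) and technical replicates per well.
#' @slot seed Integer seed; the single source of randomness.
#' @export
setClass("SimConfig",
         representation(nGenes = "integer", nPerGroup = "integer",
                        nGroups = "integer", geneSets = "GeneSetList",
                        perturbedSets = "numeric", fracDeGenes = "numeric",
                        deEffect = "numeric", dyeBias = "numeric",
                        varDf = "numeric", varScale = "numeric",
                        rhoWithinSet = "numeric",
                        baselineMean = "numeric", baselineSD = "numeric",
                        aNoiseSD = "numeric",
                        nNegativeControls = "integer", nReplicates = "integer",
                        backgroundMean = "numeric", backgroundSD = "numeric",
                        signalMargin = "numeric", targetSpread = "numeric",
                        ctGenes = "numeric", ctHousekeeping = "character",
                        ctBaseline = "numeric", ctNoiseSD = "numeric",
                        nCtReplicates = "integer", seed = "integer"))

.validSimConfig <- function(object) {
  msg <- NULL
  if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
  if (object@nPerGroup < 2L) msg <- c(msg, "nPerGroup must be >= 2")
  if (object@nGroups != 2L) msg <- c(msg, "only two treatment groups supported")
  if (!all(is.finite(object@perturbedSets)))
    msg <- c(msg, "perturbed-set effects (delta) must be finite")
  if (object@fracDeGenes < 0 || object@fracDeGenes > 1)
    msg <- c(msg, "fracDeGenes must be in [0,1]")
  if (object@rhoWithinSet < 0 || object@rhoWithinSet >= 1)
    msg <- c(msg, "rhoWithinSet must be in [0,1)")
  bad <- setdiff(names(object@perturbedSets), names(object@geneSets))
  if (length(bad))
    msg <- c(msg, paste("perturbed sets not in geneSets:",
                        paste(bad, collapse = ", ")))
  if (object@varDf <= 0 || object@varScale < 0)
    msg <- c(msg, "variance model needs varDf > 0 and varScale >= 0")
  if (is.null(msg)) TRUE else msg
}
setValidity("SimConfig", .validSimConfig)

#' Default gene-set layout for simulations
#'
#' Carves the first `nSets * setSize` gene identifiers into disjoint sets
#' `pathway01`, `pathway02`, ...
#'
#' @param nGenes Total number of genes.
#' @param setSize Genes per set (default 50, shrunk for small experiments).
#' @param nSets Number of sets (default 10 when they fit).
#' @return A [GeneSetList].
#' @export
makeGeneSets <- function(nGenes = 1000L,
                         setSize = min(50L, max(2L, nGenes %/% 10L)),
                         nSets = min(10L, nGenes %/% setSize)) {
  stopifnot(nSets >= 1L, nSets * setSize <= nGenes)
  ids <- sprintf("gene%04d", seq_len(nGenes))
  sets <- split(ids[seq_len(nSets * setSize)],
                rep(seq_len(nSets), each = setSize))
  names(sets) <- sprintf("pathway%02d", seq_len(nSets))
  GeneSetList(sets)
}

#' @param nGenes,nPerGroup,nGroups,geneSets,perturbedSets,fracDeGenes,deEffect
#'   See slots.
#' @param dyeBias,varDf,varScale,rhoWithinSet,baselineMean,baselineSD,aNoiseSD
#'   See slots.
#' @param nNegativeControls,nReplicates,backgroundMean,backgroundSD See slots.
#' @param signalMargin,targetSpread,ctGenes,ctHousekeeping,ctBaseline See slots.
#' @param ctNoiseSD,nCtReplicates,seed See slots.
#' @return A validated `SimConfig`.
#' @details Defaults emulate the study design the package targets: 1000
#'   genes, 8 animals per group, ten disjoint 50-gene pathways with
#'   within-pathway equicorrelation 0.3, one pathway shifted by 2 log2 units
#'   in the treated group, a mildly curved intensity-dependent dye bias, and
#'   gene variances from a scaled inverse-chi-square law centred near
#'   (0.2)^2 on the log2 scale.
#' @rdname SimConfig-class
#' @examples
#' cfg <- simConfig(seed = 7)
#' sim <- simulateTwoColor(cfg)
#' sim$experiment
#' @export
simConfig <- function(nGenes = 1000L, nPerGroup = 8L, nGroups = 2L,
                      geneSets = makeGeneSets(nGenes),
                      perturbedSets = c(pathway01 = 2),
                      fracDeGenes = 0, deEffect = 1,
                      dyeBias = c(0.3, 0.1, -0.05),
                      varDf = 4, varScale = 0.04, rhoWithinSet = 0.3,
                      baselineMean = 10, baselineSD = 1.5, aNoiseSD = 0.2,
                      nNegativeControls = 50L, nReplicates = 3L,
                      backgroundMean = 6, backgroundSD = 0.5,
                      signalMargin = 4, targetSpread = 1,
                      ctGenes = c(Cxcl5 = 30, Cxcl1 = 7, Ccl2 = 4.2,
                                  Tnf = 1.8, Il6 = 1),
                      ctHousekeeping = c("Hprt", "Actb"),
                      ctBaseline = 22, ctNoiseSD = 0.25,
                      nCtReplicates = 2L, seed = 1L) {
  methods::new("SimConfig",
               nGenes = as.integer(nGenes), nPerGroup = as.integer(nPerGroup),
               nGroups = as.integer(nGroups), geneSets = geneSets,
               perturbedSets = perturbedSets, fracDeGenes = fracDeGenes,
               deEffect = deEffect, dyeBias = as.numeric(dyeBias),
               varDf = varDf, varScale = varScale,
               rhoWithinSet = rhoWithinSet, baselineMean = baselineMean,
               baselineSD = baselineSD, aNoiseSD = aNoiseSD,
               nNegativeControls = as.integer(nNegativeControls),
               nReplicates = as.integer(nReplicates),
               backgroundMean = backgroundMean, backgroundSD = backgroundSD,
               signalMargin = signalMargin, targetSpread = targetSpread,
               ctGenes = ctGenes, ctHousekeeping = ctHousekeeping,
               ctBaseline = ctBaseline, ctNoiseSD = ctNoiseSD,
               nCtReplicates = as.integer(nCtReplicates),
               seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes,", object@nPerGroup, "per group,",
      length(object@geneSets), "gene sets,",
      length(object@perturbedSets), "perturbed; seed", object@seed, "\n")
})

#' Ground truth of a simulated experiment
#'
#' @slot deGenes Named numeric: true log2 treatment effect per affected gene
#'   (includes members of perturbed sets).
#' @slot perturbedSets Named numeric of set-level shifts (delta, log2).
#' @slot trueVariance Named numeric of gene-wise noise variances.
#' @export
setClass("SyntheticTruth",
         representation(deGenes = "numeric", perturbedSets = "numeric",
                        trueVariance = "numeric"))

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@deGenes), "true DE genes;",
      length(object@perturbedSets), "perturbed sets\n")
})

#' @param object A `SyntheticTruth`.
#' @return Named numeric vector of true log2 effects.
#' @rdname SyntheticTruth-class
#' @export
trueEffects <- function(object) object@deGenes
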