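## Synthetic-data generators with known ground truth. All randomness is
## scoped to the config seed via withr::with_seed (no global RNG pollution).

#' @importFrom withr with_seed
NULL

## Equicorrelated noise: genes of a set share a latent per-sample factor,
## e_gs = sigma_g * (sqrt(rho) z_s + sqrt(1-rho) eps_gs).
.correlatedNoise <- function(nGenes, nSamples, sigma, geneSets, rho,
                             geneIds) {
  eps <- matrix(stats::rnorm(nGenes * nSamples), nGenes, nSamples)
  if (rho > 0) {
    for (members in geneSets(geneSets)) {
      idx <- match(members, geneIds)
      idx <- idx[!is.na(idx)]
      if (!length(idx)) next
      z <- stats::rnorm(nSamples)
      eps[idx, ] <- sqrt(rho) * matrix(z, length(idx), nSamples,
                                       byrow = TRUE) +
        sqrt(1 - rho) * eps[idx, , drop = FALSE]
    }
  }
  eps * sigma
}

## True log2 treatment effects: delta on perturbed-set members plus an
## independent DE fraction (random sign) outside perturbed sets.
.trueEffectVector <- function(config, geneIds) {
  effect <- stats::setNames(numeric(length(geneIds)), geneIds)
  for (setName in names(config@perturbedSets)) {
    members <- intersect(config@geneSets[[setName]], geneIds)
    if (!length(members))
      stop("perturbed set '", setName, "' has no members among the genes")
    effect[members] <- effect[members] + config@perturbedSets[[setName]]
  }
  nDe <- floor(config@fracDeGenes * length(geneIds))
  if (nDe > 0) {
    pool <- setdiff(geneIds, names(effect)[effect != 0])
    pick <- sample(pool, min(nDe, length(pool)))
    effect[pick] <- config@deEffect * sample(c(-1, 1), length(pick),
                                             replace = TRUE)
  }
  effect
}

.dyeBiasCurve <- function(a, coef, center) {
  z <- a - center
  coef[1] + coef[2] * z + coef[3] * z^2
}

.designFrame <- function(nPerGroup) {
  S4Vectors::DataFrame(
    sample = sprintf("s%02d", seq_len(2 * nPerGroup)),
    group = factor(rep(c("control", "treated"), each = nPerGroup),
                   levels = c("control", "treated")),
    array = sprintf("array%02d", seq_len(2 * nPerGroup)),
    dye = "Cy5/Cy3")
}

#' Simulate a two-color reference-design experiment
#'
#' Generates paired red (experimental, Cy5) and green (common reference,
#' Cy3) raw intensity matrices. On the log scale, each probe's mean
#' intensity A is drawn per gene, the log-ratio M carries the true treatment
#' effect, an additive smooth dye-bias trend in A, and heteroscedastic
#' (optionally within-set equicorrelated) noise; channels are reconstructed
#' as `red = 2^(A + M/2)`, `green = 2^(A - M/2)`. Null genes have zero
#' expected treatment difference in `log2(red/green)`.
#'
#' @param config A [SimConfig].
#' @return A list with elements `experiment` (an [ArrayExperiment] with
#'   assays `red` and `green` and the design in `colData`), and `truth`
#'   (a [SyntheticTruth]).
#' @examples
#' sim <- simulateTwoColor(simConfig(nGenes = 200, seed = 1))
#' SummarizedExperiment::assayNames(sim$experiment)
#' @export
simulateTwoColor <- function(config) {
  methods::validObject(config)
  withr::with_seed(config@seed, {
    G <- config@nGenes; n <- config@nPerGroup; S <- 2L * n
    ids <- sprintf("gene%04d", seq_len(G))
    design <- .designFrame(n)
    treated <- design$group == "treated"

    effect <- .trueEffectVector(config, ids)
    sigma2 <- config@varDf * config@varScale /
      stats::rchisq(G, df = config@varDf)
    if (config@varScale == 0) sigma2 <- rep(0, G)
    baseA <- stats::rnorm(G, config@baselineMean, config@baselineSD)

    A <- baseA + matrix(stats::rnorm(G * S, sd = config@aNoiseSD), G, S)
    mu <- outer(effect, as.numeric(treated))        # shift in treated only
    noise <- .correlatedNoise(G, S, sqrt(sigma2), config@geneSets,
                              config@rhoWithinSet, ids)
    M <- mu + .dyeBiasCurve(A, config@dyeBias, config@baselineMean) + noise

    red <- 2^(A + M / 2); green <- 2^(A - M / 2)
    dimnames(red) <- dimnames(green) <- list(ids, design$sample)

    experiment <- ArrayExperiment(
      list(red = red, green = green),
      rowData = S4Vectors::DataFrame(probe = ids, row.names = ids),
      colData = design,
      metadata = list(scale = "raw intensity", design = "common reference"))
    truth <- methods::new("SyntheticTruth",
                          deGenes = effect[effect != 0],
                          perturbedSets = config@perturbedSets,
                          trueVariance = stats::setNames(sigma2, ids))
    list(experiment = experiment, truth = truth)
  })
}

#' Simulate a single-channel array with negative controls
#'
#' Emulates a one-color layout: background-only negative-control probes,
#' signal probes sitting `signalMargin` log2 units above background, and `k
#' = nReplicates` technical-replicate probes per target (to exercise median
#' collapsing). Treatment shifts follow the configured perturbed sets.
#' Intensities are returned on the raw scale.
#'
#' @param config A [SimConfig] with `nNegativeControls >= 3`.
#' @return A list with `experiment` (assay `exprs`; `rowData` columns
#'   `target` and `negativeControl`) and `truth`.
#' @examples
#' sim <- simulateSingleChannel(simConfig(nGenes = 100, seed = 2))
#' table(negativeControls(sim$experiment))
#' @export
simulateSingleChannel <- function(config) {
  methods::validObject(config)
  if (config@nNegativeControls < 3L)
    stop("at least 3 negative-control probes are required")
  withr::with_seed(config@seed, {
    G <- config@nGenes; n <- config@nPerGroup; S <- 2L * n
    k <- config@nReplicates
    ids <- sprintf("gene%04d", seq_len(G))
    design <- .designFrame(n)
    treated <- design$group == "treated"

    effect <- .trueEffectVector(config, ids)
    level <- config@backgroundMean + config@signalMargin +
      stats::rnorm(G, sd = config@targetSpread)
    targetLog <- outer(level, rep(1, S)) + outer(effect, as.numeric(treated))

    ## replicate probes: target value + probe-level background-sized noise
    probeTarget <- rep(ids, each = k)
    probeIds <- sprintf("%s_p%d", probeTarget, rep(seq_len(k), times = G))
    x <- targetLog[rep(seq_len(G), each = k), , drop = FALSE] +
      matrix(stats::rnorm(G * k * S, sd = config@backgroundSD), G * k, S)

    ncIds <- sprintf("negctl%03d", seq_len(config@nNegativeControls))
    ncX <- matrix(stats::rnorm(config@nNegativeControls * S,
                               config@backgroundMean, config@backgroundSD),
                  config@nNegativeControls, S)

    exprs <- 2^rbind(x, ncX)
    rownames(exprs) <- c(probeIds, ncIds)
    colnames(exprs) <- design$sample
    rowData <- S4Vectors::DataFrame(
      target = c(probeTarget, rep(NA_character_,
                                  config@nNegativeControls)),
      negativeControl = c(rep(FALSE, length(probeIds)),
                          rep(TRUE, config@nNegativeControls)),
      row.names = rownames(exprs))

    experiment <- ArrayExperiment(list(exprs = exprs), rowData = rowData,
                                  colData = design,
                                  metadata = list(scale = "raw intensity"))
    truth <- methods::new("SyntheticTruth",
                          deGenes = effect[effect != 0],
                          perturbedSets = config@perturbedSets,
                          trueVariance = stats::setNames(
                            rep(config@backgroundSD^2, G), ids))
    list(experiment = experiment, truth = truth)
  })
}

#' Simulate a qPCR threshold-cycle table
#'
#' Ct values follow `Ct = baseline - log2(relative expression) + noise`;
#' treated samples of a target gene with true fold change FC have their Ct
#' lowered by `log2(FC)`. Housekeeping genes have zero treatment effect. A
#' per-sample loading offset (removed by housekeeping normalization) and
#' per-well technical replicates are included.
#'
#' @param config A [SimConfig]; `ctGenes` gives true linear fold changes,
#'   `ctHousekeeping` the housekeeping genes.
#' @return A list with `ct` (a [CtTable]) and `truth` (named numeric of true
#'   fold changes).
#' @examples
#' sim <- simulateCtTable(simConfig(seed = 3))
#' sim$ct
#' @export
simulateCtTable <- function(config) {
  methods::validObject(config)
  if (length(config@ctHousekeeping) < 1L)
    stop("at least one housekeeping gene must be declared")
  withr::with_seed(config@seed + 1L, {
    n <- config@nPerGroup
    genes <- c(names(config@ctGenes), config@ctHousekeeping)
    fc <- c(config@ctGenes,
            stats::setNames(rep(1, length(config@ctHousekeeping)),
                            config@ctHousekeeping))
    samples <- sprintf("s%02d", seq_len(2 * n))
    group <- rep(c("control", "treated"), each = n)
    baseline <- stats::setNames(
      stats::rnorm(length(genes), config@ctBaseline, 2), genes)
    loading <- stats::rnorm(2 * n, 0, 0.3)   # per-sample offset

    rows <- expand.grid(replicate = seq_len(config@nCtReplicates),
                        gene = genes, sampleIdx = seq_len(2 * n),
                        stringsAsFactors = FALSE)
    shift <- ifelse(group[rows$sampleIdx] == "treated",
                    log2(fc[rows$gene]), 0)
    ct <- baseline[rows$gene] - shift + loading[rows$sampleIdx] +
      stats::rnorm(nrow(rows), 0, config@ctNoiseSD)
    d <- data.frame(sample = samples[rows$sampleIdx],
                    group = group[rows$sampleIdx],
                    gene = rows$gene, ct = as.numeric(ct),
                    replicate = rows$replicate)
    list(ct = CtTable(d, housekeeping = config@ctHousekeeping,
                      efficiency = 2),
         truth = fc)
  })
}
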