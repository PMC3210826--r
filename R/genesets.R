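## Gene-set enrichment: a rank-based permutation test and a design-based
## bootstrap test, both built on the Euclidean distance between per-group
## gene summary vectors, plus the combined enrichment report.

## Label-permutation / bootstrap weight matrices. Each column of W encodes
## mean(group A) - mean(group B) as sample weights, so distances for all
## resamples reduce to one matrix product.
.contrastWeights <- function(group) {
  gA <- group == levels(group)[1]
  w <- ifelse(gA, 1 / sum(gA), -1 / sum(!gA))
  as.numeric(w)
}

.permWeightMatrix <- function(w, nPerm) {
  vapply(seq_len(nPerm), function(b) w[sample(length(w))], numeric(length(w)))
}

.bootWeightMatrix <- function(group, nBoot) {
  S <- length(group)
  gA <- group == levels(group)[1]
  nA <- sum(gA); nB <- S - nA
  W <- matrix(0, S, nBoot)
  for (b in seq_len(nBoot)) {
    ia <- sample.int(S, nA, replace = TRUE)
    ib <- sample.int(S, nB, replace = TRUE)
    W[, b] <- tabulate(ia, S) / nA - tabulate(ib, S) / nB
  }
  W
}

.resolveSet <- function(x, set) {
  measured <- rownames(x)
  idx <- match(intersect(set, measured), measured)
  if (!length(idx))
    stop("gene set has no members among the measured genes")
  idx
}

#' Rank-based gene-set test
#'
#' Within each sample (observation), all measured gene values are converted
#' to ranks (average ranks for ties), so the test uses the magnitude of the
#' intensities while making no distributional assumption. Restricted to the
#' set members, each gene's mean rank per treatment group gives one
#' mean-rank vector per group; the test statistic D is the Euclidean
#' distance between the two group vectors. Sample-to-group labels are
#' permuted -- preserving within-sample gene-gene correlation -- and
#' `p = (1 + #\{D* >= D\}) / (nPerm + 1)`.
#'
#' @param x An [ArrayExperiment] or numeric matrix of expression values
#'   (genes in rows).
#' @param set Character vector of member gene identifiers.
#' @param group Two-level treatment factor (defaults to `colData(x)$group`).
#' @param nPerm Number of label permutations, at least 100.
#' @param seed Integer seed.
#' @param rankScope `"global"` (rank all measured genes, default) or
#'   `"within-set"` (rank only set members).
#' @param assay Assay to use.
#' @return An object of class `"htest"` with the distance statistic, the
#'   permutation p-value and the number of measured set genes.
#' @examples
#' sim <- simulateTwoColor(simConfig(nGenes = 200, dyeBias = c(0, 0, 0),
#'                                   seed = 1))
#' m <- log2(SummarizedExperiment::assay(sim$experiment, "red") /
#'           SummarizedExperiment::assay(sim$experiment, "green"))
#' rankBasedTest(m, geneSets(simConfig(nGenes = 200)@geneSets)[["pathway01"]],
#'               group = sim$experiment$group, nPerm = 200)
#' @export
rankBasedTest <- function(x, set, group = NULL, nPerm = 1000L, seed = 1L,
                          rankScope = c("global", "within-set"),
                          assay = 1L) {
  rankScope <- match.arg(rankScope)
  if (nPerm < 100L) stop("'nPerm' must be at least 100")
  m <- .assayMatrix(x, assay)
  group <- .resolveGroup(x, group)
  idx <- .resolveSet(m, set)
  if (rankScope == "within-set") m <- m[idx, , drop = FALSE]
  R <- apply(m, 2, rank, ties.method = "average")
  if (rankScope == "global") R <- R[idx, , drop = FALSE]

  w <- .contrastWeights(group)
  D <- sqrt(sum((R %*% w)^2))
  Dperm <- withr::with_seed(seed, {
    W <- .permWeightMatrix(w, nPerm)
    sqrt(colSums((R %*% W)^2))
  })
  p <- addOneP(sum(Dperm >= D), nPerm)
  structure(list(statistic = c(D = D), p.value = p,
                 parameter = c(nPerm = nPerm, nGenes = length(idx)),
                 method = "Rank-based gene-set test (label permutation)",
                 data.name = deparse(substitute(set))),
            class = "htest")
}

#' Design-based gene-set test (bootstrap)
#'
#' The test statistic D is the Euclidean distance between the two treatment
#' groups' gene-wise mean vectors, restricted to the set. The null
#' distribution honors the design: the treatment effect is removed (each
#' gene centered on its grand mean), and whole sample-columns of the
#' full-model residuals are resampled with replacement and reassigned to
#' groups at the original sizes -- preserving gene-gene correlation.
#' `p = (1 + #\{D* >= D\}) / (nBoot + 1)`.
#'
#' @param x An [ArrayExperiment] or numeric matrix (genes in rows).
#' @param set Character vector of member gene identifiers.
#' @param group Two-level treatment factor (defaults to `colData(x)$group`).
#' @param nBoot Number of bootstrap resamples, at least 100.
#' @param seed Integer seed.
#' @param perGene Resample each gene independently instead of whole sample
#'   columns (for comparison only; breaks gene-gene correlation).
#' @param assay Assay to use.
#' @return An `"htest"` object (distance statistic, bootstrap p-value).
#' @export
designBasedTest <- function(x, set, group = NULL, nBoot = 1000L, seed = 1L,
                            perGene = FALSE, assay = 1L) {
  if (nBoot < 100L) stop("'nBoot' must be at least 100")
  m <- .assayMatrix(x, assay)
  group <- .resolveGroup(x, group)
  idx <- .resolveSet(m, set)
  y <- m[idx, , drop = FALSE]

  gA <- group == levels(group)[1]
  mA <- rowMeans(y[, gA, drop = FALSE]); mB <- rowMeans(y[, !gA, drop = FALSE])
  D <- sqrt(sum((mA - mB)^2))

  ## full-model residuals: treatment effect removed; rescaled by
  ## sqrt(n_k / (n_k - 1)) so resampled columns carry the full noise
  ## variance (group-mean residuals are deflated by (n_k - 1)/n_k)
  nA <- sum(gA); nB <- sum(!gA)
  E <- y
  E[, gA] <- (y[, gA, drop = FALSE] - mA) * sqrt(nA / (nA - 1))
  E[, !gA] <- (y[, !gA, drop = FALSE] - mB) * sqrt(nB / (nB - 1))

  Dboot <- withr::with_seed(seed, {
    if (perGene) {
      vapply(seq_len(nBoot), function(b) {
        Eb <- t(apply(E, 1, sample, replace = TRUE))
        dA <- rowMeans(Eb[, gA, drop = FALSE])
        dB <- rowMeans(Eb[, !gA, drop = FALSE])
        sqrt(sum((dA - dB)^2))
      }, numeric(1))
    } else {
      W <- .bootWeightMatrix(group, nBoot)
      sqrt(colSums((E %*% W)^2))
    }
  })
  p <- addOneP(sum(Dboot >= D), nBoot)
  structure(list(statistic = c(D = D), p.value = p,
                 parameter = c(nBoot = nBoot, nGenes = length(idx)),
                 method = "Design-based gene-set test (residual bootstrap)",
                 data.name = deparse(substitute(set))),
            class = "htest")
}

#' Gene-set enrichment report
#'
#' Runs the rank-based and/or design-based test for every set of a
#' collection and assembles the enrichment table: one row per set with the
#' p-value(s) and distance statistic(s), `total` (measured probes in the
#' set) and `changing` (set probes passing the differential-expression
#' threshold `fdr < alpha`). Sets with no measured members are excluded
#' with a warning. Rows are sorted ascending by p-value (rank-test p when
#' both methods are run). Raw p-values are reported; optional
#' Benjamini-Hochberg columns via `adjust = TRUE`.
#'
#' @param x An [ArrayExperiment] or matrix of normalized values.
#' @param collection A [GeneSetList].
#' @param deResult A [DEResult] computed on the same matrix (used for the
#'   `changing` counts); may be `NULL` to skip them.
#' @param group Two-level treatment factor (defaults to `colData(x)$group`).
#' @param method `"both"`, `"rank"` or `"design"`.
#' @param nResample Resamples per set and method.
#' @param seed Integer seed (per-set seeds are derived deterministically).
#' @param alpha Adjusted-p threshold defining "changing" probes.
#' @param rankScope Passed to [rankBasedTest].
#' @param adjust Add BH-adjusted p-value columns?
#' @param assay Assay to use.
#' @return A [S4Vectors::DataFrame], sorted by p-value.
#' @examples
#' cfg <- simConfig(nGenes = 300, geneSets = makeGeneSets(300, setSize = 40,
#'                                                        nSets = 5),
#'                  perturbedSets = c(pathway01 = 2), seed = 1)
#' sim <- simulateTwoColor(cfg)
#' norm <- lowessNormalize(sim$experiment)
#' de <- runDE(norm, nPerm = 200, seed = 2)
#' runEnrichment(norm, cfg@geneSets, de, nResample = 200, seed = 3)
#' @export
runEnrichment <- function(x, collection, deResult = NULL, group = NULL,
                          method = c("both", "rank", "design"),
                          nResample = 1000L, seed = 1L, alpha = 0.05,
                          rankScope = "global", adjust = FALSE,
                          assay = 1L) {
  method <- match.arg(method)
  m <- .assayMatrix(x, assay)
  group <- .resolveGroup(x, group)
  measured <- rownames(m)
  sig <- if (is.null(deResult)) character(0)
         else significantGenes(deResult, alpha)

  rows <- list()
  for (i in seq_along(collection)) {
    nm <- names(collection)[i]
    members <- collection[[nm]]
    inter <- intersect(members, measured)
    if (!length(inter)) {
      warning("set '", nm, "' has no measured members; excluded")
      next
    }
    row <- list(set = nm, total = length(inter),
                changing = length(intersect(inter, sig)))
    setSeed <- seed + i
    if (method %in% c("both", "rank")) {
      rt <- rankBasedTest(m, inter, group, nPerm = nResample,
                          seed = setSeed, rankScope = rankScope)
      row$pRank <- rt$p.value; row$dRank <- unname(rt$statistic)
    }
    if (method %in% c("both", "design")) {
      dt <- designBasedTest(m, inter, group, nBoot = nResample,
                            seed = setSeed)
      row$pDesign <- dt$p.value; row$dDesign <- unname(dt$statistic)
    }
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) stop("no gene set overlaps the measured genes")
  out <- S4Vectors::DataFrame(do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE))))
  ## ascending p; ties (granular resampling p) broken by larger distance
  if ("pRank" %in% colnames(out)) {
    out <- out[order(out$pRank, -out$dRank), , drop = FALSE]
  } else {
    out <- out[order(out$pDesign, -out$dDesign), , drop = FALSE]
  }
  if (adjust) {
    if ("pRank" %in% colnames(out)) out$fdrRank <- fdrAdjust(out$pRank)
    if ("pDesign" %in% colnames(out)) out$fdrDesign <- fdrAdjust(out$pDesign)
  }
  S4Vectors::metadata(out) <- list(method = method, nResample = nResample,
                                   seed = seed, alpha = alpha)
  out
}

# ---------------------------------------------------------------------------
# GMT input/output
# ---------------------------------------------------------------------------

#' Read and write GMT gene-set files
#'
#' Standard tab-separated GMT: one set per line as
#' `name <TAB> description <TAB> member1 <TAB> member2 ...`. Duplicate
#' members within a set are removed with a warning; duplicate set names are
#' an error.
#'
#' @param path File path.
#' @return `readGmt()` returns a [GeneSetList].
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  nms <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nms))
    stop("duplicate set names in GMT: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  ndup <- sum(vapply(sets, function(s) sum(duplicated(s)), numeric(1)))
  if (ndup > 0)
    warning("removed ", ndup, " duplicate member(s) within sets")
  names(sets) <- nms
  GeneSetList(sets, description = desc)
}

#' @param x A [GeneSetList].
#' @rdname readGmt
#' @export
writeGmt <- function(x, path) {
  desc <- setDescriptions(x)
  lines <- vapply(names(x), function(nm)
    paste(c(nm, desc[[nm]], x[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
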