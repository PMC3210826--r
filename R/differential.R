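## Gene-wise two-group differential expression: least-square means,
## shrinkage Fs statistic, residual-shuffling permutation p-values,
## Benjamini-Hochberg FDR, least-square-mean fold changes, and the
## parametric gene-specific F1 test.

## Vectorized per-gene one-way two-group decomposition. Handles NA cells.
.rowGroupStats <- function(y, group) {
  g1 <- group == levels(group)[1]
  y1 <- y[, g1, drop = FALSE]; y2 <- y[, !g1, drop = FALSE]
  n1 <- rowSums(!is.na(y1)); n2 <- rowSums(!is.na(y2))
  m1 <- rowMeans(y1, na.rm = TRUE); m2 <- rowMeans(y2, na.rm = TRUE)
  n <- n1 + n2
  grand <- (n1 * m1 + n2 * m2) / n
  ssTreat <- n1 * (m1 - grand)^2 + n2 * (m2 - grand)^2
  rss <- rowSums(y1^2, na.rm = TRUE) + rowSums(y2^2, na.rm = TRUE) -
    n1 * m1^2 - n2 * m2^2
  rss <- pmax(rss, 0)                       # guard tiny negative round-off
  df <- n - 2
  list(m1 = m1, m2 = m2, grand = grand, msTreat = ssTreat,
       residMS = ifelse(df > 0, rss / df, NA_real_), df = df)
}

#' Fit per-gene two-group linear models
#'
#' For every gene, computes the least-square group means, the treatment mean
#' square (1 df), and the residual mean square with `n - 2` degrees of
#' freedom, retaining both full-model and null-model (grand-mean) residuals
#' for resampling. Genes with fewer than 1 residual degree of freedom get
#' `NA` statistics.
#'
#' @param x An [ArrayExperiment] (normalized log2 ratios or log2
#'   intensities) or numeric matrix.
#' @param group Two-level factor of treatment labels; defaults to
#'   `colData(x)$group`.
#' @param assay Assay to model.
#' @return A [GeneFits] object.
#' @examples
#' y <- matrix(rnorm(40), 10, 4)
#' fitGeneModels(y, group = rep(c("control", "treated"), each = 2))
#' @export
fitGeneModels <- function(x, group = NULL, assay = 1L) {
  y <- .assayMatrix(x, assay)
  group <- .resolveGroup(x, group)
  if (length(group) != ncol(y))
    stop("length of 'group' must match the number of samples")
  st <- .rowGroupStats(y, group)
  g1 <- group == levels(group)[1]
  fitted <- matrix(NA_real_, nrow(y), ncol(y))
  fitted[, g1] <- st$m1; fitted[, !g1] <- st$m2
  lsMeans <- cbind(st$m1, st$m2)
  colnames(lsMeans) <- levels(group)
  rownames(lsMeans) <- rownames(y)
  methods::new("GeneFits",
               lsMeans = lsMeans, msTreat = st$msTreat,
               residMS = st$residMS, df = st$df,
               residuals = y - fitted,
               nullResiduals = y - st$grand,
               group = group)
}

#' Shrink gene-wise residual variances (James-Stein, log scale)
#'
#' Shrinks each gene's residual variance toward the across-gene center on
#' the log-variance scale, with the positive-part Lindley-James-Stein
#' factor `1 - (G-3) * trigamma(df/2) / sum((X - Xbar)^2)` clipped to
#' `[0, 1]`, where `X = log(residMS)`. With a single gene the variance is
#' returned unchanged; when all variances are equal every gene keeps its own
#' variance (no shrinkage possible). The estimator is equivariant across
#' genes, so permutation p-values of the resulting Fs are unaffected by any
#' gene-constant scale factor.
#'
#' @param s2 Numeric vector of residual variances.
#' @param df Residual degrees of freedom (scalar or per-gene; the median is
#'   used for the log-variance sampling variance).
#' @return Numeric vector of shrunk variances.
#' @export
shrinkVariances <- function(s2, df) {
  ok <- !is.na(s2)
  if (!any(ok)) stop("no usable residual variances")
  if (all(s2[ok] == 0)) stop("all residual variances are zero: degenerate data")
  out <- s2
  G <- sum(ok)
  if (G == 1L) return(out)
  pos <- ok & s2 > 0
  X <- log(s2[pos])
  Xbar <- mean(X)
  S <- sum((X - Xbar)^2)
  nu <- stats::median(df[pos], na.rm = TRUE)
  V <- trigamma(nu / 2)
  b <- if (S == 0) 0 else 1 - (sum(pos) - 3) * V / S
  b <- min(max(b, 0), 1)
  out[pos] <- exp(Xbar + b * (X - Xbar))
  out[ok & s2 == 0] <- exp(Xbar)   # fully shrunk to the center
  out
}

#' Shrinkage Fs statistic
#'
#' `Fs_g = MS_treat_g / shrunk variance_g`, the F-like statistic whose
#' denominator is stabilized by cross-gene variance shrinkage
#' (see [shrinkVariances]). Significance is assessed by residual-shuffling
#' permutation, not by the F distribution.
#'
#' @param fits A [GeneFits] object.
#' @return Numeric vector of per-gene Fs values.
#' @export
fsStatistic <- function(fits) {
  shr <- shrinkVariances(fits@residMS, fits@df)
  fs <- fits@msTreat / shr
  fs[is.na(fits@residMS)] <- NA_real_
  fs[which(fits@msTreat == 0)] <- 0
  fs
}

## Ordinary gene-specific F (F1): no shrinkage.
.f1Statistic <- function(msTreat, residMS) {
  f <- msTreat / residMS
  f[msTreat == 0] <- 0                       # 0/0 -> no effect
  f[msTreat > 0 & residMS == 0] <- Inf
  f
}

#' Residual-shuffling permutation p-values
#'
#' Residuals from the null (no-treatment) fit are shuffled as whole
#' sample-columns -- preserving gene-gene correlation -- the null data are
#' rebuilt and the statistic recomputed. The add-one estimator
#' `p = (1 + #\{perm >= observed\}) / (nPerm + 1)` is returned per gene
#' (gene-specific null by default; `pool = TRUE` compares each observed
#' statistic against the pooled permutation distribution of all genes).
#'
#' @param fits A [GeneFits] object.
#' @param statistic `"fs"` (shrinkage F, default) or `"f1"` (ordinary F).
#' @param nPerm Number of permutations, at least 100.
#' @param seed Integer seed.
#' @param pool Pool permuted statistics across genes?
#' @return Numeric vector of raw p-values.
#' @export
permutationPvalues <- function(fits, statistic = c("fs", "f1"),
                               nPerm = 1000L, seed = 1L, pool = FALSE) {
  statistic <- match.arg(statistic)
  if (nPerm < 100L) stop("'nPerm' must be at least 100")
  statFun <- function(y) {
    st <- .rowGroupStats(y, fits@group)
    if (statistic == "fs")
      st$msTreat / shrinkVariances(st$residMS, st$df)
    else .f1Statistic(st$msTreat, st$residMS)
  }
  obs <- if (statistic == "fs") fsStatistic(fits)
         else .f1Statistic(fits@msTreat, fits@residMS)
  y0 <- fits@nullResiduals
  S <- ncol(y0)
  withr::with_seed(seed, {
    if (pool) {
      exceed <- numeric(length(obs)); total <- 0L
      for (b in seq_len(nPerm)) {
        stat <- statFun(y0[, sample(S), drop = FALSE])
        stat <- stat[!is.na(stat)]
        total <- total + length(stat)
        exceed <- exceed + vapply(obs, function(o) sum(stat >= o), numeric(1))
      }
      p <- (1 + exceed) / (total + 1)
    } else {
      exceed <- numeric(length(obs))
      for (b in seq_len(nPerm)) {
        stat <- statFun(y0[, sample(S), drop = FALSE])
        exceed <- exceed + as.numeric(stat >= obs)
      }
      p <- addOneP(exceed, nPerm)
    }
  })
  p[is.na(obs)] <- NA_real_
  unname(p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment `q_(i) = min_{j>=i} m p_(j)/j`, capped at 1 and
#' returned in input order (via [stats::p.adjust]).
#'
#' @param p Numeric vector of raw p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03, 0.5))
#' @export
fdrAdjust <- function(p) {
  if (!is.numeric(p)) stop("'p' must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fold changes from least-square means
#'
#' `FC = 2^(LSmean_treated - LSmean_control)`, with values below 1 reported
#' as `-1/FC` (signed convention: negative = downregulation, `|FC| >= 1`).
#'
#' @param fits A [GeneFits] object.
#' @param treated,control Group labels; default to the second and first
#'   factor level of the design.
#' @return Numeric vector of signed linear fold changes.
#' @export
foldChangeLsmeans <- function(fits, treated = levels(fits@group)[2],
                              control = levels(fits@group)[1]) {
  d <- fits@lsMeans[, treated] - fits@lsMeans[, control]
  unname(signedFoldChange(d))
}

#' Parametric F1 test for single-channel data
#'
#' The ordinary gene-specific one-way F statistic with parametric p-values
#' from the F distribution with `(1, n - 2)` degrees of freedom, followed by
#' Benjamini-Hochberg adjustment. For two groups this is the squared pooled
#' two-sample t test.
#'
#' @param x An [ArrayExperiment] or matrix of (log2) expression values.
#' @param group Two-level treatment factor (defaults to `colData(x)$group`).
#' @param assay Assay to test.
#' @param alpha Significance threshold recorded in the result.
#' @return A [DEResult] with method `"f1-parametric"`.
#' @export
f1Test <- function(x, group = NULL, assay = 1L, alpha = 0.05) {
  fits <- fitGeneModels(x, group, assay)
  f <- .f1Statistic(fits@msTreat, fits@residMS)
  p <- stats::pf(f, 1, fits@df, lower.tail = FALSE)
  p[which(f == 0)] <- 1                     # no observed effect
  p[which(is.infinite(f))] <- 0
  p[which(fits@df < 1)] <- NA_real_
  .deResult(fits, f, p, "f1-parametric", alpha)
}

.deResult <- function(fits, stat, p, method, alpha) {
  d <- fits@lsMeans[, 2] - fits@lsMeans[, 1]
  ids <- rownames(fits@lsMeans)
  if (is.null(ids)) ids <- sprintf("gene%d", seq_along(stat))
  res <- S4Vectors::DataFrame(
    gene = ids,
    statistic = unname(stat), pvalue = unname(p),
    fdr = fdrAdjust(unname(p)),
    foldChange = unname(signedFoldChange(d)),
    log2FoldChange = unname(d))
  methods::new("DEResult", results = res, method = method, alpha = alpha)
}

#' Run the full differential-expression analysis
#'
#' Convenience wrapper: per-gene fits, test statistic (`"fs"` with
#' residual-shuffling permutation p-values, or `"f1"` with parametric
#' p-values), FDR adjustment and least-square-mean fold changes.
#'
#' @param x An [ArrayExperiment] or matrix of normalized values.
#' @param group Two-level treatment factor (defaults to `colData(x)$group`).
#' @param statistic `"fs"` or `"f1"`.
#' @param nPerm Permutations for the Fs test.
#' @param seed Integer seed for the permutation draw.
#' @param alpha Adjusted-p significance threshold.
#' @param pool Pool permutation null across genes?
#' @param assay Assay to analyze.
#' @return A [DEResult].
#' @examples
#' sim <- simulateTwoColor(simConfig(nGenes = 120, seed = 1))
#' norm <- lowessNormalize(sim$experiment)
#' de <- runDE(norm, nPerm = 100, seed = 2)
#' de
#' @export
runDE <- function(x, group = NULL, statistic = c("fs", "f1"),
                  nPerm = 1000L, seed = 1L, alpha = 0.05, pool = FALSE,
                  assay = 1L) {
  statistic <- match.arg(statistic)
  if (statistic == "f1") return(f1Test(x, group, assay, alpha))
  fits <- fitGeneModels(x, group, assay)
  stat <- fsStatistic(fits)
  p <- permutationPvalues(fits, "fs", nPerm = nPerm, seed = seed, pool = pool)
  .deResult(fits, stat, p, "fs-permutation", alpha)
}
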