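## Array normalization: LOWESS for two-color log-ratios, quantile
## normalization for single-channel data, negative-control present calls,
## technical-replicate collapsing and array-level QC.

#' LOWESS normalization of two-color arrays
#'
#' Per array, computes the MA transform `M = log2(red/green)`,
#' `A = (log2 red + log2 green)/2` and removes intensity-dependent dye bias
#' by subtracting a locally weighted regression of M on A
#' (`M' = M - fhat(A)`, robustified LOWESS via [stats::lowess]).
#' Probes with a zero or negative value in either channel cannot be logged:
#' they are excluded from smoothing and returned as `NA` (the per-array
#' counts are reported in `metadata(x)$droppedNonPositive`).
#'
#' @param x An [ArrayExperiment] with assays `red` and `green` on the raw
#'   intensity scale.
#' @param span LOWESS smoother span (fraction of probes per window), in
#'   `(0, 1]`. Default 0.4.
#' @param iter Robustifying reweighting iterations. Default 3.
#' @return An `ArrayExperiment` with assays `M` (normalized log2 ratios) and
#'   `A` (mean log2 intensities).
#' @examples
#' sim <- simulateTwoColor(simConfig(nGenes = 300, seed = 1))
#' norm <- lowessNormalize(sim$experiment)
#' summary(as.vector(SummarizedExperiment::assay(norm, "M")))
#' @export
lowessNormalize <- function(x, span = 0.4, iter = 3) {
  stopifnot(methods::is(x, "ArrayExperiment"))
  if (!all(c("red", "green") %in% SummarizedExperiment::assayNames(x)))
    stop("two-color normalization needs 'red' and 'green' assays")
  if (!is.numeric(span) || length(span) != 1L || span <= 0 || span > 1)
    stop("'span' must be in (0, 1]")
  red <- .assayMatrix(x, "red"); green <- .assayMatrix(x, "green")
  bad <- !(red > 0 & green > 0)
  red[bad] <- NA; green[bad] <- NA

  M <- log2(red / green)
  A <- 0.5 * (log2(red) + log2(green))
  Mn <- M
  for (j in seq_len(ncol(M))) {
    ok <- is.finite(M[, j]) & is.finite(A[, j])
    if (sum(ok) < 10L) stop("too few usable probes on array ", colnames(M)[j])
    fit <- stats::lowess(A[ok, j], M[ok, j], f = span, iter = iter)
    fhat <- stats::approx(fit$x, fit$y, xout = A[ok, j], rule = 2,
                          ties = mean)$y
    Mn[ok, j] <- M[ok, j] - fhat
  }
  dropped <- colSums(bad)
  if (any(dropped > 0))
    message("excluded ", sum(dropped),
            " probe/array values with non-positive channel intensities")
  out <- ArrayExperiment(list(M = Mn, A = A),
                         rowData = SummarizedExperiment::rowData(x),
                         colData = SummarizedExperiment::colData(x),
                         metadata = c(S4Vectors::metadata(x),
                                      list(scale = "log2 ratio",
                                           droppedNonPositive = dropped,
                                           lowessSpan = span)))
  out
}

#' Quantile normalization
#'
#' Forces all arrays to share one intensity distribution: each column's
#' order statistics are mapped to the across-column mean order statistics
#' (ties receive the average of their assigned values). Backed by
#' [limma::normalizeQuantiles].
#'
#' @param x An [ArrayExperiment] (single assay used) or numeric matrix with
#'   at least two columns and no missing values.
#' @param assay Assay to normalize when `x` is an `ArrayExperiment`.
#' @return Same type as the input, with normalized values.
#' @examples
#' m <- cbind(a = c(2, 6, 4), b = c(8, 2, 4))
#' quantileNormalize(m)
#' @export
quantileNormalize <- function(x, assay = 1L) {
  m <- .assayMatrix(x, assay)
  if (ncol(m) < 2L) stop("quantile normalization needs >= 2 samples")
  if (anyNA(m)) stop("quantile normalization requires complete data")
  qn <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(qn) <- dimnames(m)
  if (methods::is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, assay) <- qn
    x
  } else qn
}

#' Present calls from negative-control probes
#'
#' Per sample, a detection threshold is built from the array's
#' negative-control probes as `trimmed mean + 3 * trimmed SD`; a probe is
#' called present iff its signal strictly exceeds the threshold.
#'
#' @param x An [ArrayExperiment] whose `rowData` flags `negativeControl`
#'   probes (at least 3 per array), or a numeric matrix together with
#'   `negative` giving the control rows.
#' @param trim Fraction trimmed from each tail of the control distribution
#'   before mean/SD, in `[0, 0.25)`. Default 0.05.
#' @param negative Optional logical vector of control rows (matrix input).
#' @return Logical probes-by-samples matrix of present calls (controls
#'   excluded from the rows).
#' @examples
#' sim <- simulateSingleChannel(simConfig(nGenes = 50, seed = 1))
#' calls <- presentCall(sim$experiment)
#' mean(calls)
#' @export
presentCall <- function(x, trim = 0.05, negative = NULL) {
  m <- .assayMatrix(x)
  if (is.null(negative)) {
    if (!methods::is(x, "ArrayExperiment"))
      stop("'negative' must be given for matrix input")
    negative <- negativeControls(x)
  }
  negative <- as.logical(negative)
  if (sum(negative) < 3L)
    stop("at least 3 negative-control probes are required, got ",
         sum(negative))
  signal <- m[!negative, , drop = FALSE]
  calls <- matrix(NA, nrow(signal), ncol(signal), dimnames = dimnames(signal))
  for (j in seq_len(ncol(m))) {
    nc <- m[negative, j]
    thr <- trimmedMean(nc, trim) + 3 * trimmedSD(nc, trim)
    calls[, j] <- signal[, j] > thr       # strict inequality
  }
  calls
}

#' Collapse technical-replicate probes to target level
#'
#' Probes sharing a `target` annotation are averaged using the median signal
#' intensity, per sample. Probes without a target annotation (e.g. negative
#' controls) are dropped with a message.
#'
#' @param x An [ArrayExperiment] with a `target` column in `rowData`.
#' @param assay Assay to collapse.
#' @return An `ArrayExperiment` with one row per target.
#' @examples
#' sim <- simulateSingleChannel(simConfig(nGenes = 20, seed = 1))
#' collapseReplicates(sim$experiment)
#' @export
collapseReplicates <- function(x, assay = 1L) {
  stopifnot(methods::is(x, "ArrayExperiment"))
  target <- probeTargets(x)
  if (all(is.na(target))) stop("probe-to-target mapping ('target') required")
  keep <- !is.na(target)
  if (any(!keep))
    message("dropping ", sum(!keep), " probes without a target annotation")
  m <- .assayMatrix(x, assay)[keep, , drop = FALSE]
  target <- target[keep]
  idx <- split(seq_len(nrow(m)), target)
  collapsed <- t(vapply(idx, function(i)
    apply(m[i, , drop = FALSE], 2, stats::median),
    numeric(ncol(m))))
  colnames(collapsed) <- colnames(m)
  ArrayExperiment(stats::setNames(list(collapsed),
                                  SummarizedExperiment::assayNames(x)[assay]),
                  rowData = S4Vectors::DataFrame(
                    target = rownames(collapsed),
                    negativeControl = FALSE,
                    row.names = rownames(collapsed)),
                  colData = SummarizedExperiment::colData(x),
                  metadata = S4Vectors::metadata(x))
}

#' Flag outlier arrays by inter-array correlation
#'
#' Advisory QC: an array is flagged when its median Spearman correlation to
#' all other arrays falls below `threshold`. The caller decides whether to
#' exclude flagged arrays; nothing is removed here.
#'
#' @param x An [ArrayExperiment] or matrix with at least 3 samples.
#' @param threshold Correlation threshold; arrays strictly below are
#'   flagged. Default 0.5.
#' @param assay Assay to use.
#' @return Character vector of flagged sample names (possibly empty).
#' @examples
#' m <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' m[, 2] <- m[, 1] + rnorm(100, sd = 0.1)
#' qcFlagOutlierArrays(m, threshold = 0.2)
#' @export
qcFlagOutlierArrays <- function(x, threshold = 0.5, assay = 1L) {
  m <- .assayMatrix(x, assay)
  if (ncol(m) < 3L) stop("QC needs at least 3 arrays")
  cc <- stats::cor(m, method = "spearman", use = "pairwise.complete.obs")
  diag(cc) <- NA
  medcor <- apply(cc, 2, stats::median, na.rm = TRUE)
  names(medcor)[medcor < threshold]
}
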