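## Internal helpers shared across modules.

#' Trimmed mean and trimmed standard deviation
#'
#' Symmetric trimming: `floor(trim * n)` observations are removed from each
#' tail before the mean or SD is computed. `trim = 0` gives the ordinary
#' sample statistics.
#'
#' @param x Numeric vector.
#' @param trim Fraction to trim from each tail, in `[0, 0.25)`.
#' @return A single numeric value.
#' @keywords internal
#' @noRd
trimmedValues <- function(x, trim) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  if (!is.numeric(trim) || length(trim) != 1L || trim < 0 || trim >= 0.25)
    stop("'trim' must be a single fraction in [0, 0.25)")
  x <- sort(x)
  k <- floor(trim * length(x))
  if (2L * k >= length(x)) stop("trimming removes all observations")
  x[(k + 1L):(length(x) - k)]
}

trimmedMean <- function(x, trim = 0) mean(trimmedValues(x, trim))

trimmedSD <- function(x, trim = 0) {
  kept <- trimmedValues(x, trim)
  if (length(kept) < 2L) stop("need >= 2 observations after trimming")
  stats::sd(kept)
}

## Signed fold-change convention: values below 1 are reported as -1/FC so
## that |FC| >= 1 always and the sign encodes direction.
signedFoldChange <- function(log2diff, base = 2) {
  fc <- base^log2diff
  ifelse(fc >= 1, fc, -1 / fc)
}

## Resolve a two-level grouping factor for an experiment or matrix.
.resolveGroup <- function(x, group = NULL) {
  if (is.null(group)) {
    if (methods::is(x, "SummarizedExperiment")) {
      cd <- SummarizedExperiment::colData(x)
      if (!"group" %in% colnames(cd))
        stop("no 'group' column in colData and no 'group' argument supplied")
      group <- cd$group
    } else {
      stop("'group' must be supplied for plain matrices")
    }
  }
  group <- as.factor(as.vector(group))
  group <- droplevels(group)
  if (nlevels(group) != 2L)
    stop("exactly two treatment groups are required, got ", nlevels(group))
  if (any(table(group) < 2L))
    stop("each treatment group needs at least 2 samples")
  group
}

.assayMatrix <- function(x, assay = 1L) {
  if (methods::is(x, "SummarizedExperiment"))
    as.matrix(SummarizedExperiment::assay(x, assay))
  else as.matrix(x)
}

## Add-one permutation p-value: ties count as exceedances (conservative).
addOneP <- function(nExceed, nResample) (1 + nExceed) / (nResample + 1)
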