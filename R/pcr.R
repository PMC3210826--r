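## Comparative-Ct relative quantification for PCR arrays, with a REST-style
## randomization significance test and a two-sample t test on normalized
## (delta-Ct) expression.

## Average technical replicates, then compute per-sample delta-Ct for one
## gene: Ct_gene - mean(Ct_housekeeping). Samples missing the gene or any
## housekeeping well are dropped with a warning.
.deltaCt <- function(t, gene) {
  stopifnot(methods::is(t, "CtTable"))
  d <- t@data
  agg <- stats::aggregate(ct ~ sample + group + gene, data = d, FUN = mean)
  hk <- agg[agg$gene %in% t@housekeeping, ]
  hkMean <- tapply(hk$ct, hk$sample, mean)
  nHk <- tapply(hk$gene, hk$sample, function(g) length(unique(g)))
  g <- agg[agg$gene == gene, ]
  if (!nrow(g)) stop("gene '", gene, "' not found in the Ct table")
  ok <- g$sample %in% names(hkMean)[nHk == length(t@housekeeping)]
  if (any(!ok))
    warning("dropping sample(s) with missing housekeeping wells: ",
            paste(g$sample[!ok], collapse = ", "))
  g <- g[ok, ]
  data.frame(sample = g$sample, group = g$group,
             deltaCt = g$ct - as.numeric(hkMean[g$sample]))
}

.geneEfficiency <- function(t, gene) {
  e <- t@efficiency
  if (!is.null(names(e)) && gene %in% names(e)) unname(e[[gene]])
  else unname(e[[1]])
}

#' Comparative-Ct (delta-delta-Ct) fold change
#'
#' Per sample, `deltaCt = Ct_gene - mean(Ct_housekeeping)`; then
#' `ddCt = mean(deltaCt | treated) - mean(deltaCt | control)` and
#' `FC = E^(-ddCt)` with amplification efficiency E (2.0 by default, i.e.
#' perfect doubling). The signed reporting convention matches the
#' differential-expression module: fold changes below 1 are returned as
#' `-1/FC`.
#'
#' @param t A [CtTable].
#' @param gene Target gene name.
#' @param treated,control Group labels.
#' @return A list with `foldChange` (signed), `ratio` (raw `E^-ddCt`),
#'   `ddCt`, `efficiency`, and the per-group sample counts.
#' @examples
#' d <- expand.grid(sample = paste0("s", 1:4), gene = c("Tnf", "Hprt"))
#' d$group <- rep(c("control", "treated"), each = 2)
#' d$ct <- c(24, 24, 22, 22, 20, 20, 20, 20)
#' ddctFoldChange(CtTable(d, housekeeping = "Hprt"), "Tnf")
#' @export
ddctFoldChange <- function(t, gene, treated = "treated",
                           control = "control") {
  dct <- .deltaCt(t, gene)
  E <- .geneEfficiency(t, gene)
  mT <- mean(dct$deltaCt[dct$group == treated])
  mC <- mean(dct$deltaCt[dct$group == control])
  if (is.nan(mT) || is.nan(mC))
    stop("gene '", gene, "' lacks Ct values in one of the groups")
  ddCt <- mT - mC
  ratio <- E^(-ddCt)
  list(foldChange = unname(signedFoldChange(-ddCt, base = E)),
       ratio = ratio, ddCt = ddCt, efficiency = E,
       nTreated = sum(dct$group == treated),
       nControl = sum(dct$group == control))
}

#' REST-style randomization test for relative expression
#'
#' The observed statistic is the expression ratio `E^(-ddCt)`. The null is
#' built by randomly reallocating samples between the treated and control
#' labels (group sizes fixed) and recomputing the ratio; the two-sided
#' p-value is `(1 + #\{|log ratio*| >= |log ratio|\}) / (nRand + 1)`.
#'
#' @param t A [CtTable] with at least 3 samples per group.
#' @param gene Target gene name.
#' @param treated,control Group labels.
#' @param nRand Number of random reallocations, at least 1000.
#' @param seed Integer seed.
#' @return An `"htest"` object with `estimate` the expression ratio.
#' @export
restRandomizationTest <- function(t, gene, treated = "treated",
                                  control = "control", nRand = 2000L,
                                  seed = 1L) {
  if (nRand < 1000L) stop("'nRand' must be at least 1000")
  dct <- .deltaCt(t, gene)
  isT <- dct$group == treated
  nT <- sum(isT); nC <- sum(dct$group == control)
  if (nT < 3L || nC < 3L)
    stop("REST randomization needs at least 3 samples per group")
  E <- .geneEfficiency(t, gene)
  v <- dct$deltaCt[dct$group %in% c(treated, control)]
  lab <- isT[dct$group %in% c(treated, control)]
  obsLog <- abs(mean(v[lab]) - mean(v[!lab])) * log(E)
  exceed <- withr::with_seed(seed, {
    sum(vapply(seq_len(nRand), function(b) {
      rl <- sample(lab)
      abs(mean(v[rl]) - mean(v[!rl])) * log(E) >= obsLog
    }, logical(1)))
  })
  ratio <- E^(-(mean(v[lab]) - mean(v[!lab])))
  structure(list(statistic = c(absLogRatio = obsLog),
                 estimate = c(ratio = ratio),
                 p.value = addOneP(exceed, nRand),
                 parameter = c(nRand = nRand),
                 method = "REST-style randomization test (fixed reallocation)",
                 data.name = gene),
            class = "htest")
}

#' Two-sample t test on normalized expression
#'
#' Equal-variance two-sided t test on the per-sample housekeeping-normalized
#' delta-Ct values, reported with the comparative-Ct fold change. Degenerate
#' zero-variance input is handled at the limit (p = 1 when the group means
#' agree, p = 0 otherwise).
#'
#' @param t A [CtTable] with at least 2 samples per group.
#' @param gene Target gene name.
#' @param treated,control Group labels.
#' @return A list with `foldChange`, `p.value`, `statistic` and `method`.
#' @export
normalizedExpressionTtest <- function(t, gene, treated = "treated",
                                      control = "control") {
  dct <- .deltaCt(t, gene)
  vT <- dct$deltaCt[dct$group == treated]
  vC <- dct$deltaCt[dct$group == control]
  if (length(vT) < 2L || length(vC) < 2L)
    stop("t test needs at least 2 samples per group")
  fc <- ddctFoldChange(t, gene, treated, control)$foldChange
  pooledVar <- (sum((vT - mean(vT))^2) + sum((vC - mean(vC))^2)) /
    (length(vT) + length(vC) - 2)
  if (pooledVar == 0) {
    p <- if (mean(vT) == mean(vC)) 1 else 0
    stat <- if (p == 1) 0 else Inf
  } else {
    tt <- stats::t.test(vT, vC, var.equal = TRUE)
    p <- tt$p.value; stat <- unname(tt$statistic)
  }
  list(foldChange = fc, p.value = p, statistic = stat,
       method = "Two-sample equal-variance t test on delta-Ct")
}

#' Read a long-format Ct CSV
#'
#' Expects columns `sample`, `group`, `gene`, `ct` and optionally
#' `replicate`.
#'
#' @param path CSV file path.
#' @param housekeeping Character vector of housekeeping gene names.
#' @param efficiency Amplification efficiency (scalar or named per-gene).
#' @return A [CtTable].
#' @export
readCtCsv <- function(path, housekeeping, efficiency = 2) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  CtTable(d, housekeeping = housekeeping, efficiency = efficiency)
}

#' PCR-array report
#'
#' Fold change and REST randomization p-value for every non-housekeeping
#' gene of a Ct table (Table-style layout: gene, fold_change, p).
#'
#' @param t A [CtTable].
#' @param treated,control Group labels.
#' @param nRand Randomizations per gene.
#' @param seed Integer seed (per-gene seeds derived deterministically).
#' @return A data.frame with columns `gene`, `foldChange`, `p`.
#' @export
pcrReport <- function(t, treated = "treated", control = "control",
                      nRand = 2000L, seed = 1L) {
  genes <- setdiff(unique(t@data$gene), t@housekeeping)
  rows <- lapply(seq_along(genes), function(i) {
    fc <- ddctFoldChange(t, genes[i], treated, control)
    rt <- restRandomizationTest(t, genes[i], treated, control,
                                nRand = nRand, seed = seed + i)
    data.frame(gene = genes[i], foldChange = fc$foldChange, p = rt$p.value)
  })
  out <- do.call(rbind, rows)
  out[order(out$p, -abs(out$foldChange)), , drop = FALSE]
}
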