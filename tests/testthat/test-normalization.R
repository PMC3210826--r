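# LOWESS and quantile normalization, present calls, replicate collapsing,
# array QC.

makeTwoColor <- function(M, A) {
  ids <- sprintf("p%03d", seq_len(nrow(M)))
  dimnames(M) <- dimnames(A) <- list(ids, sprintf("s%02d", seq_len(ncol(M))))
  ArrayExperiment(list(red = 2^(A + M / 2), green = 2^(A - M / 2)))
}

test_that("lowess normalization removes a constant log-ratio offset", {
  withr::with_seed(1, A <- matrix(runif(400, 6, 14), 200, 2))
  M <- matrix(1.7, 200, 2)
  out <- lowessNormalize(makeTwoColor(M, A))
  expect_lt(max(abs(SummarizedExperiment::assay(out, "M"))), 1e-6)
})

test_that("lowess normalization recovers an exact linear M~A trend", {
  withr::with_seed(2, A <- matrix(runif(600, 6, 14), 300, 2))
  M <- 0.5 * A
  out <- lowessNormalize(makeTwoColor(M, A))
  interior <- A > quantile(A, 0.1) & A < quantile(A, 0.9)
  expect_lt(max(abs(SummarizedExperiment::assay(out, "M")[interior])), 0.02)
})

test_that("an injected noiseless dye-bias curve is removed", {
  cfg <- noiselessConfig(nGenes = 800, seed = 3)
  sim <- simulateTwoColor(cfg)
  red <- SummarizedExperiment::assay(sim$experiment, "red")
  green <- SummarizedExperiment::assay(sim$experiment, "green")
  A <- 0.5 * (log2(red) + log2(green))
  bias <- range(log2(red / green))           # M is pure bias here
  amplitude <- diff(bias)
  out <- lowessNormalize(sim$experiment)
  Mn <- SummarizedExperiment::assay(out, "M")
  interior <- A > quantile(A, 0.1) & A < quantile(A, 0.9)
  expect_lt(max(abs(Mn[interior])), 0.01 * amplitude)
})

test_that("probes with non-positive channel values become NA, others survive", {
  withr::with_seed(4, A <- matrix(runif(200, 6, 14), 100, 2))
  ae <- makeTwoColor(matrix(0.2, 100, 2), A)
  red <- SummarizedExperiment::assay(ae, "red")
  red[1, 1] <- 0
  SummarizedExperiment::assay(ae, "red") <- red
  expect_message(out <- lowessNormalize(ae), "non-positive")
  Mn <- SummarizedExperiment::assay(out, "M")
  expect_true(is.na(Mn[1, 1]))
  expect_equal(nrow(Mn), 100)               # retained as missing, not dropped
  expect_true(all(is.finite(Mn[-1, ])))
})

test_that("quantile normalization matches the sorted-mean hand example", {
  m <- cbind(s1 = c(2, 6, 4), s2 = c(8, 2, 4))
  qn <- quantileNormalize(m)
  expect_equal(unname(qn[, 1]), c(2, 7, 4))
  expect_equal(unname(qn[, 2]), c(7, 2, 4))
})

test_that("quantile normalization is a fixed point on identical columns and idempotent", {
  m <- matrix(rep(c(1, 5, 9, 2), 3), 4, 3)
  expect_equal(quantileNormalize(m), m, ignore_attr = TRUE)
  withr::with_seed(5, x <- matrix(rexp(200), 50, 4))
  once <- quantileNormalize(x)
  expect_equal(quantileNormalize(once), once)
  # within-column rank order is preserved
  for (j in 1:4) expect_equal(rank(once[, j]), rank(x[, j]))
  expect_error(quantileNormalize(matrix(c(1, NA, 2, 3), 2)), "complete")
  expect_error(quantileNormalize(matrix(1:3, 3, 1)), ">= 2 samples")
})

test_that("present calls use a strict > threshold from the control stats", {
  # zero-spread controls: threshold is exactly 10
  m <- rbind(probeA = c(10, 10.5), probeB = c(10.5, 10),
             nc1 = c(10, 10), nc2 = c(10, 10), nc3 = c(10, 10))
  calls <- presentCall(m, trim = 0, negative = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_identical(unname(calls), rbind(c(FALSE, TRUE), c(TRUE, FALSE)))
})

test_that("present-call threshold equals trimmed mean + 3 trimmed SD", {
  nc <- c(6, 8, 10, 12, 14)
  thr <- mean(nc) + 3 * sd(nc)
  m <- rbind(matrix(c(thr - 0.01, thr + 0.01), 2, 1),
             matrix(nc, 5, 1))
  calls <- presentCall(m, trim = 0, negative = c(FALSE, FALSE, rep(TRUE, 5)))
  expect_identical(unname(calls[, 1]), c(FALSE, TRUE))
})

test_that("trimming protects the threshold from a control outlier", {
  nc <- c(rep(10, 9), 1e6)                # one wild control
  m <- rbind(matrix(10.5, 1, 1), matrix(nc, 10, 1))
  calls <- presentCall(m, trim = 0.1, negative = c(FALSE, rep(TRUE, 10)))
  # trimmed stats: mean 10, sd 0 -> threshold 10 -> 10.5 is present
  expect_true(calls[1, 1])
  expect_error(presentCall(m[1:3, , drop = FALSE], negative = c(FALSE, TRUE, TRUE)),
               "at least 3")
})

test_that("replicate collapsing takes the per-target median", {
  m <- rbind(a_p1 = c(1, 5), a_p2 = c(2, 6), a_p3 = c(100, 7),
             b_p1 = c(9, 9))
  ae <- ArrayExperiment(list(exprs = m),
                        rowData = S4Vectors::DataFrame(
                          target = c("a", "a", "a", "b"),
                          row.names = rownames(m)))
  out <- collapseReplicates(ae)
  ex <- SummarizedExperiment::assay(out)
  expect_equal(unname(ex["a", ]), c(2, 6))       # median robust to the 100
  expect_equal(unname(ex["b", ]), c(9, 9))       # single probe -> identity
})

test_that("replicate collapsing equals a brute-force per-cell median", {
  withr::with_seed(6, {
    G <- 30; k <- 3; S <- 5
    m <- matrix(rnorm(G * k * S), G * k, S)
    tg <- rep(sprintf("t%02d", 1:G), each = k)
    rownames(m) <- sprintf("%s_p%d", tg, rep(1:k, G))
    colnames(m) <- sprintf("s%d", 1:S)
    ae <- ArrayExperiment(list(exprs = m),
                          rowData = S4Vectors::DataFrame(target = tg,
                                                         row.names = rownames(m)))
    out <- SummarizedExperiment::assay(collapseReplicates(ae))
    for (t in unique(tg)) for (j in 1:S)
      expect_equal(out[t, j], median(m[tg == t, j]))
  })
})

test_that("array QC flags only genuinely discordant arrays", {
  withr::with_seed(7, {
    base <- rnorm(200)
    m <- sapply(1:5, function(i) base + rnorm(200, sd = 0.1))
    colnames(m) <- sprintf("s%d", 1:5)
    expect_length(qcFlagOutlierArrays(m, threshold = 0.5), 0)
    m[, 3] <- rnorm(200)                     # independent noise
    expect_identical(qcFlagOutlierArrays(m, threshold = 0.5), "s3")
    expect_length(qcFlagOutlierArrays(m, threshold = -1), 0)
  })
  expect_error(qcFlagOutlierArrays(matrix(1:4, 2, 2)), "at least 3")
})
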