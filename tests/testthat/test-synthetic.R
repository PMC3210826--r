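# Synthetic-data generators: ground truth, determinism, calibration.

test_that("null configuration yields empty truth and zero expected contrast", {
  cfg <- simConfig(nGenes = 100, fracDeGenes = 0,
                   perturbedSets = stats::setNames(numeric(0), character(0)),
                   seed = 1)
  sim <- simulateTwoColor(cfg)
  expect_length(trueEffects(sim$truth), 0)
})

test_that("a fixed seed reproduces two-color output bit for bit", {
  cfg <- simConfig(nGenes = 80, seed = 42)
  a <- simulateTwoColor(cfg); b <- simulateTwoColor(cfg)
  expect_identical(SummarizedExperiment::assay(a$experiment, "red"),
                   SummarizedExperiment::assay(b$experiment, "red"))
  expect_identical(trueEffects(a$truth), trueEffects(b$truth))
  c <- simulateTwoColor(simConfig(nGenes = 80, seed = 43))
  expect_false(identical(SummarizedExperiment::assay(a$experiment, "red"),
                         SummarizedExperiment::assay(c$experiment, "red")))
})

test_that("the configured set shift is recovered from the log-ratios", {
  # delta = 2 on a 200-gene set, 1000 genes, n = 8/group
  cfg <- simConfig(nGenes = 1000,
                   geneSets = makeGeneSets(1000, setSize = 200, nSets = 5),
                   perturbedSets = c(pathway01 = 2), dyeBias = c(0, 0, 0),
                   seed = 7)
  sim <- simulateTwoColor(cfg)
  m <- log2(SummarizedExperiment::assay(sim$experiment, "red") /
            SummarizedExperiment::assay(sim$experiment, "green"))
  members <- geneSets(cfg@geneSets)[["pathway01"]]
  g <- sim$experiment$group
  diff <- rowMeans(m[members, g == "treated"]) -
    rowMeans(m[members, g == "control"])
  expect_lt(abs(mean(diff) - 2), 0.1)
})

test_that("perturbing a set with no measured members is rejected", {
  gs <- GeneSetList(list(real = c("gene0001", "gene0002"),
                         phantom = c("other1", "other2")))
  cfg <- simConfig(nGenes = 10, geneSets = gs,
                   perturbedSets = c(phantom = 1), seed = 1)
  expect_error(simulateTwoColor(cfg), "no members")
  expect_error(simConfig(nGenes = 10, geneSets = gs,
                         perturbedSets = c(absent = 1)), "not in geneSets")
})

test_that("within-set noise correlation approaches the configured rho", {
  cfg <- simConfig(nGenes = 100, nPerGroup = 150,
                   geneSets = makeGeneSets(100, setSize = 50, nSets = 2),
                   perturbedSets = stats::setNames(numeric(0), character(0)),
                   dyeBias = c(0, 0, 0), aNoiseSD = 0, rhoWithinSet = 0.4,
                   seed = 8)
  sim <- simulateTwoColor(cfg)
  m <- log2(SummarizedExperiment::assay(sim$experiment, "red") /
            SummarizedExperiment::assay(sim$experiment, "green"))
  members <- geneSets(cfg@geneSets)[["pathway01"]]
  cors <- cor(t(m[members[1:20], ]))
  est <- mean(cors[upper.tri(cors)])
  se <- sd(cors[upper.tri(cors)]) / sqrt(sum(upper.tri(cors)))
  # correlations share samples, so allow the SE bound some slack
  expect_lt(abs(est - 0.4), max(3 * se, 0.05))
})

test_that("single-channel arrays carry calibrated controls and replicates", {
  cfg <- simConfig(nGenes = 60, nReplicates = 1, seed = 9)
  sim <- simulateSingleChannel(cfg)
  expect_equal(sum(negativeControls(sim$experiment)), 50)
  # k = 1: collapsing is the identity on signal probes
  collapsed <- collapseReplicates(sim$experiment)
  sig <- !negativeControls(sim$experiment)
  expect_equal(unname(SummarizedExperiment::assay(collapsed)[
                 probeTargets(sim$experiment)[sig], ]),
               unname(SummarizedExperiment::assay(sim$experiment)[sig, ]))
  # fixed seed reproducibility
  sim2 <- simulateSingleChannel(cfg)
  expect_identical(SummarizedExperiment::assay(sim$experiment),
                   SummarizedExperiment::assay(sim2$experiment))
  expect_error(simulateSingleChannel(simConfig(nNegativeControls = 2)),
               "at least 3")
})

test_that("at zero margin the present-call rate matches the filter's FPR", {
  # signal probes drawn from the background law itself
  cfg <- simConfig(nGenes = 2000, nPerGroup = 2, nReplicates = 1,
                   signalMargin = 0, targetSpread = 0,
                   perturbedSets = stats::setNames(numeric(0), character(0)),
                   nNegativeControls = 200, seed = 10)
  sim <- simulateSingleChannel(cfg)
  calls <- presentCall(sim$experiment, trim = 0)
  # empirical FPR of the 3-SD rule on the same background distribution
  withr::with_seed(11, {
    bg <- matrix(2^rnorm(2000 * 50, 6, 0.5), 2000, 50)
    nc <- matrix(2^rnorm(200 * 50, 6, 0.5), 200, 50)
    fpr <- mean(vapply(1:50, function(j) {
      thr <- mean(nc[, j]) + 3 * sd(nc[, j])
      mean(bg[, j] > thr)
    }, numeric(1)))
  })
  expect_lt(abs(mean(calls) - fpr), 0.01)
})

test_that("Ct tables invert exactly without noise and center at zero under null", {
  cfg <- simConfig(ctGenes = c(GeneX = 4), ctNoiseSD = 0, seed = 12)
  sim <- simulateCtTable(cfg)
  expect_equal(ddctFoldChange(sim$ct, "GeneX")$foldChange, 4)
  # true FC = 1 everywhere: ddCt recovery centered at 0 across replicates
  dd <- vapply(1:30, function(s) {
    simN <- simulateCtTable(simConfig(ctGenes = c(GeneX = 1),
                                      ctNoiseSD = 0.3, seed = 100 + s))
    ddctFoldChange(simN$ct, "GeneX")$ddCt
  }, numeric(1))
  expect_lt(abs(mean(dd)), 3 * sd(dd) / sqrt(length(dd)))
  # determinism
  expect_identical(simulateCtTable(cfg)$ct@data, sim$ct@data)
})

test_that("null synthetic data yield uniform downstream p-values", {
  # aggregate permutation p over replicate null simulations
  ps <- unlist(lapply(1:6, function(s) {
    cfg <- simConfig(nGenes = 150, nPerGroup = 4,
                     perturbedSets = stats::setNames(numeric(0), character(0)),
                     dyeBias = c(0, 0, 0), rhoWithinSet = 0,
                     seed = 500 + s)
    sim <- simulateTwoColor(cfg)
    m <- log2(SummarizedExperiment::assay(sim$experiment, "red") /
              SummarizedExperiment::assay(sim$experiment, "green"))
    fits <- fitGeneModels(m, sim$experiment$group)
    permutationPvalues(fits, "fs", nPerm = 100, seed = s)
  }))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
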