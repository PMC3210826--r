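# Gene-wise linear models, shrinkage Fs, permutation p-values, FDR and
# fold changes.

test_that("per-gene fits agree with one-way ANOVA computed independently", {
  withr::with_seed(1, {
    y <- nullMatrix(20, 8, seed = 10)
    g <- twoGroups(4)
    fits <- fitGeneModels(y, g)
    for (i in 1:20) {
      a <- anova(lm(y[i, ] ~ g))
      expect_equal(unname(fits@msTreat[i]), a$`Sum Sq`[1])
      expect_equal(unname(fits@residMS[i]), a$`Mean Sq`[2])
      expect_equal(unname(fits@df[i]), a$Df[2])
      expect_equal(unname(fits@lsMeans[i, ]),
                   as.numeric(tapply(y[i, ], g, mean)))
    }
  })
})

test_that("degenerate fits behave at the boundaries", {
  g <- twoGroups(2)
  # identical values everywhere: no treatment signal, Fs defined as zero
  y <- matrix(5, 3, 4)
  fits <- fitGeneModels(y, g)
  expect_equal(unname(fits@msTreat), rep(0, 3))
  expect_error(fsStatistic(fits), "degenerate")
  # {0,0} vs {1,1}: exact unit effect, zero residual
  y2 <- rbind(c(0, 0, 1, 1), c(1, 2, 3, 4))
  fits2 <- fitGeneModels(y2, g)
  expect_equal(unname(fits2@lsMeans[1, "treated"] -
                      fits2@lsMeans[1, "control"]), 1)
  expect_equal(unname(fits2@residMS[1]), 0)
})

test_that("Fs reduces to the ordinary F with one gene or equal variances", {
  g <- twoGroups(4)
  y1 <- nullMatrix(1, 8, seed = 2)
  f1 <- fitGeneModels(y1, g)
  expect_equal(unname(fsStatistic(f1)), unname(f1@msTreat / f1@residMS))

  # identical residual patterns across genes -> identical residual variances
  withr::with_seed(3, {
    e <- rnorm(8)
    mu <- rnorm(50)
    y <- outer(mu, rep(1, 8)) + matrix(e, 50, 8, byrow = TRUE)
  })
  fits <- fitGeneModels(y, g)
  expect_lt(max(abs(fits@residMS - fits@residMS[1])), 1e-12)
  expect_equal(unname(fsStatistic(fits)),
               unname(fits@msTreat / fits@residMS), tolerance = 1e-10)
})

test_that("shrinkage contracts the spread of variance estimates", {
  withr::with_seed(4, {
    G <- 400; g <- twoGroups(4)
    sigma2 <- 4 * 0.04 / rchisq(G, 4)
    y <- matrix(rnorm(G * 8, sd = sqrt(sigma2)), G, 8)
  })
  fits <- fitGeneModels(y, g)
  shr <- shrinkVariances(fits@residMS, fits@df)
  expect_lt(var(shr), var(fits@residMS))
  expect_gt(cor(shr, fits@residMS), 0)       # shrinkage, not replacement
})

test_that("permutation p attains the add-one minimum for a separated gene", {
  withr::with_seed(5, {
    y <- nullMatrix(20, 16, seed = 6, sd = 0.2)
    y[1, ] <- c(rep(0, 8), rep(8, 8)) + rnorm(16, sd = 0.01)
  })
  fits <- fitGeneModels(y, twoGroups(8))
  p <- permutationPvalues(fits, "fs", nPerm = 200, seed = 7)
  expect_equal(p[1], 1 / 201)
  # fixed seed reproducibility
  expect_identical(p, permutationPvalues(fits, "fs", nPerm = 200, seed = 7))
  expect_error(permutationPvalues(fits, nPerm = 50), "at least 100")
})

test_that("null permutation p-values are approximately uniform", {
  y <- nullMatrix(400, 16, seed = 8)
  fits <- fitGeneModels(y, twoGroups(8))
  p <- permutationPvalues(fits, "fs", nPerm = 200, seed = 9)
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
  expect_gt(mean(p < 0.05), 0.02); expect_lt(mean(p < 0.05), 0.09)
})

test_that("BH adjustment matches the hand-worked step-up and the oracle", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(fdrAdjust(rep(1, 5)), rep(1, 5))
  # brute-force double-loop definition: q_i = min over p_j >= p_i of m p_j / rank_j
  bhOracle <- function(p) {
    m <- length(p); o <- order(p); ps <- p[o]; q <- numeric(m)
    for (i in seq_len(m)) {
      best <- 1
      for (j in i:m) best <- min(best, m * ps[j] / j)
      q[o[i]] <- best
    }
    q
  }
  withr::with_seed(10, {
    for (r in 1:25) {
      p <- runif(40)
      expect_equal(fdrAdjust(p), bhOracle(p))
    }
    # invariance to input ordering
    p <- runif(60)
    perm <- sample(60)
    expect_equal(fdrAdjust(p)[perm], fdrAdjust(p[perm]))
  })
  expect_error(fdrAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fold changes follow the signed least-square-mean convention", {
  g <- twoGroups(2)
  fits <- fitGeneModels(rbind(c(1, 1, 1, 1),      # equal means -> +1
                              c(2, 2, 1, 1),      # log2 diff -1 -> -2
                              c(0, 0, 1.5, 1.5)), g)
  expect_equal(foldChangeLsmeans(fits), c(1, -2, 2^1.5))
  withr::with_seed(11, {
    y <- nullMatrix(30, 6, seed = 12)
    fits <- fitGeneModels(y, twoGroups(3))
    d <- rowMeans(y[, 4:6]) - rowMeans(y[, 1:3])
    expect_equal(foldChangeLsmeans(fits),
                 unname(ifelse(2^d >= 1, 2^d, -2^(-d))))
  })
})

test_that("F1 equals the squared pooled t test with identical p-values", {
  withr::with_seed(13, {
    y <- nullMatrix(25, 10, seed = 14)
    g <- twoGroups(5)
    res <- deTable(f1Test(y, g))
    for (i in 1:25) {
      tt <- t.test(y[i, g == "treated"], y[i, g == "control"],
                   var.equal = TRUE)
      expect_equal(res$statistic[i], unname(tt$statistic)^2)
      expect_equal(res$pvalue[i], tt$p.value)
    }
  })
  # identical groups -> p = 1
  y0 <- matrix(rep(c(1, 2, 1, 2), 2), 2, 4, byrow = TRUE)
  expect_equal(deTable(f1Test(y0, twoGroups(2)))$pvalue, c(1, 1))
})

test_that("null F1 p-values are approximately uniform", {
  y <- nullMatrix(600, 12, seed = 15)
  p <- deTable(f1Test(y, twoGroups(6)))$pvalue
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("the estimated log2 effect is unbiased on synthetic data", {
  # independent noise so the naive SE of the mean bias is valid
  cfg <- simConfig(nGenes = 400, perturbedSets = c(pathway01 = 1),
                   dyeBias = c(0, 0, 0), rhoWithinSet = 0, seed = 16)
  sim <- simulateTwoColor(cfg)
  m <- log2(SummarizedExperiment::assay(sim$experiment, "red") /
            SummarizedExperiment::assay(sim$experiment, "green"))
  fits <- fitGeneModels(m, sim$experiment$group)
  est <- fits@lsMeans[, "treated"] - fits@lsMeans[, "control"]
  truth <- rep(0, 400); names(truth) <- rownames(m)
  truth[names(trueEffects(sim$truth))] <- trueEffects(sim$truth)
  bias <- est - truth
  se <- sd(bias) / sqrt(length(bias))
  expect_lt(abs(mean(bias)), 3 * se)
})

test_that("DEResult accessors and validity hold on a full run", {
  sim <- simulateTwoColor(simConfig(nGenes = 150, seed = 17))
  norm <- lowessNormalize(sim$experiment)
  de <- runDE(norm, nPerm = 100, seed = 18)
  tab <- deTable(de)
  expect_true(all(tab$fdr >= tab$pvalue - 1e-12))
  expect_true(all(abs(tab$foldChange) >= 1))
  expect_true(all(significantGenes(de, alpha = 1.1) == tab$gene))
})
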