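# Shared fixtures built in code.

# Gaussian null matrix with named rows/columns.
nullMatrix <- function(G, S, seed = 1, sd = 1, mean = 0) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(G * S, mean, sd), G, S,
                dimnames = list(sprintf("gene%04d", seq_len(G)),
                                sprintf("s%02d", seq_len(S))))
    m
  })
}

twoGroups <- function(nPerGroup) {
  factor(rep(c("control", "treated"), each = nPerGroup),
         levels = c("control", "treated"))
}

# Tiny Ct table: one target gene, one housekeeping gene, explicit values.
smallCtTable <- function(target, hk, groups, housekeeping = "Hprt",
                         gene = "Tnf", efficiency = 2) {
  n <- length(target)
  d <- data.frame(
    sample = rep(sprintf("s%02d", seq_len(n)), 2),
    group = rep(groups, 2),
    gene = rep(c(gene, housekeeping), each = n),
    ct = c(target, hk),
    replicate = 1L)
  CtTable(d, housekeeping = housekeeping, efficiency = efficiency)
}

# A noiseless two-color config (dye bias only).
noiselessConfig <- function(nGenes = 800, seed = 1,
                            dyeBias = c(0.3, 0.1, -0.05)) {
  simConfig(nGenes = nGenes, seed = seed, dyeBias = dyeBias,
            varScale = 0, aNoiseSD = 0, fracDeGenes = 0,
            perturbedSets = stats::setNames(numeric(0), character(0)))
}
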