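---
title: "Statistical methods in toxarray"
author: "toxarray authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Statistical methods in toxarray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxarray)
```

# Scope

`toxarray` implements the statistical chain used in inhalation
toxicogenomics studies of pulmonary gene expression: normalization of
two-color reference-design and single-channel arrays, gene-wise
differential expression with a shrinkage F statistic and
residual-shuffling permutation inference, two correlation-tolerant
gene-set enrichment tests, comparative-Ct qPCR quantification with a
randomization test, and deposited-dose arithmetic. A synthetic-data
generator with known ground truth backs every stage, so the package's
operating characteristics (type-I error, power, bias) are verified by
simulation in its own test suite.

# The synthetic experiment

The generator emulates a two-group (control vs treated) common-reference
two-color design: every experimental sample is labeled in the red channel
(Cy5) and co-hybridized against one universal reference in the green
channel (Cy3), so treatment contrasts live on the log-ratio scale
`M = log2(red/green)`.

Per gene `g` and array `s` the model is

* mean log2 intensity `A_gs = a_g + jitter`, `a_g ~ N(10, 1.5^2)` —
  typical of the usable intensity range of long-oligo arrays;
* log-ratio `M_gs = effect_g 1[treated] + bias(A_gs) + e_gs`;
* channels reconstructed as `red = 2^(A + M/2)`, `green = 2^(A - M/2)`.

Three features deliberately break the assumptions naive methods make:

* **Heteroscedastic gene variances.** `sigma^2_g = nu s0^2 / chisq(nu)`
  (scaled inverse-chi-square), a right-skewed law that mimics the spread
  of gene-wise residual variances in array data. Defaults `nu = 4`,
  `s0^2 = 0.04` put the typical residual SD near 0.2 on the log2 scale.
  This is exactly the regime in which shrinking the F denominator is
  worthwhile.
* **Within-pathway correlation.** Genes of a set share a per-sample
  latent factor: `e_gs = sigma_g (sqrt(rho) z_s + sqrt(1 - rho) eps_gs)`,
  giving exchangeable (equi-)correlation `rho` within the set, default
  0.3. This is the simplest structure that invalidates
  independence-assuming set tests, which is precisely what the two
  implemented tests claim to tolerate.
* **Intensity-dependent dye bias.** An additive quadratic trend
  `bias(A) = b0 + b1 (A - 10) + b2 (A - 10)^2` with default
  `c(0.3, 0.1, -0.05)` — a smoothly curved bias of roughly one log2 unit
  of amplitude over the observed intensity range, the classic signature
  LOWESS normalization exists to remove. In the noiseless limit the bias
  is the only component of M, so normalization can be checked as an
  exact round trip.

Treatment effects enter as a shift `delta` (log2 units) on the members of
chosen sets in the treated group, plus optionally a fraction of
independent DE genes with random sign. Study-scale defaults are 1000
genes, 8 samples per group, and ten disjoint 50-gene pathways with one
pathway shifted by `delta = 2`.

The single-channel generator adds background-only negative-control probes
(`N(6, 0.5^2)` on the log2 scale), signal probes a configurable margin
above background, and `k` technical-replicate probes per target. The Ct
generator writes `Ct = baseline_g - log2(expression) + noise` with
per-sample loading offsets that the housekeeping normalization must
remove, and housekeeping genes with zero treatment effect.

What the generator does *not* emulate — and what passing tests therefore
do not establish for real data — includes spatial/print-tip artifacts,
scanner saturation, probe-sequence effects, outlier arrays beyond simple
noise replacement, non-Gaussian heavy-tailed noise, and realistic
pathway overlap (generated sets are disjoint). All randomness flows from
one integer seed through `withr::with_seed`, so nothing touches the
global RNG state and every output is reproducible bit for bit.

# Normalization

**LOWESS (two-color).** Per array, `M` is regressed on `A` with
`stats::lowess` and the fit subtracted: `M' = M - fhat(A)`. The span
defaults to 0.4 with 3 robustifying iterations — a common choice for MA
normalization that follows curvature of the usual magnitude without
chasing noise; both are exposed as arguments. Probes non-positive in
either channel have no defined log-ratio: they are excluded from the
smoothing but *retained as missing* in the output, with per-array counts
recorded in the metadata, so no rows silently disappear. The test suite
verifies that a noiseless injected dye-bias curve is removed to below 1%
of its amplitude on the interior (10th–90th percentile) of the intensity
range; at the extreme tails a local smoother is necessarily less
accurate, which is why the contract is stated for the interior.

**Quantile normalization (single-channel).** Delegated to
`limma::normalizeQuantiles` (the sorted-column-mean algorithm, ties
averaged). It is checked against a hand-computed example and for
idempotence and rank preservation.

**Present calls.** Per array, the detection threshold is
`trimmed mean + 3 x trimmed SD` of the negative-control signals, and a
probe is present iff its signal strictly exceeds the threshold. The trim
fraction is not standardized in vendor pipelines; the default trims 5%
from each tail — enough to neutralize an occasional wild control without
discarding most of them — and is exposed as an argument. With Gaussian
background the 3-SD rule implies a false-positive rate near
`pnorm(-3) ~ 0.13%`; the suite verifies the empirical rate on
background-distributed probes matches the rule's own tail mass.

**Replicate collapsing and QC.** Technical replicate probes are
summarized by the per-sample median. Array-level QC flags arrays whose
median Spearman correlation to the others falls below a threshold
(default 0.5); flags are advisory and nothing is excluded
automatically — exclusions belong to the caller and are recorded in the
pipeline run log.

# Differential expression

For a two-group comparison on normalized log-ratios the package uses the
per-gene one-way decomposition: least-square group means, treatment mean
square (1 df) and residual mean square with `n - 2` df. In a
common-reference design with one sample per array, array effects are
confounded with samples, so the full mixed model reduces to exactly this
contrast; the package implements the reduced model deliberately.

**Shrinkage Fs.** The Fs statistic divides each gene's treatment mean
square by a cross-gene *shrunk* variance. Shrinkage is
James–Stein–Lindley on the log-variance scale: with `X_g = log(s2_g)`,

```
Xtilde_g = Xbar + max(0, min(1, 1 - (G - 3) trigamma(df/2) / sum((X - Xbar)^2))) (X_g - Xbar)
sigma2tilde_g = exp(Xtilde_g)
```

`trigamma(df/2)` is the sampling variance of a log chi-square variance
estimate, so the factor compares observed spread to pure noise: when the
gene variances are genuinely equal the estimator collapses every gene to
the common center, and when they differ widely it leaves them nearly
untouched. Two design choices matter:

* The multiplicative bias-correction constant sometimes attached to
  exponentiated log-variance estimators is omitted. It is identical for
  every gene *and for every permuted dataset*, so permutation p-values
  are exactly invariant to it; omitting it buys the clean limiting
  identity "equal variances implies Fs = ordinary F", which the suite
  checks to 1e-10.
* Genes with zero residual variance (when not all are zero) receive the
  shrinkage center; all-zero variances are degenerate data and an error.

**Permutation p-values.** Significance comes from residual shuffling:
residuals from the *null* (grand-mean) fit are permuted as whole sample
columns — preserving the gene–gene correlation structure — the null data
rebuilt, and the statistic (including re-shrinkage) recomputed. P-values
use the add-one estimator `p = (1 + #[perm >= obs]) / (nPerm + 1)`,
which can never be exactly zero; ties count as exceedances
(conservative). The null is gene-specific by default; a pooled mode
(compare each gene to the pooled permutation distribution) is available
for stability at small permutation counts.

**FDR and fold changes.** Multiplicity is handled by Benjamini–Hochberg
step-up (`stats::p.adjust`), verified in the suite against a brute-force
transcription of the step-up definition. Fold changes come from the
least-square means, `FC = 2^(LSmean_treated - LSmean_control)`, reported
with the signed convention (values below 1 as `-1/FC`, so `|FC| >= 1`
always and sign encodes direction). The default significance rule is
adjusted p < 0.05.

**F1 test.** For single-channel data the gene-specific parametric route
is the ordinary one-way F with p from `F(1, n - 2)` — identically the
squared pooled t test — followed by BH. With one array per sample a
per-sample random effect is not separable from the residual, so the
package implements the fixed-effects reduction and says so rather than
guessing at a richer model.

# Gene-set tests

Both tests use the Euclidean distance between two group summary vectors
restricted to a set, and both obtain their null by resampling whole
samples, so no assumption about gene–gene independence is needed — the
property the synthetic equicorrelated nulls exercise.

**Rank-based test.** Within each sample, all measured gene values are
converted to ranks (average for ties); the statistic is the distance
between the two groups' mean-rank vectors over the set, and the null
comes from permuting sample-to-group labels. Ranking over *all* measured
genes (not only set members) is the default scope, so the magnitude of a
gene's intensity relative to the rest of the array matters;
`rankScope = "within-set"` is available for sensitivity analysis. Because
ranks are invariant to any strictly monotone per-sample transform, the
test is unaffected by scale or calibration differences between samples.
One caveat of global ranking is compensation: a very strong shift in one
set slightly displaces the ranks of all other genes, so other sets can
acquire weak secondary signal.

**Design-based test.** The statistic is the distance between the two
group mean vectors. The null removes the treatment effect (each gene
centered on its grand mean) and resamples whole sample-columns of the
full-model residuals with replacement, reassigning them to groups at the
original sizes. Residual columns are rescaled by `sqrt(n_k / (n_k - 1))`
before resampling: group-mean residuals carry only `(n_k - 1)/n_k` of the
noise variance, and without the rescaling the bootstrap null is too
narrow and the test anticonservative (about 9% rejection at nominal 5%
with 4 samples per group in our simulations; nominal after the fix). A
per-gene resampling mode exists for comparison but breaks the
correlation preservation and is not the default.

**Enrichment report.** One row per set: p-value(s) and distance(s),
`total` = measured probes in the set, `changing` = set probes with
adjusted p below the DE threshold. Raw p-values are reported (one row
per pathway, as such tables are conventionally printed); optional BH
columns are available. Rows sort by p ascending with ties — unavoidable
given the `1/(n + 1)` granularity of resampling p-values — broken by the
larger observed distance. Sets with no measured members are excluded
with a warning.

# qPCR quantification

Technical replicates of a well are averaged first. Per sample,
`deltaCt = Ct_gene - mean(Ct_housekeeping)` — the arithmetic mean over
housekeeping genes, equivalent to a geometric mean of their expression.
Then `ddCt = mean_treated(deltaCt) - mean_control(deltaCt)` and
`FC = E^(-ddCt)` with amplification efficiency `E = 2` by default
(perfect doubling); per-gene efficiencies are accepted as input.
Samples missing a housekeeping well are dropped with a warning.

Significance uses a REST-style randomization test: samples are
reallocated between the group labels (sizes fixed), the log ratio
recomputed, and the two-sided p-value is the add-one exceedance
frequency of `|log ratio|`. A pooled-variance two-sample t test on the
per-sample `deltaCt` values is provided for validation assays, with the
zero-variance limits handled explicitly (p = 1 for identical groups,
p = 0 for an exact separation).

# Dosimetry

Pure, unit-checked arithmetic: cumulative inhaled mass
(`days x hr/day x mg/m^3 x m^3/hr`), regional deposited mass from
user-supplied deposition fractions (with the undeposited remainder
returned so mass is conserved exactly), tissue dose (`ug` deposited over
`mg` organ mass, reported in mg/kg), surface-area dose (`ug x m^2/g` in
cm^2), and retention percent. Deposition fractions are *inputs*: they
come from an external deposition model, and
`inst/extdata/deposition_fractions_example.tsv` ships an example set
derived from published deposited-mass figures (72.5, 48, 356 and 267 ug
out of an 840 ug inhaled total). Reported precision follows convention:
3 decimals for mg, nearest integer for mg/kg and percent. Two
documented arithmetic notes: a regimen of 11 days x 1 hr at the measured
42.4 mg/m^3 and 0.0018 m^3/hr gives 0.840 mg (a nominal 40 mg/m^3 does
not reproduce that product), and 72.5 ug x 107.7 m^2/g is 78.08 cm^2 —
the package always reports the exact product of its inputs.

# Numerical and engineering choices

* Sizes used by the verification suite: the operating-characteristic
  checks run 500 null datasets and 200 power datasets of 1000 genes x 16
  arrays with 500 resamples each; smaller unit fixtures cover the exact
  contracts. These sizes give binomial 99% CIs of about +/- 2.5
  percentage points around a 5% rejection rate, tight enough to detect
  the size distortions that matter.
* Add-one p-values everywhere (never exactly zero); ties counted as
  exceedances.
* `fitGeneModels` tolerates missing cells (probes dropped per-array by
  normalization): means, sums of squares and df are computed over the
  observed cells, and genes with fewer than 1 residual df report missing
  statistics.
* Degenerate inputs have defined limits: zero treatment mean square
  gives statistic 0 / p 1; zero residual with nonzero effect gives an
  infinite F / p 0; all-zero variances error.
* The pipeline writes every table through a fixed-precision formatter,
  so identical configurations produce byte-identical tables; the run log
  carries timestamps, seeds, parameter values and filter counts
  (rows in/out/dropped) for every stage.

# Limitations

Two treatment groups only; no dye-swap designs; no mixed models (the
reference design makes them unidentifiable here); no background
subtraction; gene identifiers are matched exactly (annotation aliasing
is out of scope); and the generator's disjoint equicorrelated sets are a
deliberately simple stand-in for real pathway structure. The gene-set
tests report raw per-set p-values by default, matching how such tables
are conventionally presented — use the optional BH columns when many
sets are screened.
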