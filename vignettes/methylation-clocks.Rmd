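---
title: "Cross-species methylation clocks and aging EWAS: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species methylation clocks and aging EWAS: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

DNA methylation drifts with age in a sufficiently reproducible way that a
sparse linear model over CpG beta values — an *epigenetic clock* — can
predict chronological age. Clocks built on a conserved-sequence mammalian
methylation array can in principle be shared across species, but species
lifespans differ enormously (a laboratory opossum's recorded maximum is
4.2 years against 122.5 for humans, a ~29-fold ratio), so the *scale* on
which age is modeled becomes a first-class design decision. This package
implements the full desk-scale workflow around that question:

* elastic-net clocks on three target scales (chronological years,
  relative age, piecewise log-linear age), evaluated by leave-one-sample-
  out cross-validation (LOOCV);
* an epigenome-wide association screen (EWAS) of age, with Fisher z
  effect statistics, Stouffer meta-analysis across tissues, top-CpG
  selection, cross-stratum sector classification, and annotation
  enrichment tests;
* sample-integrity QC (clustering purity, out-of-bag classification);
* a synthetic data generator with known ground truth that makes every
  stage testable without access to consortium data.

# Age transforms

`relative_age(a, L) = a / L` rescales age by the species maximum
lifespan, mapping every species onto a nominal [0, 1] interval. Values
above 1 (an animal outliving the recorded maximum) are legal and returned
unclamped with a warning — clamping would bias median-error statistics.

The chronological dual-species clock instead uses a piecewise
log-linear transform around the species' age at sexual maturity `m`
(`loglinear_forward`):

$$y(a) = \begin{cases}\log\frac{a+k}{m+k} & a < m\\[2pt]
\frac{a-m}{m+k} & a \ge m\end{cases}$$

logarithmic through the fast developmental phase, linear in adulthood,
continuous with value 0 at the knot. The offset `k` (default 1 year)
keeps the logarithm finite at age 0. This is the standard invertible
form of a "log-linear" age transform; its exact published parameterization
varies between studies, so both `m` (per species, from the sample sheet)
and `k` are configurable. `loglinear_inverse` is the exact inverse,
floored at age 0. Both transforms are strictly increasing, which
prediction requires.

# The clock model

`fit_clock` regresses transformed age on beta values with the elastic
net at mixing parameter $\alpha = 0.5$ — the conventional midpoint
between ridge and lasso for methylation clocks, deliberately not tuned.
Fitting is delegated to `glmnet::cv.glmnet`:

* penalty grid: 100 log-spaced values from $\lambda_{max}$ down to
  $10^{-4}\lambda_{max}$;
* $\lambda$ chosen by the 10-fold cross-validation minimum (not the
  1-SE rule), which maximizes accuracy at desk scale; ties resolve to
  the larger, sparser $\lambda$;
* folds are contiguous blocks of a seeded uniform shuffle, so every fit
  is exactly reproducible; inside LOOCV the folds are re-drawn for each
  left-out sample;
* predictors are standardized internally; coefficients are reported on
  the beta scale;
* convergence threshold $10^{-5}$ — looser than glmnet's default
  $10^{-7}$, indistinguishable in the fitted clocks at these problem
  sizes and substantially faster across the thousands of fits an LOOCV
  study performs.

Probes with any missing training value are dropped from that fit
(simple and leakage-proof, versus imputation), as are zero-variance
probes; at prediction time a sample missing a model probe's value is
flagged `NA` rather than silently imputed.

`loocv_evaluate` runs one complete `fit_clock` per held-out sample —
including the internal penalty search — so no information from the
held-out sample can leak into its prediction. Accuracy is summarized as
the Pearson correlation R between predicted and actual age and the
median absolute error, on the target's natural units (relative age for
the relative transform, otherwise years). A zero-variance prediction
vector yields `r = 0` with a degenerate-fit flag instead of an error.

One property of this evaluation deserves emphasis: **under the null,
LOOCV Pearson r is negatively biased, not centered at zero.** Each
held-out prediction embeds the leave-one-out training mean
$\bar y_{-i}$, which is perfectly anti-correlated with the held-out
label (an intercept-only clock evaluated by LOOCV gives r = −1
*identically*), and partially-penalized fits inherit the same bias:
the chance correlation between a signal-free target and the dominant
shared factor among probes is estimated *excluding* sample i, coupling
the prediction negatively to $y_i$. On permuted-age or signal-free
simulations we observe per-seed LOOCV r between roughly −1 and +0.05
with a mean near −0.4. This is an artifact of the evaluation under the
null — not information leakage, which would bias r upward — and it
vanishes as soon as real signal dominates (the strong-signal designs
in the test suite recover r > 0.98). Null experiments on LOOCV output
should therefore test for *absence of positive* correlation, not for
r ≈ 0.

A dual-species clock is simply `fit_clock` on the pooled samples of the
probes mappable in all species involved (`pool_datasets` /
`subset_mappable_probes`, intersection semantics), with the target
scale carrying the species differences: relative age divides by each
species' own lifespan, the log-linear transform uses each species' own
maturity. This is why the single-species case reduces exactly to
`fit_clock`.

# EWAS and meta-analysis

`correlation_screen` computes, per probe, the pairwise-complete Pearson
correlation $r$ of beta with age, the Student-t p-value on $n-2$
degrees of freedom ($t = r\sqrt{n-2}/\sqrt{1-r^2}$; a normal-
approximation option exists), and the Fisher z statistic
$z = \mathrm{atanh}(r)\sqrt{n-3}$, with $r$ clipped to
$|r| \le 1-10^{-12}$ so z stays finite for perfect correlations. Probes
with fewer than 4 complete pairs or zero variance are invalid
(`r = 0, p = 1`), never errors. BH-FDR and Bonferroni columns are
always emitted beside the nominal p.

`stouffer_meta` combines strata as
$z_{meta} = \sum_i w_i z_i / \sqrt{\sum_i w_i^2}$ with default weights
$w_i = \sqrt{n_i}$ (per-probe sample counts; unweighted available).
Probes invalid in a stratum contribute nothing there and the weights
renormalize over contributing strata, so a probe measured in two of
three tissues is still meta-analyzed over those two.

`select_top_cpgs` implements "up to k CpGs per direction": among probes
below the p threshold, the k most significant with positive z and the k
most significant with negative z, ordered by ascending p with ties
broken by descending |z| then probe id. `sector_classify` reproduces
the sector-plot logic with two normal-quantile thresholds (strict,
e.g., $p < 10^{-4}$ within species or $p < 0.005$ on conserved-probe
cross-species runs; lenient $p > 0.05$): shared up/down, divergent,
significant-in-one-only, null.

# Enrichment statistics

Three related tests serve different annotation questions:

* `island_shift_test` — pooled-variance two-sample t of the Fisher z
  statistics, island vs non-island probes: is there a *systematic*
  island-wide shift of aging effects?
* `feature_fisher_enrichment` — per-category 2×2 Fisher exact test
  (two-sided p as the classic sum over margin-fixed tables with
  probability at most the observed table's; the figure-star convention
  0.05/0.01/0.001/0.0001), with the sample cross-product odds ratio
  (`Inf` flagged on zero cells, not an error).
* `hypergeom_state_enrichment` — one-sided hypergeometric tail
  $P(X \ge k)$ per chromatin state or flag, with the depletion tail
  reported alongside.

The background for every enrichment is the probe universe the top set
was selected from — the array-conditioned background that removes the
probe-design bias. `gene_set_enrichment` maps each probe to its single
annotated gene and runs the hypergeometric test over the background
gene universe with a 10–3000 gene-set size filter. This is a
deliberately simpler surrogate for region-based regulatory-domain
tools (no basal-plus-extension domains, no binomial-over-regions test);
that fidelity gap is intentional and documented here.

# The synthetic data generator

`simulate_dataset` emulates the structure the analyses rely on, not the
sequence content of a real array. For sample $i$, probe $j$:

$$\mu_{ij} = \mathrm{logit}^{-1}\!\big(b_{0j}(sp_i, tis_i) + s_j\,
g(a_i)\big),\qquad \beta_{ij} \sim \mathrm{Beta}(\mu_{ij}\varphi,
(1-\mu_{ij})\varphi)$$

* $g(a) = a/L$ is relative age, so cross-species sharing of
  trajectories is exact by construction — the premise the relative-age
  clock exploits and the reason the chronological clock is handicapped
  in the short-lived species;
* baselines $b_{0j} \sim N(0, \sigma_b)$ are drawn independently per
  species × tissue ($\sigma_b$ default 1), which creates the
  species/tissue separation that the clustering and out-of-bag QC
  detect;
* a fraction `frac_age_related` (default 0.1) of probes get nonzero
  slopes with magnitude uniform in `slope_range` (default [1, 3] logit
  units per unit relative age — chosen so that a strong probe reaches
  |r| ≈ 0.9 at n = 50, a realistic figure for top aging CpGs; no
  published effect-size scale exists to copy) and Rademacher signs;
* the Beta precision $\varphi$ (default 50) puts per-probe noise SD
  near 0.05–0.07 at mid-range betas, typical of normalized array data;
* `frac_island` defaults to 0.5 — methylation arrays deliberately
  target CpG islands, so about half of probes island-flagged is the
  realistic emulation and gives the island-coupled modes a
  representative stratum size; `frac_prc2` defaults to 0.3,
  independent of island status.

The two `island_aging_mode`s encode the qualitative contrast between
placental-type and opossum-type aging methylomes. In
`placental_like`, age-related probes are drawn from all probes and
those in the island∧PRC2 stratum are forced to positive slopes —
islands and PRC2 targets gain methylation with age. In `opossum_like`,
age-related probes are drawn outside the island∧PRC2 stratum (its true
slopes are exactly zero, making the ground-truth invariant sharp) and
all signs stay symmetric, so neither the island z shift nor PRC2
enrichment should appear. Observed betas are clamped to
$[10^{-6}, 1-10^{-6}]$ because Beta draws can underflow to the boundary
at extreme means.

All draws come from one seeded generator in a fixed order (annotation,
slopes, baselines, samples, noise), so identical config + seed is
bit-identical, and `export_fixture` serializes canonically
(byte-identical re-export).

What the generator does **not** emulate: batch/chip effects, cell-
composition heterogeneity, SNP-artifact probes, realistic genomic
clustering of islands, or non-monotone age trajectories. Passing tests
therefore demonstrate correctness of the statistical machinery and
recoverability under the stated model — not performance on real
consortium data, whose headline accuracies cannot be reproduced here
because those data are not deposited with an accession.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale designs
chosen to keep a full run in minutes on one core while leaving clear
statistical margins: the default single-species dataset is 80 samples ×
2000 probes (10% age-related), mode-contrast runs are 4000 probes ×
50 samples, the dual-species design is 2 × 25 samples × 1000 conserved
probes, and the null-calibration run for the $10^{-4}$ threshold uses a
$10^5$-probe draw. Monte-Carlo claims use 10–50 seeds depending on the
sharpness of the band being checked.

Numerical conventions collected in one place: beta bound tolerance
1e-9 on read (text round-trip); read∘write identity to 1e-12; r
clipping at $1-10^{-12}$ before `atanh`; BED export is 0-based
half-open (`start = pos − 1`); annotation coordinates are 1-based
inclusive; glmnet convergence threshold 1e-5; equal-CV-error $\lambda$
ties toward the sparser model; degenerate Pearson correlations report 0
with a flag.

# Species constants

The shipped `species_constants.tsv` records maximum lifespans of 4.2
(opossum) and 122.5 (human) years, the anAge-style constants whose
ratio rounds to 29. Ages at sexual maturity (0.5 y opossum, 13.5 y
human) are standard colony/anAge values; they only enter the log-linear
transform's knot, not relative age.

# Known limitations

* The log-linear transform's published parameterization varies; ours is
  the standard continuous piecewise form with configurable `k`.
* Stouffer weights $\sqrt{n_i}$ are a convention, not a published
  choice; unweighted combination is available.
* Gene-set enrichment is gene-per-probe, not region-based.
* No covariate adjustment in the EWAS (none is used in the screening
  design this package targets), and no genomic-control inflation
  correction.
* The whole validation rests on the generator's model; see the
  generator section for what that does and does not establish.
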