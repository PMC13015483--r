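---
title: "Models and methods behind exermap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind exermap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exermap)
```

This vignette is the package's own account of its statistical content:
the models, the assumptions behind them, the tunable parameters and their
defaults, what the synthetic-data generators do and do not emulate, and
the places where the design was genuinely open and a choice had to be
made.

## The design and the difference-in-changes model

The design is a three-arm randomized acute-exercise study — endurance
(EE), resistance (RE), and non-exercising control (CON) — in which every
participant contributes a pre-exercise sample plus exactly one
post-exercise sample, the post timepoint (45 min, 4 hr, or 24 hr) being
fixed by a randomized *temporal profile*. Two consequences drive all the
modelling:

1. **Repeated measures.** Each participant appears twice, so observations
   are correlated within participant. `fit_feature()` fits a cell-means
   fixed-effect structure (one mean per group × timepoint cell, plus age,
   sex, BMI and clinical site) with a participant random intercept, by
   REML with the variance ratio profiled out. Satterthwaite denominator
   degrees of freedom are computed analytically from the gradient of the
   contrast variance in (σ²ₑ, σ²ᵤ) and the inverse REML information.
   The fitter is a compact specialized implementation (the per-cluster
   covariance is inverted with Sherman–Morrison), which is what makes
   per-feature fits over thousands of features and 20,000-replicate
   simulations practical; it is validated against lme4/lmerTest in the
   test suite (estimates and SEs agree to 1e-5; variance components to
   1e-3; the degrees of freedom differ slightly because the package uses
   the expected rather than observed information, shifting p-values by
   under 2% in the checked cases).

2. **A control arm for time itself.** Adipose tissue changes over a day
   without any exercise, so the primary contrast is the
   *difference-in-changes* Δ = (post − pre)ₑₓ − (post − pre)_CON. A
   group-specific contrast (post − pre within one arm) and a modality
   contrast (EE change − RE change) complete the three families. Sign
   conventions are post minus pre, exercise minus control, EE minus RE,
   male minus female.

Testability requires at least 3 participants with both members of the
pre/post pair observed, in *every* group the contrast involves
(`min_pairs_filter()`). Boundary fits with the random-intercept variance
at zero are flagged and reduce to (weighted) ordinary least squares with
residual degrees of freedom. p-values are BH-adjusted within each
(family, group, ome, timepoint) stratum, so each stratum controls its own
FDR at 0.05.

For count data, `estimate_precision_weights()` reproduces the standard
log-CPM mean–variance-trend procedure (0.5-count offset, lowess of the
square-root residual SD against average log count, weights equal to the
inverse fourth power of the interpolated trend at each observation's
fitted log count). Empirical-Bayes variance moderation is deliberately
not applied by default; the simulation harness exists precisely to
quantify what each modelling layer buys.

## The simulation harness

`evaluate_strategies()` answers "which longitudinal analysis should be
primary?" by Monte-Carlo. Data are drawn from a generative model matched
to the study's awkward features:

- **Non-normal marginals.** `rnonnorm()` implements the third-order
  polynomial (Fleishman) transform of a Gaussian copula, with the
  Vale–Maurelli intermediate-correlation solution, so mean, covariance,
  skewness and excess kurtosis are all matched. Infeasible
  skewness/kurtosis pairs (outside the polynomial family's region,
  roughly kurtosis ≥ 1.13·skew² − 1.43) raise an error naming the bound.
  Convergence of sample moments is tested at n = 50,000.
- **Profile missingness.** Three occasions are generated per participant
  (pre + two post "timepoint-equivalents"); each participant keeps pre
  plus one post, split evenly within group — the structure the temporal
  profiles impose.
- **Default configuration** (the adipose-like conditions, chosen once):
  group sizes CON/EE/RE = 12/21/24 (the study's 37/63/73 scaled to desk
  size), within-participant correlation 0.5, marginal skewness 1, excess
  kurtosis 3, α = 0.05, and the difference-in-changes contrast for EE at
  the first post occasion. Headline runs use 20,000 replicates (about a
  minute per strategy pair on one CPU); the vignette-scale defaults in
  the tests use 1,200–2,000.

Six strategies are implemented: paired t, OLS ignoring the clustering,
the random-intercept mixed model with and without precision weights
(identical when the data carry no count structure), a moment-based GLS
with unstructured occasion covariance, and a Gaussian GEE with AR(1)
working correlation and cluster-robust sandwich errors (Wald z, the
convention of standard GEE software; the AR(1) parameter is estimated by
least squares on the standardized residual cross-products over all
within-cluster pairs, iterated to convergence — behaviour validated
against an established GEE implementation on identical replicates).
No GEE package ships with this environment's R stack, so the GEE is
implemented in the package; the two-observation-cluster case it needs is
small enough to write exactly.

Two properties anchor the harness: the paired t and the random-intercept
model coincide algebraically on complete two-timepoint single-group data
(checked to 1e-6), and every correctly specified strategy attains its
nominal level within Monte-Carlo tolerance. On the default configuration
the mixed model holds ~5% while the GEE sandwich test is inflated; the
inflation grows as the number of clusters shrinks (at the study's full
group sizes it is mild, near 6%; at the desk-scale sizes it reaches
~9%), which is the familiar small-sample behaviour of the uncorrected
sandwich estimator and the reason the mixed model is the primary
analysis.

## Preprocessing rules

Each rule is a small function applying one published-style convention:

- `clean_metabolites()`: duplicate-ID rows averaged → non-positive
  intensities to missing → features > 20% missing removed → imputation
  (KNN over samples with k = 10 when more than 12 features remain, half
  the per-feature minimum otherwise — the half-minimum scope and k are
  choices, stated here because the conventions leave them open) →
  log2(x + 1), which keeps intensities in (0, 1) positive on the log
  scale.
- `conditional_median_mad_normalize()`: per-sample median/MAD
  normalization is *gated* — applied only when neither sample medians nor
  upper quartiles associate with sex or sex-stratified group
  (Kruskal–Wallis p < 0.01 blocks it), so real group structure is never
  normalized away. A zero-MAD sample is centred but not rescaled.
- `flag_pc_outliers()`: boxplot whiskers extended to 5× IQR on every
  principal component explaining ≥ 1% of variance (the component floor is
  configurable; the conventions do not bound the PC count).
- `filter_low_expression()`: the literal reading of the low-expression
  rule ("0.5 or fewer CPM in at least 10% of samples" ⇒ remove) is the
  default; because that phrasing removes nearly everything on deeply
  sampled designs, the conventional reading (keep genes exceeding 0.5 CPM
  in ≥ 10% of samples) is available as `rule = "conventional"` and is what
  `run_pipeline()` uses.
- `filter_min_quantified()`: proteomics features quantified in < 30% of
  samples are removed; exactly 30% is kept (boundary inclusive).
- `regress_technical()`: technical covariates are estimated *jointly*
  with the protected biological design and only the technical
  contribution subtracted; a technical covariate collinear with the
  design (the extraction-batch situation) is skipped with a warning
  rather than silently absorbing biology.
- TMM/log-CPM normalization is delegated to edgeR, the standard
  implementation.

## Enrichment

`camera_pr()` is the competitive pre-ranked set test: in-set minus
out-of-set mean difference on z-scores, pooled-variance t on n − 2 df
with the in-set variance inflated by VIF = 1 + (m − 1)ρ̄. The default
ρ̄ = 0.01 is the established convention; at ρ̄ = 0 the statistic is
*exactly* the classical pooled two-sample t (an oracle equivalence the
tests enforce to 1e-10), and the implementation is cross-checked against
limma's at ρ̄ = 0.01. The directional summary z.std =
sign(δ)·Φ⁻¹(1 − p/2) is derived from the two-sided p — a definitional
choice recorded here because published figures plot z.std without
defining it. Set filtering keeps sets with ≥ 5 members present and, for
gene-type collections only (pathways, cell markers, kinase sets), ≥ 70%
of original members; metabolite-class collections are exempt from the
retention rule. Significance is 0.05, raised to 0.1 for kinase
collections. `ora()` is the upper-tail hypergeometric test against the
measured universe, verified against exhaustive enumeration on universes
of up to 12 identifiers.

## Co-expression networks

`build_modules()` follows the signed weighted-network recipe: adjacency
((1 + cor)/2)^β, topological-overlap dissimilarity, average-linkage
clustering, a height-based cut, merging of modules whose eigengenes
correlate above 0.7 (a merge threshold of 0.3 read as eigengene
dissimilarity, the standard convention), eigengenes as the first
principal component sign-fixed and unit-variance, and kME as each
feature's correlation with every eigengene. Two numerical choices were
genuinely open:

- **The cut height.** A cut at the 0.99 quantile of merge heights — the
  first parametrization considered — isolates only the final singleton
  merges on block-structured data and leaves one giant cluster; the
  default is therefore the 0.90 quantile followed by a kME cleanup
  (features whose own-module kME < 0.3 are released to module 0), both
  configurable. On planted four-block data this recovers the blocks at
  adjusted Rand index ≥ 0.8 with noise predominantly unassigned.
- **Scale-free fit.** `pick_soft_power()` scores each candidate power by
  the signed R² of the log–log binned degree distribution (equal-width
  bins) and returns the smallest power reaching 0.8, flagging the case
  where none does (e.g., pure noise). Note that equicorrelated blocks
  produce a two-point connectivity distribution on which a power-law fit
  is meaningless; graded (hub-like) connectivity is required for the
  criterion to be informative, and the tests construct exactly that.

`bicor()` is the biweight midcorrelation (u = (x − med)/(9·MAD) with
unscaled MAD, weights (1 − u²)² inside |u| < 1), with a Pearson fallback
for zero-MAD margins and a t-approximation p-value on n − 2 df.
`module_trait()` z-scores traits, optionally residualizes both sides on
covariates (age, sex, waist circumference being the typical set), and
stars significance at 0.05/0.01/0.001. Networks are meant to be built on
baseline (pre-exercise) samples, as `run_pipeline()` does.

## Trajectory clustering

`stack_and_scale()` row-stacks per-ome z-score matrices over the
post-exercise timepoints and divides each row by the standard deviation
computed with two zero columns temporarily appended — the zeros represent
the pre-exercise baseline, anchoring each feature's scale to "no change"
without entering the clustering. `fuzzy_cmeans()` is the standard FCM
(Euclidean distances, alternating centroid/membership updates, random
membership initialization deterministic in the seed, duplicate centroids
re-initialized); iteration stops when the largest membership change
falls below 1e-6, the standard stopping rule, and the objective Σu^m d²
is traced and checked non-increasing. The fuzzifier defaults to the
empirical estimate m(N, D) = 1 + (1418/N + 22.05)D⁻² +
(12.33/N + 0.243)D^(−0.0406·ln N − 0.1134). Cluster number is chosen by
inspecting the scree of minimum centroid distances over c = 3–14
(`choose_c()`); there is deliberately no automatic selection, because the
published workflow made that choice manually. Hard labels assign each
feature to its maximum-membership cluster only when that membership
reaches 0.3; cluster labels are stabilized by sorting centroids
lexicographically. The Euclidean metric is an assumption (the source
package's default); it is recorded here because the original text does
not state it.

## Endocrine connectivity

`ssec()` scores each secretory origin-tissue gene by the sum of −ln p
over biweight midcorrelations against every target-tissue gene,
normalized by the target gene count — so under independence the null
mean is exactly 1 (E[−ln U] = 1), a property the tests verify within
Monte-Carlo tolerance (the bicor t-approximation leaves the realized
mean near 0.98 at 20 samples). Natural log is the implemented
definition; a base-10 switch exists and changes only the scale, never
the ranks. Correlations can be residualized on sex before scoring, which
removes planted sex-confounded connectivity in the tests. Ranks are
descending (rank 1 = broadest connectivity) and are computed among all
origin genes present. `rank_shift_test()` compares candidate ranks
between conditions by paired Wilcoxon signed-rank and paired t tests.
`gene_correlation_enrichment()` z-scores a gene's bicor vector against a
target tissue and feeds it to the same competitive set test used
everywhere else — one ranked-statistic engine serves the pathway,
cell-marker, metabolite-class, kinase and cross-tissue analyses; a
permutation-style running-sum alternative was considered and rejected to
keep a single, analytically calibrated engine.

## What the synthetic data do and do not emulate

`generate_cohort()` / `generate_omics()` plant: the pre + one-post
design with profiles; participant random intercepts (within-person
correlation 0.5 at the default ri_sd = 1); non-normal marginals
(skewness 1, excess kurtosis 3 by default); equicorrelated module
blocks; difference-in-changes effects confined to exercise-group post
samples, with temporal archetypes; sex effects on 5% of features;
count-valued transcripts produced by quantile-mapping the Gaussian
latent into negative-binomial counts (so a mean–variance trend exists
for the precision weights); and completely-at-random missingness for the
MS-based omes. A truth table records every label.

They do **not** emulate: batch structure and instrument drift, real
moment summaries of any cohort, correlated missingness beyond the
profile design, feature-specific variance heterogeneity beyond the
count-model trend, or realistic pathway topology (synthetic gene sets
are random). Passing parameter-recovery tests on these data therefore
demonstrates that the machinery is correct and calibrated under its own
assumptions — not that any particular biological conclusion transfers to
real tissue.

Fixed study-condition choices (made once, not revisited): cohort
covariates emulate a sedentary mid-life cohort (age ≈ 41 ± 15, BMI ≈
27 ± 4, 72% female); the default effect size is one marginal SD on a 5%
affected fraction; two-tissue data use 20 animals with a balanced sex
covariate, one planted driver gene at correlation 0.8 to half the target
genes.

## Problem sizes

The packaged checks run at desk scale: 20,000 simulation replicates for
the type-I-error comparisons; 500-feature differential recovery with 20
pairs per arm; 400-feature networks over 100 samples; 160-feature
trajectory sets over 10 seeds; 200 × 500 two-tissue matrices over 100
seeds for driver recovery. These sizes put every headline number within
a few minutes on one CPU while keeping Monte-Carlo error well inside the
tolerances asserted.

## Known limitations

- Satterthwaite df use the expected information; observed-information
  implementations differ by ~1 df on 50-participant designs.
- The unstructured-covariance GLS strategy is a moment-based evaluation
  stand-in, not a full REML mixed-model-for-repeated-measures; it exists
  to rank strategies, not to be one.
- KNN imputation is O(features × samples²) and meant for
  metabolomics-scale matrices.
- The height-based dynamic tree cut is simpler than the hybrid
  tree-cutting algorithms in dedicated network packages; on weakly
  separated modules it will under-split before it over-splits.
- `camera_pr()` treats ρ̄ as a constant per collection rather than
  estimating per-set correlations from expression data, which is all a
  pre-ranked test can do.
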