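# exermap

Statistical machinery for repeated-measures multi-omic studies of acute
exercise, built around a three-arm randomized design: endurance exercise
(EE), resistance exercise (RE), and a non-exercising control group (CON),
with tissue sampled pre-exercise and at one randomized post-exercise
timepoint per participant (45 min, 4 hr, or 24 hr).

The scientific problem: adipose tissue changes substantially over a day
even without exercise (time of day, fasting, the biopsy itself), so a
naive pre-vs-post comparison inside an exercise arm mixes exercise effects
with circadian and procedural ones. The package's core is the
**difference-in-changes ("delta-delta") contrast** on a per-feature
cell-means mixed model: for feature abundance *y*, with cell means
μ<sub>g,t</sub> per group × timepoint, covariates (age, sex, BMI, site)
and a participant random intercept,

&nbsp;&nbsp;Δ<sub>g,t</sub> = (μ<sub>g,t</sub> − μ<sub>g,pre</sub>) −
(μ<sub>CON,t</sub> − μ<sub>CON,pre</sub>)

tested with Satterthwaite degrees of freedom, minimum-pairs testability
(≥ 3 paired participants in every involved group), and Benjamini-Hochberg
adjustment within each contrast-group-ome-timepoint stratum.

Around that core the package provides, as composable functions returning
tibbles:

- **synthetic cohorts and multi-omic matrices** (`generate_cohort()`,
  `generate_omics()`, `generate_two_tissue()`) with every structure the
  pipeline assumes planted and recorded in a truth table — non-normal
  marginals via a third-order polynomial (Vale-Maurelli/Fleishman)
  transform (`rnonnorm()`), participant random intercepts, correlated
  module blocks, trajectory archetypes, sex effects, secreted-gene flags;
- **preprocessing rules** (`clean_metabolites()`,
  `conditional_median_mad_normalize()`, `flag_pc_outliers()`,
  `resolve_platform_redundancy()`, `filter_low_expression()`,
  `filter_min_quantified()`, `normalize_tmm()`, `regress_technical()`);
- **differential analysis** (`fit_feature()`, `contrast_cellmeans()`,
  `fit_differential()`, `sex_difference()`, `estimate_precision_weights()`,
  `build_zscore_matrix()`);
- a **simulation harness** (`simulation_spec()`, `evaluate_strategies()`)
  that measures type-I error and power of six candidate longitudinal
  strategies — paired t, OLS, weighted/unweighted random-intercept mixed
  models, unstructured GLS, and GEE-AR(1) with cluster-robust sandwich
  errors — on moment-matched non-normal data with study-like missingness;
- **enrichment** (`camera_pr()` competitive pre-ranked set test with
  inter-feature-correlation variance inflation, `ora()` hypergeometric
  over-representation, `filter_sets()` with the ≥ 5-member and ≥ 70%
  gene-retention rules, GMT I/O);
- **signed co-expression networks** (`bicor()`, `pick_soft_power()`,
  `build_modules()`, `module_trait()`) with module eigengenes, kME, and
  covariate-adjusted biweight-midcorrelation trait tables;
- **fuzzy c-means trajectory clustering** (`stack_and_scale()` with the
  zero-baseline scaling, `estimate_fuzzifier()`, `fuzzy_cmeans()`,
  `choose_c()`, `hard_assign()` at the 0.3 membership threshold);
- **endocrine connectivity** (`build_secretome()`,
  `extracellular_score()`, `ssec()`, `rank_shift_test()`,
  `gene_correlation_enrichment()`): per secretory origin-tissue gene, the
  normalized sum of −ln p over biweight midcorrelations against all
  target-tissue genes (Ssec), whose null mean is 1.

Fitted objects have broom-style `tidy()`/`glance()` methods and ggplot2
`autoplot()`s; `run_pipeline()` chains the stages end to end on synthetic
data.

## Worked example

```r
library(exermap)

design <- generate_cohort(c(EE = 20, CON = 20),
                          profile_weights = c(1, 0, 0), seed = 21)
sim <- generate_omics(design, effect_spec(
  n_features_per_ome = c(protein = 500), frac_dd_affected = 0.2,
  dd_effect = 1, n_modules = 0, module_size = 0, n_clusters = 1,
  sex_effect = 0, seed = 22))

res <- fit_differential(sim$matrices$protein, design,
                        families = "difference_in_changes",
                        covariates = NULL)
truth <- sim$truth[match(res$feature_id, sim$truth$feature_id), ]
mean(res$p_value[truth$is_dd_affected] < 0.05)   # power
#> [1] 0.81
sum(res$significant & !truth$is_dd_affected) /
  sum(res$significant)                            # realized FDP at BH 0.05
#> [1] 0
```

100 of the 500 proteins carry a planted one-SD difference-in-changes
effect. With 20 paired participants per arm the delta-delta test detects
81% of them at α = 0.05 — in line with the closed-form paired two-sample
calculation (d = 1 on change scores, power 0.87) — and none of the
BH-significant calls on this draw are false, consistent with the 5% FDR
target.

```r
rep <- evaluate_strategies(
  simulation_spec(n_reps = 2000, effect_size = 0, seed = 7))
rep[, c("strategy", "type_I_error")]
#>   strategy          type_I_error
#> 1 paired_t                0.0485
#> 2 ols                     0.0185
#> 3 lmm_ri_weighted         0.0475
#> 4 lmm_ri                  0.0475
#> 5 mmrm_unstructured       0.0800
#> 6 gee_ar1                 0.0875
```

Under the null, the random-intercept mixed model sits at its nominal 5%
level on skewed, heavy-tailed, profile-missing data, while the GEE
sandwich test is visibly inflated at these cluster counts — the basis for
preferring the mixed model as the primary analysis.

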