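---
title: "Judging aggregate personality scores: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Judging aggregate personality scores: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stateagg)
```

## The problem

Large online questionnaires can place hundreds of thousands of respondents in
their home state, which makes it tempting to average individual Big Five
scores into "state personality" scores and to correlate those with state-level
outcomes. Whether such aggregates deserve trust depends on a chain of
quantitative checks, each of which this package implements as a tested
function:

1. **Scoring under planned missingness.** Assessments that give each
   respondent a random subset of a large item pool leave most item cells
   empty by design. Scores are the simple mean of the observed keyed items
   (`score_scales()`), with reverse-keyed items reflected as
   `likert_min + likert_max - response`. No imputation and no IRT scoring:
   only means and variances matter downstream, and the mean of a random item
   subset is an unbiased estimate of the mean over the pool.
2. **Reliability of unit differences.** ICC1 from a one-way random-effects
   ANOVA (`anova_icc()`) measures the share of individual-score variance
   attributable to unit membership; the Spearman-Brown relation
   `ICC2 = k*ICC1 / (1 + (k-1)*ICC1)` (`spearman_brown()`) converts it into
   the reliability of a unit mean of ~k respondents. Tiny ICC1 values
   (0.001-0.015 in this literature) still produce reliable unit means when k
   is in the hundreds or thousands.
3. **A permutation null.** Because those ICC1 values are so small, the
   package provides a label-permutation null (`permutation_null()`):
   participants are randomly reassigned to units with per-unit counts held
   fixed, and ICC1/ICC2 recomputed per iteration. If the observed ICC1 were
   of the same magnitude as the permuted mean, the "reliable" differences
   would be an aggregation artifact.
4. **Cross-sample convergence.** Same-trait correlations between two
   samples' unit scores (`pairwise_convergence()`), weighted by census
   population (`weighted_pearson()`) so that thinly sampled units do not
   dominate, and pooled with Fisher's z (`fisher_mean()`). Pairs are grouped
   by design similarity (`classify_pair_design()`): same/different inventory,
   same/different project, same/adjacent/non-adjacent period.
5. **Convergence across inventories.** Within one sample, inventories drawn
   from a shared item pool are correlated at the unit level by a split-half
   bootstrap (`split_half_bootstrap()`): halving the participants breaks the
   dependence induced by shared items, and the same-inventory cross-half
   correlation estimates the reliability used to disattenuate the
   cross-inventory cells (`disattenuate()`).
6. **Replication of correlation patterns.** Unit scores are correlated with
   unit-level sociodemographic variables, census-weighted and partialled for
   the other traits (`weighted_partial_correlation()`, `build_panel()`), and
   replicability is summarized as a correlation of correlations
   (`replication_correlation()`).

## Estimator choices

**ICC1.** For unbalanced one-way designs we use
`icc1 = (MSB - MSW) / (MSB + (k - 1) * MSW)` with `k` the *arithmetic mean*
group size, matching how "average participants per unit" is conventionally
reported alongside these statistics. The unbalanced-design effective size
`k0 = (N - sum(n_j^2)/N) / (J - 1)` is available via
`anova_icc(..., k_method = "effective")`; with ~50 units and k in the
hundreds the two differ negligibly. ICC1 may be negative (group means more
alike than chance predicts); it is reported unclipped, and `anova_icc()`
reports `NA` for ICC2 in the pathological case where
`1 + (k - 1) * icc1 <= 0` (where `spearman_brown()` itself errors).

**Mean ICCs across traits.** Per-trait ICCs are computed separately; the
"mean across the Big Five" is the arithmetic mean of per-trait ICC1s and,
separately, of per-trait ICC2s. The Spearman-Brown relation is nonlinear, so
applying it to the mean ICC1 does not reproduce the mean ICC2; the two
summaries are deliberately not interchangeable.

**Permutation design.** Each iteration draws a fresh independent shuffle of
unit labels from a seeded generator. Under planned missingness the traits
have slightly different complete-case sets, so labels are permuted *within
each trait's complete cases*; this keeps the multiset of group sizes exactly
constant across iterations, which is the property the null is meant to hold
fixed. The mean permuted ICC1 is ~0 by construction; the mean permuted ICC2
is slightly *negative*, because the Spearman-Brown transform is concave
around 0 and Jensen's inequality pulls the mean of `k*u/(1+(k-1)u)` below 0
for a null-centered `u`.

**Weighted correlations.** Census weights are treated as frequency weights,
normalized to sum to one; weighted means, variances and covariance define
the correlation. The same weighted correlation matrix feeds the partial
correlations, which are computed by the Schur-complement (matrix-inversion)
identity. The weighted-least-squares residualization route gives the same
number and is kept as an independent oracle in the test suite. If `x` or `y`
is *exactly* explained by the controls, its partial variance vanishes and the
partial correlation is reported as 0 (nothing left to correlate); collinear
controls raise an error naming the columns.

**Fisher pooling.** Every "mean correlation" in the package is
`tanh(mean(atanh(r)))`. Inputs of exactly +/-1 (which occur in self-pair
tests) are clipped to 1 - 1e-12 with a warning. Cross-iteration summaries of
the split-half bootstrap use the same pooling by default (`pool = "raw"`
averages on the r scale instead; at the observed correlation magnitudes the
difference is in the third decimal).

**Split-half conventions.** Off-diagonal cells average the two orderings
(A-half1 x B-half2 and B-half1 x A-half2) within an iteration, since there is
no principled reason to prefer one. A `split = "duplicate"` test hook places
the full sample in both halves, which reduces every cell to the full-sample
cross-inventory correlation and anchors the bootstrap's correctness.

**Time classes.** Collection periods that overlap by more than a shared
boundary year are "Same"; boundary-touching periods (a sequential hand-off
within one project) or disjoint periods with a gap under `gap_years = 5` are
"Adjacent"; gaps of five or more years are "Non-adjacent". Year-granular
periods cannot express month-level overlap, so a pair that genuinely
overlapped for a few months but shares only a boundary year classifies as
Adjacent; the threshold and the rule are exposed as arguments.

**Other conventions.** `min_items` defaults to 1: a scale score is the mean
of whatever items were observed, with the floor exposed for sensitivity
analyses rather than guessed. Unit means are unweighted within unit (each
participant counts once, no post-stratification). The median absolute
deviation is reported both raw and with the 1.4826 normal-consistency factor,
since both conventions are common. `critical_r(n, alpha)` uses the exact t
transform and is a descriptive aid only -- no multiple-testing correction is
applied anywhere, because the package's analyses reason through patterns and
means of correlations rather than per-cell significance.

## The synthetic study generator

Every stage is exercised end to end on synthetic data with known ground
truth (`synth_config()`, `simulate_study()`). The defaults emulate the
structure of a large online assessment:

- **51 units with very unequal populations.** Weights follow a fixed
  right-skewed profile (lognormal quantiles, max/min ratio ~66, the order of
  magnitude separating the most and least populous US states). Unit
  assignment is multinomial by weight; a `"quota"` mode fixes per-unit counts
  at their expectations, which is the design that permutation-null studies
  hold constant.
- **Small between-unit variance.** Latent trait = unit mean + individual
  deviation, with `between_unit_sd = 0.055` and `within_unit_sd = 1` so the
  implied ICC1 is ~0.003 -- the upper end of what Big Five aggregation
  studies report. The implied ICC1 is recorded as `true_icc1` ground truth.
- **Planned missingness.** One 100-item inventory (20 items per trait)
  sampled at rate 0.30, i.e. ~6 observed items per trait per person, matching
  a 100-item pool taken at ~30%. Multiple inventories, inventory-specific
  rates, and shared items across inventories are configurable.
- **Item model.** Response = round(clip(midpoint + keying * loading *
  (latent - midpoint) + noise)) on the 1-6 scale, with `item_noise_sd = 1`
  (single-item reliability ~0.5, typical of short Likert items). The linear
  latent + Gaussian noise model is a deliberate simplification: only the
  first two moments matter to any statistic downstream. Rounding and
  clipping attenuate the observed-score ICC1 slightly below the latent
  `true_icc1`; recovery tests budget for that attenuation.
- **Sociodemographics with known structure.** Each variable is a linear
  combination of standardized unit trait means plus Gaussian noise. With
  `noise_sd = NA` the noise is calibrated so the expected realized
  correlation equals the target (`beta = r`, `sigma = sqrt(1 - sum(r^2))`
  up to scale); realized correlations are recorded for parameter-recovery
  tests. The default thirteen variables concentrate their targets on
  Conscientiousness, Neuroticism and Openness and leave Extraversion and
  Agreeableness weak -- the regime in which replication correlations are
  informative.
- **Demographics.** Ethnicity, age band and education are drawn from
  per-unit census margins generated around national base rates, so
  composition-representativeness checks have a known positive target; sex is
  a constant 66% female. The generator does *not* mimic real response styles
  (acquiescence, careless responding), real demographic joint distributions,
  or the age/education skew of volunteer web samples -- so passing tests
  certify the statistical machinery, not the field realism of any particular
  sample.

One master seed governs everything; each stage derives a documented
sub-stream via `derive_seed(seed, tag)`, so full runs are reproducible
bit-for-bit while stages remain independently re-runnable.

## Problem sizes used in the tests

Structural tests run on hundreds of participants. The statistical checks use
the smallest sizes at which their targets are sharp: parameter recovery of
ICC1 ~ 0.003 runs at n = 100,000 over 51 units (the between-unit sampling
error with ~50 units is the binding constraint, about 7e-4 on the ICC1
scale); the permutation null runs at 51 units x k = 500 with 500 iterations,
where the Monte-Carlo error of the mean permuted ICC1 is ~2e-5, far inside
the fourth decimal it is compared at; split-half and convergence recovery
tests use 6,000-20,000 participants with a larger `between_unit_sd` so that
reliabilities are well separated from zero at that scale.

## Known limitations

- Scores are plain item means; no IRT scoring, no imputation, no
  post-stratification of unit means.
- One-way ICCs only; no two-way/multi-rater variants and no REML variance
  components.
- The cross-sample convergence panel is not adjusted for ICC2 attenuation
  (the split-half machinery covers the within-sample version of that
  question).
- Facet-level analyses and heterogeneity statistics for the pooled
  correlations are out of scope.
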