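---
title: "Methods: transcriptomic sub-phenotyping of pediatric ARDS cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptomic sub-phenotyping of pediatric ARDS cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical models implemented in `pardsub`,
the assumptions they make, the tunable parameters and their defaults, the
design of the synthetic cohort generator, and the numerical choices made
where the methodology leaves room.

## Subtype discovery

Subjects are clustered on their whole-blood expression profiles —
log2-scale, already background-corrected and quantile-normalized — in the
full gene space, with no per-gene rescaling. Rescaling is deliberately
omitted: robust multi-array average output places all genes on a common
log2 scale, and variance-standardizing would up-weight low-variance genes
whose fluctuations are mostly noise. Values are used as given.

### k-means

`kmeans_cluster()` runs Lloyd iterations from kmeans++ seedings and keeps
the best of `n_init` restarts by total within-cluster sum of squared
Euclidean distances. Restarts matter more here than in textbook settings:
in p ≈ 2,000 dimensions the between-subtype separation is a small part of
any pairwise distance, so kmeans++ seeding behaves almost uniformly and a
single start reaches the global optimum only about half the time on
well-separated synthetic cohorts; ten restarts make a poor final fit
(probability ≈ 0.5^10) negligible. Empty clusters are repaired by
reseeding the empty center at the point farthest from its assigned
center, protecting singleton donors. The within-SS after every assignment
step is non-increasing by construction and asserted at run time.

The pooled dispersion `W_k = sum_r D_r / (2 n_r)` (with `D_r` the sum of
pairwise squared distances in cluster r) is algebraically identical to
the k-means objective; `within_dispersion()` exposes both forms and the
test suite checks their numerical agreement.

### Gap statistic

For k = 1..`k_max` (default 10), `gap_statistic()` compares `log W_k` on
the data against its expectation over `B` (default 50) reference datasets
drawn uniformly over each observed feature range — the simple-box
reference, chosen over the PCA-rotated box because with p ≫ n the
rotation adds cost without a stated benefit for this design.
Zero-range features are dropped from reference generation with a warning.
The spread `s_k = sd_b(log W*_kb) sqrt(1 + 1/B)` yields the normal
approximation CI `gap_k ± 1.96 s_k`; a bootstrap-percentile interval
would need far larger `B` for no practical gain at these sizes.

### Choosing k

`select_k()` implements a three-part rule:

1. **Similar performance set.** All k whose 95% CI overlaps the CI of the
   globally maximal gap are candidates.
2. **Size constraint.** Candidates whose clustering contains a cluster of
   10 or fewer subjects (≈ 10% of a 96-subject cohort) are eliminated;
   `min_cluster_size = 11` encodes the strict "more than 10" reading.
3. **Maximal gap with a one-SE tie band.** Among the admissible
   candidates, gaps within one `s` of the best admissible gap are treated
   as tied, and ties resolve to the smallest k.

The tie band deserves justification. On strongly clustered
high-dimensional data the gap curve rises steeply to the true k and then
plateaus: splitting a genuine cluster changes `log W` by an amount
(~1e-4) that is an order of magnitude below the Monte-Carlo resolution
`s_k` (~2e-3 at B = 50), so which plateau point carries the literal
arg-max is sampling noise. A strict arg-max would pick among the plateau
essentially at random; declaring sub-resolution differences ties — the
familiar one-standard-error convention for the gap statistic — makes the
choice parsimonious and stable. `se_factor = 0` restores the strict
arg-max for users who want it.

`pca_project()` provides the two-dimensional centered singular-value
projection used to visualize subtype separation, with exact
variance-explained fractions.

## Characterization statistics

Categorical subtype associations use the Freeman–Halton generalization of
Fisher's exact test (`fisher_exact_rxc()`): the p-value sums multivariate
hypergeometric probabilities of all tables with the observed margins that
are no more probable than the observed table, with a 1 + 1e-7 relative
tolerance absorbing floating-point ties. Continuous variables use
Kruskal–Wallis with tie correction. The reported effect size is the
rank-based `η²_H = (H − k + 1)/(n − k)`, floored at 0 — consistent with
the nonparametric testing framework; the ANOVA `SS_between/SS_total`
variant is available via `method = "anova"`. For k perfectly separated
equal groups `η²_H` tends to `1 − 1/k²`, not 1, which the tests assert
exactly. Characterization p-values are reported unadjusted;
Benjamini–Hochberg adjustment (`bh_adjust()`) is reserved for the
differential-expression q-values.

## Outcome models

**Mortality** is modeled by logistic regression (`fit_logistic()`), IRLS
to a 1e-12 deviance tolerance, Wald CIs and p-values. Perfect separation
(near-zero deviance, or runaway coefficients with degenerate fitted
probabilities) and rank-deficient designs raise explicit errors rather
than returning meaningless estimates.

**Extubation** is modeled by Fine–Gray subdistribution-hazard regression
(`fit_fine_gray()`), with death as the competing event: subjects who die
remain in later risk sets with inverse-probability-of-censoring weights
from the Kaplan–Meier estimate of the censoring distribution, ties are
handled Breslow-style, and variances are the model's robust (sandwich)
estimates. The event time is the first *sustained* liberation from
invasive ventilation (extubated more than 24 h); reintubation after a
sustained liberation adds ventilator days but does not re-enter the risk
set. Time origin is ARDS onset with administrative censoring at day 28 —
the ventilator-free-days horizon — so subjects still ventilated at day 28
are censored there. Convergence uses a gradient tolerance of 1e-7: on
some datasets the gradient criterion has a floating-point floor just
above 1e-8 while the coefficients are already stable to more digits, and
the reduction-to-Cox agreement is still verified at 1e-6.

`fit_cox()` (Breslow ties) serves both as a user-facing utility and as
the independent oracle for the reduction property: with no competing
events the Fine–Gray and Cox fits coincide. `km_estimate()`,
`logrank_test()` (overall and pairwise, unadjusted) and
`cumulative_incidence()` (Aalen–Johansen; cause-specific incidences plus
overall survival sum to one at every jump time) complete the
time-to-event toolkit.

**Clinical scores.** Oxygenation index `(MAP × FiO2 × 100)/PaO2`,
P/F ratio, and the weighted vasopressor score are direct formula
implementations. Ventilator days merge extubation gaps of at most 24 h (a
gap of exactly 24 h is *not* liberation) and add courses separated by
longer gaps. VFD at 28 days is `28 − ventilator days` for survivors, with
nonsurvivors and subjects ventilated ≥ 28 days assigned 0; partial days
are counted as whole days (rounded up) before subtraction so VFDs are
integers, a convention the `round_up` argument makes explicit since
source definitions rarely state it.

**Adjustment presets** mirror the confounding structure of the design:
none, PRISM III, immunocompromised status, both, and both plus ANC or
ALC, with subtype 1 as the reference level.

## Differential expression

The per-subtype signature pipeline keeps the canonical gates — expression
filter (≥ 10 in ≥ 10 samples by default), twofold change (inclusive,
`|log2FC| ≥ 1`), q < 0.1 (strict) — around a deliberately simple test: a
per-gene Welch two-sample t on log2 values, one subtype against the rest.
A negative-binomial count model is not appropriate for continuous
log-scale microarray intensities, so the package does not attempt one;
the Welch test on approximately Gaussian log2 data is the defensible
substitute and its null calibration and FDR control are verified by
simulation in the test suite. Zero-variance genes are handled explicitly
(t = 0, p = 1 when means agree; p = 0 otherwise).

`quantile_normalize()` maps every sample to the mean of the sorted
columns (ties receive the mean of their quantile targets) and is
idempotent to 1e-12.

## The synthetic cohort generator

`simulate_cohort()` produces the three linked tables the pipeline
consumes. Its defaults *are* the study conditions the package is
validated against: 96 subjects in three subtypes of 31/29/36 (deterministic
largest-remainder apportionment, so tests can pin exact group sizes),
2,000 genes of which 200 are informative in disjoint per-subtype blocks,
a +2 log2 mean shift per informative gene, unit Gaussian noise on gene
baselines drawn uniformly on 6–12 (the scale of summarized microarray
output), immunocompromise prevalence 32/48/14% and 28-day mortality
32/24/8% by subtype.

Outcomes follow the indirect subdistribution parameterization with
sustained extubation as the event of interest: the probability of ever
being extubated is `1 − (1 − p_base)^exp(η)`, conditional times follow the
implied subdistribution law (baseline daily rate 0.1, so median
ventilation near one week), and the competing death path draws a
truncated-exponential time within the 28-day horizon. Parameterizing the
*extubation* mass indirectly makes the extubation subdistribution hazards
exactly proportional, so each subtype's true log-SHR versus subtype 1 is
`log(log(dp_j)/log(dp_1))` (`implied_extubation_loghr()`), and planted
effects can be recovered by the Fine–Gray fit — the property the
parameter-recovery and CI-coverage tests exercise through the low-level
`simulate_competing_risks()`. Death fractions per subtype equal the
configured probabilities by construction, which the calibration test
checks at n = 5,000 within three binomial standard errors. Censoring is
administrative only, at day 28. A 10% minority of extubated survivors
receives a late (> 24 h) reintubation episode to exercise the
ventilator-day rules without moving event times.

What the generator does **not** emulate: within-subtype gene–gene
correlation (genes are independent given subtype — real co-expression
modules would make the effective dimensionality smaller), batch effects,
probe-level artifacts, RNA degradation, random loss to follow-up, and
death after successful extubation. Passing recovery tests on these
cohorts therefore demonstrates correctness of the machinery under the
assumed signal model, not performance guarantees on real cohorts.

## Problem sizes and determinism

Every stochastic routine takes a seed and is reproducible bit for bit;
the pipeline derives named per-stage sub-seeds from a single
configuration seed and logs them in the report manifest. The test suite
runs the full-size end-to-end recovery (96 × 2,000, 20 seeds), the
planted-SHR recovery (100 simulations at n = 2,000), the Wald CI coverage
checks (500 simulations at n = 500 for both models) and the exact-test
and rank-test calibration suites (10,000 simulations each) at full size;
smaller structural tests use reduced cohorts (typically 60 subjects ×
300 genes) chosen to keep the default test run fast while preserving the
property under test. The brute-force oracles — complete table enumeration
for the exact test, exhaustive two-partition search for k-means, direct
maximization of the Breslow partial likelihood, hand Aalen–Johansen —
are implemented independently in the test helpers.

## Known limitations

- The gap statistic is computed in the full gene space; with tens of
  thousands of genes the reference generation dominates run time and the
  gap differences beyond the true k are weakly informative (hence the
  tie-band rule).
- Adjusted subtype–outcome estimates on real cohorts depend on
  subject-level covariates; the package reproduces published *unadjusted*
  quantities exactly and validates the adjusted machinery by parameter
  recovery on synthetic data.
- The DE step is a two-group location test; it does not model
  mean–variance trends across genes or borrow strength between genes.
- Pathway/enrichment analysis of the resulting gene lists is out of
  scope; the DE output is designed to feed external enrichment tools.
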