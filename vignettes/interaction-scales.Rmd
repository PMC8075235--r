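---
title: "Causal scenarios and the additive-to-multiplicative effect scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal scenarios and the additive-to-multiplicative effect scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amles)
```

## The problem

When two dichotomous risk factors are studied jointly in a case-control
design, three odds ratios describe their effects: `OR10` and `OR01` for the
exclusive exposures and `OR11` for the double exposure, all against the
doubly-unexposed reference (`OR00 = 1`). Interaction tests ask whether
`OR11` departs from a null composition of the single-exposure effects — the
*additive* null `OR11 = OR10 + OR01 - 1`, rooted in the sufficient-cause
model, or the *multiplicative* null `OR11 = OR10 x OR01`, implicit in
logistic regression. The two nulls are routinely conflated, and the same
data can "show interaction" under one and not the other.

This package simulates explicit causal mechanisms and measures where each
mechanism lands between the two nulls, so that an observed effect-scale
relationship can be translated back into statements about causation. It
also implements the metric at the center of that translation:

\[
\mathrm{AMLES} = \frac{OR_{11} - (OR_{10} + OR_{01} - 1)}
                      {OR_{10}\,OR_{01} - (OR_{10} + OR_{01} - 1)},
\]

the additive-to-multiplicative linear effect scale: 0 when the joint effect
is exactly additive, 1 when exactly multiplicative, with a meaningful
intermediate range. The denominator equals \((OR_{10}-1)(OR_{01}-1)\), which
links AMLES to the relative excess risk due to interaction:
\(\mathrm{RERI} = RR_{11} - RR_{10} - RR_{01} + 1\) and
\(\mathrm{AMLES} = \mathrm{RERI} / ((OR_{10}-1)(OR_{01}-1))\) when ORs and
RRs coincide.

## The generative model

Every simulated scenario is built from latent binary *components* —
causal sub-processes that are "present" or "absent" per individual — and an
outcome rule over them:

* **Synergism (AND)**: all components must be present. Because the case
  probability factorizes over components, relative risks are exactly
  multiplicative at every prevalence.
* **Heterogeneity (OR)**: any single component suffices. Relative risks are
  additive in the low-prevalence limit and less than additive at high
  prevalence.
* **Multifactorial threshold**: at least `t` of `F` components present.
  `t = 1` reproduces heterogeneity, `t = F` synergism, and intermediate
  thresholds land in between. On the scaled threshold
  `f_thr = (t-1)/(F-1)`, the median AMLES tracks `sqrt(f_thr)`, i.e.
  `OR11` is predicted by
  `(1 - sqrt(f)) x expected(additive) + sqrt(f) x expected(multiplicative)`.
* **Three factors**: outcome `comp1 AND (comp2 OR comp3)`, the minimal
  mixed structure whose pairwise relations disentangle into synergism
  (X with Z, X with V) and heterogeneity (Z with V).

Observed risk factors are probabilistic markers of components: a factor is
carried with its `high_freq` when its linked component is present and
`low_freq` otherwise, so factors are informative but neither necessary nor
sufficient — the situation of real genetic risk variants under a dominant
or recessive coding.

Two confounder scenarios contain no causal link between the factors:
**Confounder I** draws cases and controls from different backgrounds
(factors independent within each pool, higher frequencies among cases),
which forces exactly multiplicative expected ORs and is therefore
indistinguishable from synergism in case-control data. **Confounder II**
mixes two subpopulations differing in both factor frequencies and
prevalence; it produces less-than-additive joint effects together with a
tell-tale positive factor-factor correlation in all three strata (all,
cases, controls). Two **additive schemes** complete the set: a
linear-probability risk (`ADDITIVE_R`, exactly additive RRs) and a
two-group design in which only one factor carries risk per group
(`ADDITIVE_O`, exactly additive ORs) — the latter is also the template for
the `rand2` randomization control.

### Component probabilities and exact prevalence

The mapping from a target prevalence to component probabilities assumes all
components share one "present" probability `p` (the symmetric reading of
equally-weighted components): `p = prevalence^(1/F)` for AND,
`1 - (1-prevalence)^(1/F)` for OR, and for thresholds the root of
`P(Binomial(F, p) >= t) = prevalence`, solved by bisection to an outcome
probability error below `1e-10`. In the three-factor scenario components 2
and 3 share one probability and component 1 matches their OR-combination,
so the two arms of the AND contribute equally.

Rather than drawing each individual's outcome and rejecting cohorts whose
prevalence drifts, the simulators fix the case count at
`round(n x prevalence)` and sample latent states from the exact
outcome-conditional distribution obtained by enumerating all `2^F`
component states (`oracle_cell_probabilities()` exposes the same
enumeration). Realized prevalence is therefore always within `1/n` of the
target — far inside the default tolerance of 0.0004 — and the enumeration
doubles as an independent analytic oracle against which the simulators are
tested cell by cell.

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `low_freq` (Z-like) | uniform [0.05, 0.15] | background carrier probability |
| multiplier (Z-like) | uniform [1.1, 4] | `high_freq / low_freq` |
| `low_freq` (X-like) | uniform [0.05, 0.25] | background carrier probability |
| multiplier (X-like) | uniform [1.1, 2] | `high_freq / low_freq` |
| `n_individuals` | 1e6 | cohort size per replicate |
| `prevalence_tolerance` | 4e-4 | allowed deviation of realized prevalence |
| `min_cell` | 5 | minimum count in each of the 8 cells for a valid OR set |
| prevalence grid | 0.005, 0.02, 0.10, 0.33, 0.50 | from rare-disease to balanced designs |
| `prevalence_ratio` (Confounder II) | 3 | between-group prevalence contrast |
| bootstrap resamples | 1000 | percentile CI of the median, resampling replicates |
| correlation dead-band | 0.01 | median correlations below this report sign "0" |

Frequencies are truncated at 0.99 if a multiplier would push them to 1;
clipped draws are flagged on the factor and surfaced per replicate. The
high frequency always sits on the risk-associated side (component present,
case pool, or high-prevalence subpopulation). For `ADDITIVE_R` the drawn
multipliers act as target single-factor relative risks instead, so effect
sizes stay comparable across scenarios.

## Estimators and their stability

Odds ratios are computed from raw counts, never from model fits, and the
only guard is the minimum-cell filter (five individuals in each of the
eight cells); replicates failing it are excluded from medians and counted.
AMLES is reported as undefined when \(|(OR_{10}-1)(OR_{01}-1)| < 10^{-9}\),
and flagged when a single-factor estimate is protective (below 1), where
the scale has no established interpretation.

AMLES is a ratio of noisy, correlated quantities and is heavy-tailed when
the single-factor effects are weak or the analysis sample is small. Two
consequences shape the experiment defaults:

* With equal-size subsampling at 0.5% prevalence, a cohort of `1e5` leaves
  only 500 cases and 500 controls; the median of the resulting AMLES
  distribution sits well away from the underlying truth even though each
  cohort's exact (enumeration-level) AMLES is essentially 1. The replicate
  experiments that make quantitative median-AMLES claims therefore run at
  the full one-million-individual cohort size, where the estimator's
  median is stable.
* The threshold sweep computes its odds ratios on the complete cohort
  (`threshold_sweep(subsample = FALSE)` default). The sweep's per-factor
  effects are intrinsically weaker (a single component out of five moves a
  factor little), and the full-cohort control pool keeps the AMLES ratio
  well-conditioned; with subsampling the sweep's medians are dominated by
  estimator noise rather than by the threshold law.
* The low end of the sweep is the worst-conditioned point: at `t = 1`
  each factor's association is diluted across the five interchangeable
  components, the AMLES denominator sits near zero, and the replicate
  distribution becomes heavy-tailed with a downward-shifted median at
  realistic case counts, even though the exact-enumeration value is
  essentially 0. Growing the cohort restores the anchor (the median moves
  from about −0.2 at one million individuals to −0.03 at four million);
  interpret small-`t` sweep medians with their confidence intervals, not
  as point anchors.

## The three-factor decomposition

`three_factor_fit()` scores the eight possible assignments of
additive/multiplicative labels to the three pairs (XZ, XV, ZV). Each label
triple corresponds to exactly one logical formula over the factors, because
a multiplicative pair denotes an AND relation and an additive pair an OR
relation: all-mult is `X AND Z AND V`; all-add is `X OR Z OR V`; a triple
with two mult labels singles out the factor shared by both mult pairs as
necessary, e.g. (mult, mult, add) is `X AND (Z OR V)` with expected
`RR111 = RR100 x (RR010 + RR001 - 1)`; and a triple with two add labels
singles out the factor shared by both add pairs as an independent
alternative, e.g. (add, add, mult) is `X OR (Z AND V)` with expected
`RR111 = RR100 + RR010 x RR001 - 1`. AND arms compose by products of
relative risks, OR arms by sums minus one. This rule was chosen over
averaging-based conventions for mixed labels because it is structurally
determined — every candidate is the exact composition of some causal
formula — and never manufactures candidates that sit between the additive
and multiplicative values by construction.

Two caveats, visible in the exact enumeration: the OR arm of
`X AND (Z OR V)` operates at an effective prevalence of
`sqrt(prevalence)` (about 7% when the outcome prevalence is 0.5%), where
additivity is already slightly eroded, so the correct composition
overestimates `RR111` by a few percent even without sampling noise; and
the triple-exposure cell is rare, so the per-replicate best-fitting label
at realistic cohort sizes is noise-dominated. The decomposition is
reliable as a statement about the distribution across replicates (the
observed/expected ratio for the correct label is tightly centred near 1),
not as a per-cohort classifier.

## Randomization controls

For an observed factor table, `rand1_shuffle_within_status()` permutes
every factor within cases and within controls, preserving all per-status
marginal counts while destroying conditional dependence — the Confounder I
structure, hence a positive control for multiplicative ORs.
`rand2_group_split_null()` splits individuals into two random halves and
resamples, per individual with replacement, the anchor factor from its
control-stratum distribution in one half and each test factor likewise in
the other — the `ADDITIVE_O` structure. Resampling with replacement (and
per-individual independence) is one of several readings of this scheme;
it was chosen for simplicity and documented here because the scheme is
known to moderate odds ratios somewhat in either reading.

## What the generator does and does not emulate

The generator reproduces the statistical skeleton of a GWAS-style
case-control study: dichotomous factors, rare-to-balanced case fractions,
biased (outcome-based) sampling, per-study frequency variation, and
confounding by background mismatch or stratification. It does **not**
model linkage disequilibrium between factors, quantitative traits,
covariates, genotype uncertainty, or selection beyond the case-control
split. Tests passing on these cohorts validate the estimators and the
causal-scenario algebra; they do not certify behavior on real data where
LD and covariate structure are present — there, the randomization
controls are the intended bridge.

## Problem sizes used in the test suite

The two-component AND/OR experiments use 200 replicates at one million
individuals (the headline median-AMLES anchors); the threshold sweep uses
500 replicates per threshold at one million individuals, sized so the
Monte Carlo error of each median sits well below the effect scale's
0-to-1 range; the stratification-correlation and three-factor experiments
use 100 replicates at one million; oracle-agreement checks run at 1e5;
and fixture-based randomization checks use 20000 individuals with
50 loci. These sizes are the package's reproduction conditions; the
underlying claims are insensitive to further growth, and the enumeration
oracle provides the noise-free limits throughout.

## Known limitations

* AMLES is undefined when either single-factor OR equals 1 and unstable
  nearby; medians over replicates, with the minimum-cell filter and the
  degenerate-denominator guard, are the supported summaries.
* Protective factors (OR below 1) are flagged, not reinterpreted.
* The equal-component-probability mapping is the symmetric reading of
  equally-weighted components; other prevalence-preserving mappings exist
  and would perturb intermediate-threshold results.
* Confounder II's two-subpopulation mixture with a fixed prevalence ratio
  is a minimal stratification model, not a fitted demographic model.
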