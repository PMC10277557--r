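---
title: "Classifying chronotype from functional brain networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying chronotype from functional brain networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chronet classifies an individual as an early (ECP) or late (LCP) circadian
phenotype — or abstains ("unclear") — from a resting-state functional brain
network, by asking which group label makes that individual's network fit the
group-difference structure better. This vignette explains the model, the
tunable parameters, the synthetic-data generator used for validation, and the
numerical and design choices made where more than one reasonable option
existed.

## Functional networks: Tikhonov partial correlation

Each subject contributes a T × N matrix of ROI time series (T timepoints,
N regions). Columns are standardized to mean 0 and sample standard deviation
1 (divisor T − 1), so the sample covariance of the standardized series equals
the correlation matrix. The network's edge weights are partial correlations
computed from a ridge-regularized precision matrix:

    P = (C + λI)⁻¹,   ρᵢⱼ = −Pᵢⱼ / √(Pᵢᵢ Pⱼⱼ)  (i ≠ j)

Partial correlation suppresses indirect connections; the λI term (Tikhonov
regularization) keeps the inverse well defined even when T < N or C is
ill-conditioned. The diagonal is stored as `NA`: a self-link has no meaning
under partial correlation. Weights live in [−1, 1]; tiny floating-point
overshoots are clipped.

**Choosing λ.** `optimize_lambda()` minimizes

    F(λ) = sqrt( Σ_{i<j} Σ_m ( P̄ᵢⱼ(λ) − Pᵐᵢⱼ(λ) )² )

where Pᵐ is subject m's precision matrix and P̄ the cohort mean. Each
subject's deviation is squared *before* summing over subjects — summing the
deviations first would give identically zero, since deviations from a mean
cancel. The sum runs over the off-diagonal upper triangle only: diagonal
precision entries reflect scale, not connectivity, consistent with the
networks' `NA` diagonal. The default search uses 200 logarithmically spaced
values on [10⁻⁴, 10] refined once by a 100-point linear grid around the
coarse minimizer; ties go to the smallest λ, and a single global λ is fitted
when several cohorts (e.g. scanning sessions) are supplied together. Sample
(T − 1) denominators are used throughout; any consistent choice merely
rescales the covariance, and λ is fitted on the same convention.

## The network-based statistic and the percolation threshold

Group differences are located with the network-based statistic (NBS). For a
one-sided contrast (ECP > LCP or ECP < LCP), every off-diagonal ROI pair gets
a pooled-variance two-sample t-statistic with the contrast-favored group's
mean first in the numerator, on n₁ + n₂ − 2 degrees of freedom (a Welch
option exists behind `var_equal = FALSE`; the pooled form is the reference
NBS behavior). Edges with zero pooled variance are degenerate: they carry a
−Inf sentinel and can never be suprathreshold; if they would be needed to
connect the graph, the percolation search fails loudly rather than silently.

Thresholding the t-matrix at τ and keeping connected components of
suprathreshold edges (t ≥ τ, inclusive) yields candidate *dysconnected
networks*. Rather than picking τ by convention, the pipeline uses the
**percolation threshold**: the highest τ at which the suprathreshold graph
still connects all N ROIs. With finitely many t-values this supremum is
attained only under the inclusive rule, and it equals the minimum edge value
along a maximum spanning tree (the maximum-bottleneck property), which is how
`percolation_threshold()` computes it; every call also asserts directly that
the component spans all N nodes and that the next distinct t-value
disconnects the graph. The component at the percolation threshold is the
minimum connected component (MCC): the sparsest suprathreshold network
touching every ROI.

**Familywise error.** A component's evidence is its *intensity* — the sum of
its edges' t-values, which detects distributed-but-subtle effects that edge
counts miss (an exceedance variant Σ(t − τ) is available behind
`intensity = "exceedance"`). Significance comes from permutation: the full
label vector is permuted (group sizes preserved), the t-matrix is recomputed
under the same contrast and thresholded at the same τ, and the maximum
component intensity is recorded (0 when nothing survives). The p-value is the
fraction of permutations whose maximum intensity exceeds the observed
component's intensity — strictly greater, with no add-one correction,
matching the counting rule the method defines (a conservative
`(#{≥} + 1)/(n + 1)` mode is available). When the number of distinct
assignments is at most `n_perm`, exhaustive enumeration replaces sampling
automatically, making the p-value exact. When several components coexist at
a fixed τ they share one null distribution; the selected component is the one
with the smallest p, ties broken by edge count, then deterministically toward
the component containing the smallest ROI index.

## The three-step classifier

To classify subject m, it is hypothesized to be an ECP (training labels kept
for everyone else), giving a percolation threshold t_E and its MCC E_tE with
an FWE p-value; then hypothesized to be an LCP, giving t_L and L_tL. Two
cross networks — E_tL (m as ECP, thresholded at t_L) and L_tE — complete the
quad. The held-out subject participates in the permutation null like any
other subject: the hypothesis places it inside a group before the pipeline
runs, and nothing exempts it from relabeling.

1. **Step one** looks at E_tE and L_tL. Exactly one significant (p < α) →
   that label. Neither → unclear. Both → continue.
2. **Step two** applies the same table to E_tL and L_tE.
3. **Step three** compares edge counts at matched thresholds: |E_tE| vs
   |L_tE| (both at t_E) and |E_tL| vs |L_tL| (both at t_L). Both comparisons
   favoring the same label assign it; a conflict or an exact tie is unclear.

The matched-threshold pairing and the conservative tie handling are design
choices: pairing networks at the same τ is the only comparison that becomes
degenerate in the right way when t_E = t_L (the cross networks then alias the
direct ones, which is also how the *reduced* classifier used in fixed-τ
sweeps arises: one significance check, then one edge-count comparison).
Step-3 conflicts and ties resolve to unclear because the evidence is
genuinely ambiguous there, and this keeps the full and reduced forms
consistent. An unclear produced by step 3 records no deciding step (the
rules were exhausted); unclears at steps 1–2 record the step that fired.

The cross networks and their permutation p-values are materialized lazily —
only when step one returns "both significant" — because permutation testing
dominates runtime. Every (subject, labeling, threshold) permutation stream
has its own seed derived from the base seed by XOR with a per-subject,
per-network index, so leave-one-out results are reproducible and independent
of evaluation order.

## Evaluation

Because the classifier can abstain, accuracy is #correct / #subjects,
misclassification is #wrong-definite / #subjects and unclear is
#abstained / #subjects; the three always sum to 1, and an abstention never
counts toward accuracy. Sensitivity is the fraction of true ECPs assigned
ECP, specificity the analogue for LCPs, and balanced accuracy their mean —
reported because the group sizes are unbalanced, although the t-test itself
compares means and is not biased toward the larger group.

`sweep_threshold()` replaces the per-labeling percolation thresholds with one
fixed τ from a grid (default 0 to 4.5 in steps of 0.01) and runs the reduced
classifier in a leave-one-out loop at every grid value, reusing each
labeling's observed t-vector and permutation t-matrices across the grid. No
multiple-comparison correction is applied across the grid; sweeps are
exploratory and labeled as such. `sweep_alpha()` varies the significance
threshold over [0, 1] (default step 0.01) with all four p-values computed
once per subject — p-values do not depend on α. At α = 0 nothing is
significant, so everything is unclear; once α exceeds every subject's four
p-values the outcome is frozen, so accuracy plateaus. `stability_analysis()`
removes each subject in turn and re-runs the full leave-one-out evaluation on
the remaining N − 1 subjects.

Node-degree summaries of a dysconnected network use the full parcellation
size as denominator (untouched ROIs count as degree 0), so the mean degree is
2E/N_total; this convention reproduces all published worked examples this
package pins in its acceptance suite. The degree standard deviation uses the
population (divide-by-N) convention; the sample convention differs
negligibly and neither is asserted against published ± values.

## The synthetic cohort generator

Real resting-state cohorts of labeled extreme chronotypes are not freely
available, so validation runs on seeded synthetic cohorts built to have the
statistical structure the pipeline assumes. Defaults mirror the target study
design: 16 ECP and 22 LCP subjects, 70 ROIs, 450 timepoints.

Each subject's series is T i.i.d. draws from a zero-mean multivariate
Gaussian whose precision matrix is identity plus planted couplings: a
*planted subnetwork* of edges (default 30) where the off-diagonal precision
entries are −0.05 for LCPs and −(0.05 + δ) for ECPs, δ = 0.30 by default, so
the planted partial correlations are more positive for ECPs and the
detecting contrast is ECP > LCP. Per-subject heterogeneity adds a symmetric
Gaussian perturbation (scale `subject_sd` = 0.02) to the precision matrix.
Positive definiteness is restored by diagonal loading in increments of 0.01
until the minimum eigenvalue exceeds 10⁻⁶ (aborting loudly after 100
increments), and the loading applied is recorded per subject. Two
consequences are worth knowing:

- The planted edges are sampled as a *connected* subnetwork (a random
  spanning tree over min(N, planted + 1) nodes plus extra edges among them).
  Scattered, disconnected planted edges are not what the minimum connected
  component is designed to find; a connected planted subnetwork is the
  effect the method targets, and when it spans the parcellation the
  percolation threshold locks onto it.
- Diagonal loading shrinks the realized planted partial correlations below
  the nominal (base + δ) value — with 30 strong couplings on 15 ROIs the ECP
  planted partial correlation realizes near 0.15 rather than 0.35. The
  planted group difference remains large relative to sampling noise at
  T = 450, which is what the recovery analyses rely on.

Temporal structure defaults to white noise; an AR(1) coefficient is accepted
(stationary, unit marginal variance) because autocorrelation shrinks the
effective sample size, but the pipeline consumes only covariance, so it is a
realism knob rather than a correctness requirement. A fast edge-level
generator (`simulate_edge_cohort()`) samples network weights directly
(planted mean shift plus i.i.d. edge noise, clipped to [−1, 1]); it is
convenient for exercising the NBS and significance machinery, but its
uniformly shifted planted edges make the step-3 edge-count comparison tie
structurally, so classifier recovery analyses use the time-series generator.

The generator does **not** emulate hemodynamics, motion or physiological
artifacts, scanner drift, preprocessing-induced autocorrelation, or spatial
dependence between ROI errors. Passing tests therefore demonstrate that the
pipeline recovers the structure it models — not that chronotype is decodable
from any particular real dataset.

**Validation problem sizes.** The bundled analyses run at N = 15 ROIs,
T = 450, 16/22 subjects with 200 permutations and 200 replicates for
calibration (the familywise error rate at α = 0.05 must land in
[0.02, 0.09]), and the same cohort scale for planted-effect recovery
(leave-one-out accuracy ≥ 0.90 under the matching contrast, definite-label
rate ≤ 0.10 under the opposing one). These sizes keep full runs fast while
preserving the study's group sizes and scan length; N is reduced from 70
because the planted-subnetwork geometry, not the parcellation size, drives
the behavior being validated. With λ fixed at 0.05 for these synthetic runs
(T ≫ N makes the fit insensitive to λ), a full calibration takes well under
a minute.

## Numerical choices

- **Threshold rule**: suprathreshold means t ≥ τ, inclusive, and the
  percolation threshold is reported as the bottleneck edge's exact t-value.
- **Tie tolerance in permutation counting**: the identity permutation
  recomputes the observed t-values along a different floating-point path
  (vectorized group sums versus the per-edge observed route). "Strictly
  greater" is therefore taken beyond a relative tolerance of 10⁻⁸, and the
  permutation-side thresholding uses a 10⁻⁹ relative tolerance, so exact
  mathematical ties cannot flip on the last bit. Between distinct
  permutations the gaps are orders of magnitude larger, so the tolerance
  changes nothing else.
- **Degenerate edges**: zero pooled variance yields −Inf, logged, never
  suprathreshold; percolation fails with the isolated node set named when
  sentinels disconnect the graph.
- **Tie-breaks**: λ ties go to the smallest grid value; component-selection
  ties go to edge count and then to the smallest contained ROI index;
  step-3 count ties are unclear.
- **Symmetry and bounds**: networks are symmetrized to machine precision on
  construction; partial correlations are clipped to [−1, 1]; input adjacency
  files are validated for symmetry to 10⁻⁸ and a `NaN` (or zero, with a
  warning) diagonal.

## Known limitations

- The step-3 decision table is a reconstruction: matched-threshold pairing
  with conflicts and ties resolved to unclear is the conservative, symmetric
  completion consistent with the reduced variant, but other tables are
  conceivable.
- The λ optimization objective is a faithful implementation of a verbal
  description whose literal reading is degenerate; see above for the
  interpretation used.
- The percolation-threshold permutation test uses a data-dependent τ, so the
  permutation null is approximate rather than exact; the calibration
  analysis shows the realized familywise error sits at the nominal level for
  the study-scale design.
- Leave-one-out evaluation here cannot be nested: the hypothesized label of
  the held-out subject enters the t-matrix by design, which is what the
  classifier exploits, so standard train/validation nesting does not apply.
- At small cohort sizes, removing one subject can move several p-values
  across α — the stability analysis exists precisely to surface this, and
  single-subject sensitivity should be expected rather than treated as a
  defect.
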