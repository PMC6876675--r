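---
title: "Methods: IPW-DID impact evaluation on synthetic household panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IPW-DID impact evaluation on synthetic household panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its statistical machinery: the
models, the defaults and why they were chosen, what the synthetic data
generator does and does not emulate, and the numerical conventions a
maintainer needs to know. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## 1. The estimation problem

The package targets two-wave (baseline/endline) household panels from
non-randomized agricultural interventions in which households self-select
into participation. Identification rests on two standard assumptions:

* **Unconfoundedness / selection on observables.** Conditional on the
  pre-treatment covariate vector `z`, participation is independent of
  potential outcomes.
* **Parallel trends.** Absent treatment, treated and control outcome
  trends are equal, so the interaction of treatment and time identifies
  the effect.

Stage one fits a probit `p = Φ(z'β)` for participation, trims to common
support, and (for diagnostics) matches controls to treated on the score.
Stage two estimates

```
y_it = α + λ t + θ W_i t + ρ W_i + γ' x_i + ε_it
```

by weighted least squares with inverse-probability weights `1/p` (treated)
and `1/(1−p)` (control), clustering standard errors at village level. The
combination is doubly protective in spirit: DID absorbs time-invariant
gaps (`ρ`, `γ'x`), weighting rebalances observables, and the placebo
regressions of baseline outcomes on endline participation audit what
remains. It is *not* a formal doubly-robust estimator (AIPW is a
non-goal).

**Matching versus weighting.** The two-step procedure this package
mirrors uses matching to define and diagnose the comparable sample but
estimates with propensity-score *weights*. Accordingly
`match_households()` feeds the balance diagnostics and sample definition,
while `did_estimate()` consumes IPW weights on the support-retained
sample. Using matching weights directly in `did_estimate()` is possible
(any per-household weight vector is accepted) but is not the default
pipeline behaviour.

## 2. Tunable parameters that matter

* **Support trimming** (`common_support()`): default is the min–max
  intersection of the two arms' score ranges. A second convention,
  `"treated_preserving"`, trims only controls outside the treated range;
  it exists because narratives of this design sometimes report support
  regions with "no loss of treated observations", which the intersection
  rule cannot produce when a control's maximum lies inside the treated
  range. Neither convention is asserted to be the other's equal; the
  choice is logged in the run manifest.
* **Matching defaults**: radius 0.05, Epanechnikov bandwidth 0.06,
  nearest neighbour k = 1 with replacement (ties to the lowest household
  id). These are the conventional textbook values; the underlying study
  reports none. Each matched treated household distributes one unit of
  weight over its matched controls, so control weights sum to the number
  of matched treated.
* **IPW weights**: used as defined (`1/p`, `1/(1−p)`), unnormalized, with
  an option to renormalize within arm to the arm size. Scores are
  defensively clamped to `[1e-6, 1-1e-6]` before inversion and the count
  of clamped households is reported (`n_clamped`).
* **Cluster-robust covariance**: CR1 small-sample factor
  `G/(G−1)·(n−1)/(n−k)` by default (CR0 available); confidence intervals
  and p-values use the t distribution with `G−1` degrees of freedom, the
  conventional small-G reference.
* **Balance t-statistics**: Welch (unpooled) variances by default, pooled
  available — the convention in published balance tables is usually
  unstated. Binary covariates use the Bernoulli variance `p(1−p)` inside
  the standardized-bias denominator; this is what reproduces the
  published bias cells from their printed means. Post-matching bias keeps
  the *unmatched* variances in the denominator (the Stata `pstest`
  convention), so before/after biases share a scale.
* **Probit fitting**: Fisher scoring from zero starting values, gradient
  max-norm tolerance 1e-6 (hard contract: otherwise an explicit
  non-convergence error with the likelihood trace), step-halving for
  ascent, perfect-separation detection both during iteration (runaway
  coefficients) and at convergence (every observation classified with
  |z'β| > 3). Age and asset value enter in natural logs by default,
  configurable per covariate.
* **Marginal effects**: the derivative formula `mean φ(z'β)·β_k` is the
  default for *all* covariates, binary included, so the AME/coefficient
  ratio is constant across covariates (equal to the mean density) — the
  pattern visible in the published first-stage table. A discrete-change
  method for binaries is available.

## 3. Indicator construction

* **Knowledge scores**: each correct answer is weighted by the inverse of
  the share answering it correctly in the reference sample; the package
  fits weights on the pooled *baseline* sample and holds them fixed
  across waves so scores are comparable over time (the source protocol
  does not state the reference sample; per-wave weights would conflate
  knowledge change with difficulty re-estimation). Items never answered
  correctly are excluded with a warning. Production and vitamin A item
  sets are disjoint, so the combined score is exactly their sum. Missing
  responses score as incorrect by default. Standardized variants subtract
  the baseline mean and divide by the baseline SD.
* **Dietary diversity**: all four schemes consume the same 12 survey
  categories through an editable CSV map shipped in `extdata`
  (HDDS 8 groups incl. oil; child DDS 8 groups with organ meat separate,
  vitamin-A-rich vs other produce distinguished, oil excluded; FGDS 10
  groups; vitamin A diversity 6 groups). FGDS is allowed to be 0 here
  although its published range starts at one (which presumes at least one
  group consumed) — a documented divergence; an all-zero recall yields 0.
* **FCS**: group-sum first, then cap at 7, then weight — the printed
  order of operations. The 8-group WFP/HKI weight vector is collapsed to
  7 groups by merging sugar into oil (weight 0.5), because the protocol
  cited uses "seven specific food groups" without printing weights; the
  weight file is fully configurable.
* **Vitamin A frequency**: the instrument records days per item, not
  which days, so the day-union is resolved as `min(Σ item days, 7)`.

## 4. What the synthetic generator emulates — and what it does not

`generate_panel()` reproduces the *design*: 434 households in both waves,
village clustering (30 villages by default — the source never reports a
count, so this is a package choice), Bernoulli/beta/lognormal/Poisson
covariates with marginals matched to the published summary table,
participation by a latent-index probit whose coefficients follow the
published first-stage estimates (giving a realized treated share near
half and common support roughly (0.15, 0.87)), and outcomes from the DID
equation with published levels, trends, treated-group gaps and treatment
effects. Outcome noise SDs are set so effect sizes in SD units match the
published standardized effects (e.g. knowledge effect 2.154 ≈ 0.18 SD ⇒
noise SD ≈ 11). Raw instruments (exam items via a one-parameter IRT
model, recall and frequency items via logit-shifted category prevalences,
month calendars via per-month Bernoulli draws) track the standardized
outcome latents, so the indicator pipeline is exercised end to end.

It does **not** emulate: the voucher-delivery economics, spatial structure
beyond village ids, attrition and survey-timing seasonality, item-level
dependence within exams, or measurement error correlated with treatment.
A green Monte-Carlo test therefore establishes that the estimator
recovers known effects under selection-on-observables with clustered
noise — not that the pipeline is robust to unobserved confounding or
instrument misbehaviour, which no test on synthetic data can establish.

Binary outcomes are drawn Bernoulli at the (clamped) linear mean and
estimated by a weighted linear probability model, matching the
percentage-point effect sizes of the source tables. When the noise SD is
explicitly set to 0 the generator returns the deterministic mean for
*every* outcome, binary included — a degenerate mode that exists to make
the zero-noise determinism contract testable.

One master seed expands into named per-stage substreams (covariates,
selection, outcomes, instruments), so stages are individually
reproducible and adding instruments does not perturb outcome draws.

## 5. Numerical conventions and degenerate inputs

* Probit oracle checks: intercept-only fits equal `Φ⁻¹(share)` in closed
  form; two-parameter fits beat an exhaustive 1e-3 grid around the
  optimum; multivariate fits agree with `glm(binomial("probit"))` to
  1e-6 (the glm route is used only as an independent oracle in tests).
* Collinear regressors are dropped by QR rank detection and reported in
  `$aliased`, never silently absorbed.
* Standardized bias with both variances zero is 0 when means are equal
  and an explicit error otherwise; zero reference SD makes
  `standardize()` fail rather than return infinities.
* Degenerate treatment assignment (an arm with fewer than two
  households), single clusters, constant outcomes, disjoint score
  supports, malformed month calendars and non-binary recall indicators
  all fail with classed, named errors (`ipwdid_error`).
* CSV round trips preserve values to write precision (15 significant
  digits); exam columns are named `exam_prod_*` / `exam_vita_*` so the
  item-block split survives a round trip without sidecar metadata.

## 6. Known limitations

* Inference treats the estimated propensity score as fixed; no correction
  for first-stage estimation error (common practice, but coverage
  statements lean on the Monte-Carlo evidence, not asymptotics).
* With ~30 clusters, CR1 + t(G−1) can still be mildly anti-conservative
  for heavily unbalanced cluster sizes.
* The linear probability model can fit probabilities outside [0, 1] for
  binary outcomes; effects remain interpretable as percentage points.
* Placebo tests detect selection expressed in baseline *levels*; they are
  silent about selection on trends, which is exactly what parallel trends
  assumes away.
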