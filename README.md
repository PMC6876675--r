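# ipwdid

Impact evaluation of nutrition-sensitive agricultural interventions on
two-wave household panels, for applied economists and biostatisticians who
need the full quasi-experimental pipeline — indicator construction,
propensity scores, matching diagnostics, and weighted difference-in-
differences with clustered inference — as tested, scriptable R functions.

## The problem and the estimator

Households self-select into development projects (here, the motivating
setting is a voucher scheme distributing virus-free, biofortified
orange-fleshed sweetpotato planting material), so endline comparisons of
participants and non-participants confound the intervention's effect with
selection. The package implements the standard two-stage answer:

1. **Selection model.** Participation `W` is modelled by a probit on
   pre-treatment covariates `z`:

   `W* = β'z + ϵ,  W = 1{W* > 0},  p = Φ(z'β)`

   with robust standard errors, average marginal effects, common-support
   trimming of scores near 0/1, and nearest-neighbour / radius /
   Epanechnikov-kernel matching with covariate-balance diagnostics
   (standardized bias, post-matching pseudo-R², LR test).

2. **Weighted DID.** On the support-retained sample, outcomes follow

   `y_it = α + λ t + θ W_i t + ρ W_i + γ' x_it + ε_it`

   estimated by least squares weighted by the inverse-probability weights
   `φ = 1/p` (treated) and `φ = 1/(1−p)` (control), with standard errors
   clustered at village level (CR1) and t(G−1) confidence intervals. The
   interaction coefficient `θ` is the average effect of participation.
   Placebo regressions of *baseline* outcomes on *endline* participation
   probe for residual selection.

Composite outcomes are built from raw instruments: knowledge exam scores
weighted by the inverse probability of a correct answer (harder questions
count more), household/child dietary diversity (HDDS, CDDS, 10-group FGDS,
6-group vitamin A diversity) from 24-hour recall, the food consumption
score (7-day frequencies, group sums capped at 7, WFP/HKI weights), and
food-security indicators (MIHFP month counts, relief-food months, asset
sales, coping-strategy index).

A synthetic panel generator (`dgp_config()` / `generate_panel()`) emulates
the study design — 434 households, two waves, 30 villages, selection on
observables with published-scale probit coefficients, outcome equations
with known effects — so every stage is testable end to end without survey
microdata.

## Worked example

```r
library(ipwdid)

panel <- generate_panel(dgp_config(seed = 3))   # synthetic two-wave panel
fit   <- fit_probit(panel)                      # participation probit
cs    <- common_support(fit$scores, fit$treated)
print(cs)
#> <common_support> [0.1645, 0.8505] (intersection); trimmed 6 treated, 11 control

keep <- fit$household_id[cs$keep]
phi  <- ipw_weights(fit$scores[cs$keep], fit$treated[cs$keep])

m   <- match_households(fit$scores[cs$keep], fit$treated[cs$keep], ids = keep)
bal <- balance_report(fit$design[cs$keep, -1], fit$treated[cs$keep],
                      m$weights$weight[match(keep, m$weights$id)])
print(bal$summary, digits = 3)
#>      sample mean_abs_bias pseudo_r2 lr_chi2     lr_p n_treated n_control
#> 1 unmatched         10.31    0.0732   42.29 0.000111       206       211
#> 2   matched          5.13    0.0097    5.54 0.976736       206       131

eff <- did_estimate(panel, "knowledge_production",
                    weights = data.frame(id = keep, weight = phi),
                    controls = panel$covariates$name, keep = keep)
#> DID effect 1.2663 (SE 1.8096), 95% CI [-2.4348, 4.9674], R2 0.091, n 834, clusters 30

placebo_test(panel, "relief_months",
             weights = data.frame(id = keep, weight = phi),
             controls = panel$covariates$name, keep = keep)
#> <placebo_result> baseline relief_months on endline participation
#> coefficient 0.2164 (SE 0.1309, p 0.109), R2 0.089, n 417, clusters 30
```

Reading the output: matching shrinks the mean absolute standardized bias
from 10.3% to 5.1% and the post-matching LR test no longer rejects joint
covariate significance (p = 0.98), so the score balances the observables.
The single-replicate DID estimate 1.27 (cluster SE 1.81) is one noisy draw
around the generating effect 2.154 — with ~30 clusters and an outcome SD of
11 score points, one panel of 434 households cannot pin the effect down;
the Monte-Carlo study in `scripts/acceptance.R` shows the estimator is
centred on the truth with ~95% CI coverage. The placebo coefficient on the
baseline outcome is statistically null, as it should be when selection
operates only on observables and modelled gaps.

`run_pipeline(run_config(...))` executes all stages from one configuration
and writes `indicators.csv`, `propensity.csv`, `balance.csv`,
`balance_summary.csv`, `effects_<outcome>.csv`, `placebo.csv`,
`support_hist.csv` and a JSON manifest. A CLI wrapper ships at
`inst/cli/ipwdid` (subcommands `simulate`, `score`, `match`, `estimate`,
`placebo`, `run-all`).

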