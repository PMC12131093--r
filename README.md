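# brscore

Should a personalized prognostic model with *limited* predictive performance
be turned into a clinical tool? Publishing a model is cheap; implementing it
changes patient behaviour, and a weak predictor can talk patients out of a
treatment they would actually have benefited from. `brscore` implements a
population-level benefit-risk framework for making that call explicitly,
aimed at clinical researchers and model developers weighing tool development
against current one-size-fits-all care.

## The model

A cohort of `N` patients is followed through four binary stages:

1. **a priori intent** — would the patient follow the recommended first-line
   treatment before seeing any personalized prediction?
2. **prediction** — does the model predict outcome improvement for them?
3. **participation** — do they actually receive the treatment, given how the
   prediction interacts with their intent?
4. **outcome** — would they benefit from the treatment (counterfactual
   would-benefit status, defined even for non-participants)?

This yields 16 terminal possibilities. Branching probabilities (willingness,
positive-prediction rate, four adherence cells, prediction correctness)
allocate the cohort into expected per-leaf counts `n_i`. Each leaf is scored
on one common additive scale with a triplet: benefit/harm points `B_i`,
placebo/nocebo points `PNE_i`, and side-effect points `SE_i`, all expressed
as deltas against the follow-own-intent comparator world. The Benefit-Risk
Score is

```
BRS = Σ_{i=1..16} n_i (B_i + PNE_i + SE_i)
```

`BRS > 0` recommends creating and implementing the tool; `BRS ≤ 0` recommends
refraining. Alongside the score the package reports the harmed subgroup —
a priori willing patients who forgo a treatment they would have benefited
from — and supports one-way sensitivity sweeps, decision-boundary threshold
search, partial (clinician-gatekept) implementation restricted to an intent
subgroup, an eleven-question pre-implementation checklist, and a
patient-level microsimulation oracle that cross-checks the analytic score.

## Worked example

The packaged scenario models 1000 patients with knee osteoarthritis offered
first-line patient education and exercise therapy, guided by a survey-based
prognostic model: half are a priori willing; improvement is predicted for
three-fourths; 29/30 follow a prediction confirming their intent; a positive
prediction converts half of the a priori decliners, a negative one fails to
deter one-third of the willing; and three-fifths of predictions are correct
regarding benefit.

```r
library(brscore)

oa  <- osteoarthritis_scenario()
res <- compute_brs(oa)
res
#> <brs_result> osteoarthritis
#>   cohort:        1000 patients
#>   total points:  832
#>   per capita:    0.832
#>   harmed:        40 (40 patients)
#>   decision:      implement
```

The score is 832 effect-points over 1000 patients (0.832 per capita), so
implementation is recommended — although 40 patients end up forgoing a
treatment they would have benefited from, which is what the partial
implementation mode is for:

```r
partial_implementation(oa, expose = "decliners")$total_points
#> [1] 646         # no harm leaves populated in this mode

sweep_brs(oa, "se_scale", c(1, 3))$total_points
#> [1]  832 1026   # side effects reweighted from +/-1 to +/-3
```

Results are tidyverse-friendly: `tidy(res)` returns the 16-row calculation
table (leaf attributes, `n`, `B`, `PNE`, `SE`, per-leaf points), `glance(res)`
the one-row summary, `autoplot(res)` a per-leaf contribution chart.
`export_table()` / `import_table()` round-trip the calculation table as CSV,
`load_scenario()` / `write_scenario()` do the same for YAML scenario configs
(exact fractions like `29/30` supported), and `inst/scripts/brs-cli.R`
exposes `run`, `example`, `sweep`, `threshold`, `partial`, `export` and
`checklist` subcommands from the shell.

See the vignette (`vignettes/benefit-risk-scoring.Rmd`) for the scoring
rules, the whole-patient rounding convention, and the framework's
assumptions and limitations.

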