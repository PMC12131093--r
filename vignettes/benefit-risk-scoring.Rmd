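---
title: "Benefit-risk scoring for personalized prognostic tools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benefit-risk scoring for personalized prognostic tools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brscore)
```

## The decision problem

A prognostic model that predicts a patient's outcome under a recommended
treatment can be published without much controversy. Turning it into a tool
that patients and clinicians consult is different: the communicated
prediction changes behaviour. A patient who was going to follow the
recommended treatment may skip it after a discouraging prediction; a patient
who was going to decline may be converted by an encouraging one. When the
model's accuracy is modest, some of those behaviour changes are driven by
wrong predictions, and a subset of patients is actively harmed — they forgo
a treatment that would have helped them. `brscore` quantifies this trade-off
at the population level and condenses it into a single signed score.

The comparator throughout is *one-size-fits-all care*: every patient receives
the population-level recommendation and follows their own a priori intent.
All effects are deltas against that world, which is why the framework never
subtracts a baseline score — unchanged behaviour contributes zero by
construction.

## The outcome tree

Four binary attributes define `2^4 = 16` terminal possibilities
(`brs_tree()`): a priori intent, predicted improvement, actual
participation, and the counterfactual *would-benefit* status under
treatment. Modelling the would-benefit status rather than the realised
outcome keeps the fourth attribute defined for non-participants; prediction
correctness is then simply agreement between the prediction and that status.

Leaves are indexed lexicographically (intent yes < no, prediction
improve < no-improve, participation yes < no, outcome benefit <
no-benefit), which makes the canonical index coincide with the `E1`–`E16`
labels of the standard tree figure; intermediate labels `B1`/`B2` and
`D1`–`D8` are carried as annotation columns. Three patterns matter most:

* the **harm leaves** (E3, E7): a willing patient forgoes a treatment they
  would have benefited from; E7 is the false-negative-driven case;
* the **top-benefit leaf** (E9): an a priori decliner converted by a
  positive prediction who then benefits;
* the **unlikely subtrees** (D2, D7): patients contradicting their own
  intent despite a confirming recommendation. They are retained in the
  tree and scored — their allocation mass is controlled by the adherence
  probabilities, not by fiat.

## Cohort allocation

`allocate()` multiplies the cohort size through the branching
probabilities: P(intent), P(prediction), P(participation | intent,
prediction) — four adherence cells — and P(would-benefit | prediction),
parameterised by a single correctness probability `p_correct` applied
symmetrically to both prediction signs. Two simplifying assumptions are
deliberate and documented: the prediction is independent of the a priori
intent (a correlation parameter is reserved in the config schema but
rejected until it has validated semantics), and adherence to a confirming
prediction is the same in both aligned cells (willing + positive and
declining + negative).

Two allocation conventions are provided:

* `"none"` (default): exact expected counts, generally fractional
  (e.g. 362.5 of 1000 patients willing, predicted-positive and treated in
  the worked example). Conservation holds to floating-point tolerance, the
  score is multilinear in the probabilities, and this is the mode the
  microsimulation oracle converges to.
* `"stagewise"`: whole patients at every tree node, the way a calculation
  sheet displays a cohort. At each binary split the first-listed child is
  rounded half-up and the sibling receives the complement, so conservation
  is exact by construction. The packaged osteoarthritis example pins this
  mode: its published totals (832 / 1026 effect-points, 40 harmed) are
  exact on whole-patient counts and unreachable on fractional ones — on
  the analytic allocation the same scenario scores 825 with an expected
  40.83 harmed patients.

`baseline_allocation()` gives the comparator world (participation = intent,
adherence ignored); it is a reporting reference, not an input to the score.

## Scoring rules

Each leaf carries a triplet on one additive scale; the user's contract is
scale coherence — if a benefit is three times the placebo effect, its
points must be three times the placebo points. `default_weights()` encodes
the rule-based defaults; every entry is overridable per leaf
(`brs_weights()`, `set_parameter()`).

* **Benefit/harm `B`**: 0 where the decision is unchanged; +3 / −3 where
  the tool flipped a decision toward / away from a treatment that would
  benefit; +1 / −1 where the flip only avoids wasted effort or only costs
  time (non-beneficial treatment avoided or received).
* **Placebo/nocebo `PNE`**: +1 for every participant under a positive
  prediction — tailored positive expectations strengthen the placebo
  effect regardless of true benefit status (the E10 pattern profits from
  placebo despite no physiological benefit). −1 for participants under a
  negative prediction *who would benefit*: the nocebo effect diminishes an
  improvement, so it needs an improvement to act on (the E5 pattern);
  participants with nothing to lose score 0. This asymmetry is a design
  choice of the package's default table: it is the narratively consistent
  assignment, and it is the assignment under which the packaged example
  reproduces its published totals. Alternative conventions (e.g. nocebo
  points for all participating negative-prediction leaves) are supported
  via weight overrides.
* **Side effects `SE`**: only decision flips change side-effect exposure
  relative to the comparator, so flipped-in participants gain the
  treatment's side-effect sign and flipped-out patients lose it. The
  side-effect `profile` ("positive" for exercise therapy, whose secondary
  effects on general health are favourable; "neutral"; "negative") sets
  the sign, and `se_scale` the magnitude — treatments whose side effects
  rival the primary outcome warrant ±3 rather than ±1.

The score is `compute_brs()`: total effect-points, per-capita value,
implement/refrain decision (strictly positive total implements; an exact
zero refrains with a boundary warning), and the harmed count — the
allocation mass on leaves where a willing patient forgoes a beneficial
treatment, reported both as the expected count and rounded to whole
patients. A `catastrophic` flag on any weight row vetoes implementation
outright when that leaf is populated: harms beyond trade-off (death-like
outcomes) are not allowed to be outweighed by points.

## Sensitivity, thresholds, partial implementation

`sweep_brs()` recomputes the score over a grid for any single probability,
adherence cell, per-leaf weight or column scale, and records sign
crossings. `brs_threshold()` finds the implement/refrain boundary: the
score is exactly linear in weight and scale parameters, so two evaluations
give the root in closed form; for probabilities it is multilinear, and a
bisection search is used with tolerance `1e-6 x cohort_size` (effect-point
totals are of order cohort size). Probability thresholds are always solved
on the analytic allocation — whole-patient rounding turns the score into a
step function, on which a root of the continuous score is the meaningful
quantity.

`partial_implementation()` models the clinician-gatekeeper deployment:
the tool is offered only to one a priori intent subgroup; everyone else
follows their own intent and contributes zero delta. Restricting exposure
to a priori decliners eliminates the harm and nocebo contributions
entirely (harm leaves require a willing patient) at the cost of the
willing subtree's placebo gains — in the worked example, 646 of the 832
effect-points survive with zero patients harmed. Adherence within the
exposed subgroup is kept unchanged; how gatekeeping itself shifts
adherence is not modelled.

## The microsimulation oracle

`microsim_oracle()` estimates the score without the allocation machinery:
`M` synthetic patients are drawn through the tree by sequential Bernoulli
draws, each contributes its leaf's `B + PNE + SE`, and the mean is rescaled
to the cohort. It shares no code with `allocate()` and converges to the
analytic fractional-allocation score at the Monte-Carlo `M^(-1/2)` rate,
which the test suite checks at `M` of 10^3 to 2x10^5 together with a
chi-square goodness-of-fit of the 16 leaf frequencies. Passing these checks
validates the allocation algebra — it says nothing about whether the
assumed probabilities and weights describe any real clinic, which is
exactly the caveat the checklist is for.

## Synthetic scenarios and what they do not show

`random_scenario()` draws branching probabilities uniformly on [0, 1],
cohort sizes uniformly on 100–5000, and weights from the discrete palette
(`B` in {−3, −1, 0, 1, 3}; `PNE`, `SE` in {−1, 0, 1}) — the full valid
input space of the framework rather than any clinical reality. Property
tests over these scenarios (conservation, linearity, additivity over the
intent partition, oracle agreement) exercise the arithmetic contracts.
Real applications differ in ways no such test touches: probabilities are
correlated (willingness and predicted benefit rarely independent),
outcomes are not binary, one clinical outcome rarely suffices, and the
weights are subjective estimates. The framework is an idealised utilitarian
yardstick; the checklist (`brs_checklist()`, eleven questions spanning the
calculation inputs and tool/personal/institutional/external barriers)
is the intended entry point before trusting any single number.

## Numerical conventions

Counts print to one decimal and effect-point totals as integers when within
1e-9 of one; stored values are never rounded. Scenario YAML accepts exact
fraction strings (`29/30`); CSV exports write doubles as `%.17g` and
re-import through the correctly-rounded base-R parser, so export/import
round trips are bit-identical. Whole-patient rounding uses half-away-from-
zero (spreadsheet convention), not banker's rounding. Test-suite problem
sizes: 1000 random scenarios for conservation, 20 plus the worked example
for the 200,000-patient oracle comparison, three grid sizes for the
convergence-rate check.

## Limitations

The framework compares one personalized tool against one one-size-fits-all
recommendation — no multi-treatment or shared-decision extensions; a single
binarized clinical outcome; independence of prediction and intent; additive
population-level aggregation with no distributional weighting beyond the
catastrophic veto. These are properties of the method, faithfully
implemented, not of any particular dataset.
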