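# Worked example: knee osteoarthritis, first-line patient education and
# exercise therapy guided by a survey-based personalized prognostic model.
# The allocation keeps whole patients at every tree node (stagewise),
# the convention under which the expected totals below are exact; on
# analytic fractional counts the same scenario scores 825 effect-points
# with an expected 40.833 harmed patients.
name: osteoarthritis
notes: >-
  1000 patients; half a priori willing; improvement predicted for 3/4;
  29/30 follow an intent-confirming prediction; a positive prediction
  converts 1/2 of decliners; a negative prediction fails to deter 1/3 of
  the willing; 3/5 of predictions correct regarding benefit. Weights are
  the rule-derived defaults with a positive side-effect profile
  (exercise therapy).
cohort_size: 1000
allocation_rounding: stagewise
probabilities:
  p_intent: 1/2
  p_positive: 3/4
  p_correct: 3/5
adherence:
  willing_positive: 29/30
  willing_negative: 1/3
  decliner_positive: 1/2
  decliner_negative: 1/30
weights:
  - {leaf: 1, B: 0, PNE: 1, SE: 0}     # willing, positive, treated, benefits: placebo only
  - {leaf: 2, B: 0, PNE: 1, SE: 0}
  - {leaf: 3, B: -3, PNE: 0, SE: -1}   # harm: talked out of a beneficial treatment
  - {leaf: 4, B: 1, PNE: 0, SE: -1}    # avoided wasted effort
  - {leaf: 5, B: 0, PNE: -1, SE: 0}    # E5: nocebo diminishes a real improvement
  - {leaf: 6, B: 0, PNE: 0, SE: 0}
  - {leaf: 7, B: -3, PNE: 0, SE: -1}   # E7: harm via false-negative prediction
  - {leaf: 8, B: 1, PNE: 0, SE: -1}
  - {leaf: 9, B: 3, PNE: 1, SE: 1}     # E9: converted decliner who benefits
  - {leaf: 10, B: -1, PNE: 1, SE: 1}   # E10: wasted time, but placebo and side effects
  - {leaf: 11, B: 0, PNE: 0, SE: 0}
  - {leaf: 12, B: 0, PNE: 0, SE: 0}
  - {leaf: 13, B: 3, PNE: -1, SE: 1}
  - {leaf: 14, B: -1, PNE: 0, SE: 1}
  - {leaf: 15, B: 0, PNE: 0, SE: 0}
  - {leaf: 16, B: 0, PNE: 0, SE: 0}
expected:
  total_points: 832
  se3_total_points: 1026
  harmed_n: 40
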