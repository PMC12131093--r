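# shared scenario builders for the test suite

# adherence cells that make every patient follow their own intent
no_flip_adherence <- c(
  willing_positive = 1, willing_negative = 1,
  decliner_positive = 0, decliner_negative = 0
)

make_assumptions <- function(cohort_size = 1000,
                             p_intent = 1 / 2,
                             p_positive = 3 / 4,
                             adherence = c(
                               willing_positive = 29 / 30,
                               willing_negative = 1 / 3,
                               decliner_positive = 1 / 2,
                               decliner_negative = 1 / 30
                             ),
                             p_correct = 3 / 5) {
  brs_assumptions(cohort_size, p_intent, p_positive, adherence, p_correct)
}

zero_weights <- function() {
  tibble::tibble(leaf = 1:16, B = 0, PNE = 0, SE = 0)
}

# analytic leaf probability, independent of allocate(): direct product
leaf_probability <- function(a, intent, prediction, participation, outcome) {
  p_i <- if (intent == "yes") a$p_intent else 1 - a$p_intent
  p_p <- if (prediction == "improve") a$p_positive else 1 - a$p_positive
  cell <- paste0(
    if (intent == "yes") "willing" else "decliner",
    if (prediction == "improve") "_positive" else "_negative"
  )
  p_t <- if (participation == "yes") a$adherence[[cell]] else 1 - a$adherence[[cell]]
  p_b <- if (prediction == "improve") a$p_correct else 1 - a$p_correct
  p_o <- if (outcome == "benefit") p_b else 1 - p_b
  p_i * p_p * p_t * p_o
}
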