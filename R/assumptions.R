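#' Branching assumptions for cohort allocation
#'
#' Bundles the probabilities that allocate a patient cohort across the
#' 16-leaf outcome tree.
#'
#' @param cohort_size Number of patients (positive; fractional allowed).
#' @param p_intent Probability that a patient is a priori willing to follow
#'   the recommended treatment.
#' @param p_positive Probability that the model predicts improvement.
#' @param adherence Named numeric vector of participation probabilities, one
#'   per intent x prediction cell:
#'   `willing_positive`, `willing_negative`, `decliner_positive`,
#'   `decliner_negative`. Each is P(participate | intent, prediction): e.g.
#'   `willing_positive` close to 1 means willing patients almost always
#'   follow a confirming positive prediction, while `decliner_positive` is
#'   the conversion rate of a priori decliners by a positive prediction.
#' @param p_correct Probability that a prediction is correct regarding the
#'   benefit: P(would-benefit | prediction = improve) = `p_correct` and
#'   P(would-benefit | prediction = no_improve) = `1 - p_correct`.
#' @param intent_prediction_correlation Reserved. The framework assumes the
#'   prediction is independent of the a priori intent; only `NULL` or `0`
#'   are accepted until validated semantics for a correlation exist.
#'
#' @return An object of class `brs_assumptions` (a named list).
#' @examples
#' brs_assumptions(
#'   cohort_size = 1000, p_intent = 1 / 2, p_positive = 3 / 4,
#'   adherence = c(
#'     willing_positive = 29 / 30, willing_negative = 1 / 3,
#'     decliner_positive = 1 / 2, decliner_negative = 1 / 30
#'   ),
#'   p_correct = 3 / 5
#' )
#' @export
brs_assumptions <- function(cohort_size,
                            p_intent,
                            p_positive,
                            adherence,
                            p_correct,
                            intent_prediction_correlation = NULL) {
  if (!is.numeric(cohort_size) || length(cohort_size) != 1 ||
      !is.finite(cohort_size) || cohort_size <= 0) {
    rlang::abort("`cohort_size` must be a single positive number.")
  }
  check_prob(p_intent, "p_intent")
  check_prob(p_positive, "p_positive")
  check_prob(p_correct, "p_correct")
  cells <- c("willing_positive", "willing_negative",
             "decliner_positive", "decliner_negative")
  if (!is.numeric(adherence) || !all(cells %in% names(adherence))) {
    rlang::abort(paste0(
      "`adherence` must be a named numeric vector with cells: ",
      paste(cells, collapse = ", "), "."
    ))
  }
  adherence <- adherence[cells]
  for (cell in cells) check_prob(adherence[[cell]], paste0("adherence[", cell, "]"))
  if (!is.null(intent_prediction_correlation) &&
      !isTRUE(all.equal(intent_prediction_correlation, 0))) {
    rlang::abort(paste0(
      "A nonzero intent-prediction correlation is not supported: the ",
      "allocation assumes the prediction is independent of the a priori ",
      "intent. Set `intent_prediction_correlation = NULL` (or 0)."
    ))
  }
  structure(
    list(
      cohort_size = as.numeric(cohort_size),
      p_intent    = as.numeric(p_intent),
      p_positive  = as.numeric(p_positive),
      adherence   = stats::setNames(as.numeric(adherence), cells),
      p_correct   = as.numeric(p_correct)
    ),
    class = "brs_assumptions"
  )
}

check_prob <- function(x, name, call = rlang::caller_env()) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
    rlang::abort(
      sprintf("`%s` must be a single probability in [0, 1] (got %s).",
              name, paste(format(x), collapse = ", ")),
      call = call
    )
  }
  invisible(x)
}

#' @export
print.brs_assumptions <- function(x, ...) {
  cat("<brs_assumptions>\n")
  cat(sprintf("  cohort_size: %s\n", format(x$cohort_size)))
  cat(sprintf("  p_intent:    %.6g   p_positive: %.6g   p_correct: %.6g\n",
              x$p_intent, x$p_positive, x$p_correct))
  cat("  adherence (P[participate | intent, prediction]):\n")
  for (cell in names(x$adherence)) {
    cat(sprintf("    %-18s %.6g\n", cell, x$adherence[[cell]]))
  }
  invisible(x)
}
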