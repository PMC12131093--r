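#' Allocate a cohort across the outcome tree
#'
#' Computes the expected number of patients `n` in each of the 16 leaves
#' from the branching assumptions. In the default analytic mode each leaf
#' receives
#'
#' `n = cohort_size x P(intent) x P(prediction) x
#'      P(participation | intent, prediction) x P(outcome | prediction)`
#'
#' which is generally fractional; the total is conserved exactly.
#'
#' `rounding = "stagewise"` instead walks the tree level by level keeping
#' whole patients at every node, the way a calculation sheet displays the
#' cohort: at each binary split the first-listed branch (intent yes,
#' prediction improve, participation yes, outcome benefit) is rounded
#' half-up to an integer and the sibling receives the complement, so
#' conservation is exact by construction. The packaged osteoarthritis
#' example uses this mode; its printed totals are only reproducible on
#' whole-patient counts.
#'
#' @param tree A 16-leaf table from [brs_tree()] (or any table carrying the
#'   full canonical leaf set).
#' @param assumptions A [brs_assumptions()] object.
#' @param rounding `"none"` (analytic expected counts, default) or
#'   `"stagewise"` (whole patients at every tree node).
#' @return The tree as a tibble with a numeric `n` column appended;
#'   `sum(n)` equals `cohort_size`.
#' @examples
#' oa <- osteoarthritis_scenario()
#' allocate(brs_tree(), oa$assumptions)
#' allocate(brs_tree(), oa$assumptions, rounding = "stagewise")
#' @export
allocate <- function(tree, assumptions, rounding = c("none", "stagewise")) {
  rounding <- rlang::arg_match(rounding)
  stopifnot(inherits(assumptions, "brs_assumptions"))
  tree <- tibble::as_tibble(tree)
  validate_full_tree(tree)
  a <- assumptions

  if (rounding == "none") {
    out <- dplyr::mutate(
      tree,
      n = a$cohort_size *
        ifelse(.data$intent == "yes", a$p_intent, 1 - a$p_intent) *
        ifelse(.data$prediction == "improve", a$p_positive, 1 - a$p_positive) *
        adherence_prob(a, .data$intent, .data$prediction, .data$participation) *
        outcome_prob(a, .data$prediction, .data$outcome)
    )
    return(out)
  }

  # stagewise: integer counts at every node, complement keeps conservation
  split2 <- function(n, p) {
    first <- floor(n * p + 0.5)  # round half away from zero (n, p >= 0)
    c(first, n - first)
  }
  counts <- numeric(16)
  n_int <- split2(a$cohort_size, a$p_intent)
  for (i in 1:2) {              # intent: yes, no
    n_prd <- split2(n_int[i], a$p_positive)
    for (p in 1:2) {            # prediction: improve, no_improve
      cell <- adherence_cell(i == 1, p == 1)
      n_prt <- split2(n_prd[p], a$adherence[[cell]])
      for (t in 1:2) {          # participation: yes, no
        p_ben <- if (p == 1) a$p_correct else 1 - a$p_correct
        n_out <- split2(n_prt[t], p_ben)
        base <- (i - 1) * 8 + (p - 1) * 4 + (t - 1) * 2
        counts[base + 1:2] <- n_out
      }
    }
  }
  key <- paste(tree$intent, tree$prediction, tree$participation, tree$outcome)
  dplyr::mutate(tree, n = counts[match(key, brs_tree_keys())])
}

adherence_cell <- function(willing, positive) {
  paste0(
    ifelse(willing, "willing", "decliner"),
    ifelse(positive, "_positive", "_negative")
  )
}

adherence_prob <- function(a, intent, prediction, participation) {
  cell <- adherence_cell(intent == "yes", prediction == "improve")
  p_yes <- unname(a$adherence[cell])
  ifelse(participation == "yes", p_yes, 1 - p_yes)
}

outcome_prob <- function(a, prediction, outcome) {
  p_ben <- ifelse(prediction == "improve", a$p_correct, 1 - a$p_correct)
  ifelse(outcome == "benefit", p_ben, 1 - p_ben)
}

#' Comparator allocation without the prognostic tool
#'
#' Allocates the cohort as under the current one-size-fits-all
#' recommendation: every patient simply follows their a priori intent, so
#' participation equals intent with probability 1 and the adherence cells
#' are ignored. Predictions are still drawn (the model exists but is not
#' communicated), so leaf counts remain comparable with [allocate()].
#'
#' This is a reporting reference only: the effect weights are already
#' expressed as deltas against this follow-own-intent world, so the
#' Benefit-Risk Score never subtracts a baseline score.
#'
#' @inheritParams allocate
#' @return The tree as a tibble with an `n` column; all mass sits on leaves
#'   with `participation == intent`.
#' @examples
#' baseline_allocation(brs_tree(), osteoarthritis_scenario()$assumptions)
#' @export
baseline_allocation <- function(tree, assumptions) {
  stopifnot(inherits(assumptions, "brs_assumptions"))
  tree <- tibble::as_tibble(tree)
  validate_full_tree(tree)
  a <- assumptions
  dplyr::mutate(
    tree,
    n = a$cohort_size *
      ifelse(.data$intent == "yes", a$p_intent, 1 - a$p_intent) *
      ifelse(.data$prediction == "improve", a$p_positive, 1 - a$p_positive) *
      ifelse(.data$participation == .data$intent, 1, 0) *
      outcome_prob(a, .data$prediction, .data$outcome)
  )
}
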