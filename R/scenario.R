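#' Bundle assumptions and weights into a scenario
#'
#' A scenario is the complete, self-contained input to a Benefit-Risk Score
#' calculation: branching assumptions, a per-leaf weight table, and the
#' allocation rounding convention.
#'
#' @param assumptions A [brs_assumptions()] object.
#' @param weights A per-leaf weight table (columns `leaf`, `B`, `PNE`, `SE`,
#'   optionally `catastrophic`), e.g. a [default_weights()] result.
#' @param name Optional scenario name used in printing and exports.
#' @param allocation_rounding `"none"` for analytic expected counts or
#'   `"stagewise"` for whole-patient counts at every tree node (see
#'   [allocate()]).
#' @param notes Optional free-text provenance notes.
#' @return An object of class `brs_scenario`.
#' @examples
#' tree <- brs_tree()
#' sc <- brs_scenario(
#'   assumptions = brs_assumptions(
#'     cohort_size = 500, p_intent = 0.4, p_positive = 0.6,
#'     adherence = c(
#'       willing_positive = 0.9, willing_negative = 0.5,
#'       decliner_positive = 0.3, decliner_negative = 0.1
#'     ),
#'     p_correct = 0.7
#'   ),
#'   weights = default_weights(tree)
#' )
#' compute_brs(sc)
#' @export
brs_scenario <- function(assumptions, weights, name = "scenario",
                         allocation_rounding = c("none", "stagewise"),
                         notes = NULL) {
  allocation_rounding <- rlang::arg_match(allocation_rounding)
  stopifnot(inherits(assumptions, "brs_assumptions"))
  weights <- tibble::as_tibble(weights)
  keep <- intersect(c("leaf", "B", "PNE", "SE", "catastrophic"), names(weights))
  weights <- weights[keep]
  # validate by joining against the canonical tree
  invisible(brs_weights(brs_tree(), weights))
  structure(
    list(
      name = name,
      assumptions = assumptions,
      weights = weights,
      allocation_rounding = allocation_rounding,
      notes = notes
    ),
    class = "brs_scenario"
  )
}

#' Per-leaf calculation table for a scenario
#'
#' Runs the full pipeline — tree enumeration, classification, cohort
#' allocation and weight attachment — and returns the 16-row calculation
#' table, one row per possibility, with the per-leaf contribution
#' `points = n * (B + PNE + SE)`.
#'
#' @param scenario A [brs_scenario()].
#' @param rounding Override the scenario's allocation rounding (`"none"` or
#'   `"stagewise"`); `NULL` uses the scenario's own convention.
#' @return A 16-row tibble with leaf attributes, classification flags, `n`,
#'   `B`, `PNE`, `SE` and `points`.
#' @examples
#' brs_calculation(osteoarthritis_scenario())
#' @export
brs_calculation <- function(scenario, rounding = NULL) {
  stopifnot(inherits(scenario, "brs_scenario"))
  rounding <- rounding %||% scenario$allocation_rounding
  tab <- allocate(brs_tree(), scenario$assumptions, rounding = rounding)
  tab <- brs_weights(tab, scenario$weights)
  dplyr::mutate(tab, points = .data$n * (.data$B + .data$PNE + .data$SE))
}

#' @export
print.brs_scenario <- function(x, ...) {
  cat(sprintf("<brs_scenario> %s\n", x$name))
  print(x$assumptions)
  cat(sprintf("  allocation rounding: %s\n", x$allocation_rounding))
  nz <- sum(x$weights$B != 0 | x$weights$PNE != 0 | x$weights$SE != 0)
  cat(sprintf("  weights: %d of 16 leaves carry non-zero effect-points\n", nz))
  if (!is.null(x$notes)) cat(sprintf("  notes: %s\n", x$notes))
  invisible(x)
}

# modify one named parameter of a scenario; used by sweeps and thresholds
#' Set a scenario parameter by name
#'
#' Addresses a probability or weight parameter of a scenario by a compact
#' name, returning a modified copy. Recognised names:
#'
#' * probabilities: `"p_intent"`, `"p_positive"`, `"p_correct"`,
#'   `"adherence_willing_positive"`, `"adherence_willing_negative"`,
#'   `"adherence_decliner_positive"`, `"adherence_decliner_negative"`;
#' * `"cohort_size"`;
#' * column scales: `"b_scale"`, `"pne_scale"`, `"se_scale"` — multiply the
#'   corresponding weight column of the scenario's table by `value`
#'   (relative to the stored signs, i.e. `se_scale = 3` turns +/-1 side
#'   effects into +/-3);
#' * single leaf weights: `"B_7"`, `"PNE_5"`, `"SE_12"` etc.
#'
#' @param scenario A [brs_scenario()].
#' @param parameter Parameter name (see above).
#' @param value New value (probability in \[0, 1\] for probability
#'   parameters).
#' @return A modified `brs_scenario`.
#' @export
set_parameter <- function(scenario, parameter, value) {
  stopifnot(inherits(scenario, "brs_scenario"))
  a <- scenario$assumptions
  w <- scenario$weights
  scales <- c(b_scale = "B", pne_scale = "PNE", se_scale = "SE")

  if (parameter %in% c("p_intent", "p_positive", "p_correct", "cohort_size")) {
    args <- list(
      cohort_size = a$cohort_size, p_intent = a$p_intent,
      p_positive = a$p_positive, adherence = a$adherence,
      p_correct = a$p_correct
    )
    args[[parameter]] <- value
    scenario$assumptions <- do.call(brs_assumptions, args)
  } else if (grepl("^adherence_", parameter)) {
    cell <- sub("^adherence_", "", parameter)
    if (!cell %in% names(a$adherence)) {
      rlang::abort(sprintf("Unknown adherence cell `%s`.", cell))
    }
    adh <- a$adherence
    adh[[cell]] <- value
    scenario$assumptions <- brs_assumptions(
      a$cohort_size, a$p_intent, a$p_positive, adh, a$p_correct
    )
  } else if (parameter %in% names(scales)) {
    col <- scales[[parameter]]
    base <- attr(w, paste0("base_", col)) %||% w[[col]]
    w[[col]] <- base * value
    attr(w, paste0("base_", col)) <- base
    scenario$weights <- w
  } else if (grepl("^(B|PNE|SE)_([0-9]+)$", parameter)) {
    col <- sub("_.*$", "", parameter)
    i <- as.integer(sub("^.*_", "", parameter))
    if (!i %in% 1:16) rlang::abort("Leaf index must be in 1-16.")
    w[[col]][w$leaf == i] <- value
    scenario$weights <- w
  } else {
    rlang::abort(sprintf("Unknown parameter `%s`.", parameter))
  }
  scenario
}

# current value of a named parameter
get_parameter <- function(scenario, parameter) {
  a <- scenario$assumptions
  if (parameter %in% c("p_intent", "p_positive", "p_correct", "cohort_size")) {
    return(a[[parameter]])
  }
  if (grepl("^adherence_", parameter)) {
    cell <- sub("^adherence_", "", parameter)
    if (cell %in% names(a$adherence)) return(unname(a$adherence[[cell]]))
  }
  if (parameter %in% c("b_scale", "pne_scale", "se_scale")) return(1)
  if (grepl("^(B|PNE|SE)_([0-9]+)$", parameter)) {
    col <- sub("_.*$", "", parameter)
    i <- as.integer(sub("^.*_", "", parameter))
    if (i %in% 1:16) return(scenario$weights[[col]][scenario$weights$leaf == i])
  }
  rlang::abort(sprintf("Unknown parameter `%s`.", parameter))
}

# probability-valued parameters (domain [0, 1])
is_probability_parameter <- function(parameter) {
  parameter %in% c("p_intent", "p_positive", "p_correct") ||
    grepl("^adherence_", parameter)
}
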