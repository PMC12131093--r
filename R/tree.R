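#' Enumerate the 16-leaf outcome tree
#'
#' Builds the full decision tree of patient possibilities that follow the
#' introduction of a personalized prognostic tool. Each leaf is one
#' combination of four binary attributes:
#'
#' * `intent` — whether the patient was a priori willing to follow the
#'   recommended first-line treatment (`"yes"` / `"no"`);
#' * `prediction` — whether the model predicts outcome improvement for this
#'   patient (`"improve"` / `"no_improve"`);
#' * `participation` — whether the patient actually receives the treatment
#'   (`"yes"` / `"no"`);
#' * `outcome` — the patient's counterfactual benefit status under treatment
#'   (`"benefit"` / `"no_benefit"`). Modelling the *would-benefit* status
#'   (rather than the realised outcome) keeps the attribute defined for
#'   non-participants, which is what makes "forgoing a treatment that would
#'   have helped" expressible.
#'
#' Leaves are indexed 1–16 in canonical lexicographic order (`intent`
#' yes < no, `prediction` improve < no_improve, `participation` yes < no,
#' `outcome` benefit < no_benefit). Under this ordering the canonical index
#' coincides with the `E1`–`E16` terminal labels of the tree figure commonly
#' drawn for this framework; the internal node labels (`B1`/`B2` for intent,
#' `D1`–`D8` for intent x prediction x participation) are carried as
#' annotation columns.
#'
#' @return A tibble with 16 rows and columns `leaf`, `intent`, `prediction`,
#'   `participation`, `outcome`, the figure labels `node`, `d_node`,
#'   `b_node`, and the classification flag columns added by
#'   [classify_leaves()].
#' @seealso [classify_leaves()] for the derived flags.
#' @examples
#' brs_tree()
#' @export
brs_tree <- function() {
  tree <- tidyr::expand_grid(
    intent        = c("yes", "no"),
    prediction    = c("improve", "no_improve"),
    participation = c("yes", "no"),
    outcome       = c("benefit", "no_benefit")
  )
  tree <- dplyr::mutate(
    tree,
    leaf   = dplyr::row_number(),
    node   = paste0("E", .data$leaf),
    d_node = paste0("D", (.data$leaf - 1L) %/% 2L + 1L),
    b_node = ifelse(.data$intent == "yes", "B1", "B2"),
    .before = 1L
  )
  classify_leaves(tree)
}

#' Classify outcome-tree leaves
#'
#' Adds the derived classification flags to a table of leaves. All flags are
#' pure functions of the four binary attributes:
#'
#' * `aligned` — participation matches the a priori intent (the tool did not
#'   change what the patient does); `flipped` is its negation.
#' * `placebo_affected` — the patient participates under an improvement
#'   prediction, so positive personalized expectations can strengthen the
#'   placebo effect.
#' * `nocebo_affected` — the patient participates despite a no-improvement
#'   prediction, so negative expectations can act on the outcome.
#' * `harm_leaf` — an a priori willing patient forgoes treatment they would
#'   have benefited from (the most severely affected group; the E7 pattern).
#' * `top_benefit_leaf` — an a priori decliner converted to treatment who
#'   then benefits (the E9 pattern, the highest positive impact of the tool).
#' * `unlikely` — the decision contradicts both the patient's intent and an
#'   aligned recommendation (the D2/D7 subtrees), e.g. a willing patient who
#'   declines despite a favourable prediction.
#'
#' @param leaves A data frame with character columns `intent` (`"yes"`/`"no"`),
#'   `prediction` (`"improve"`/`"no_improve"`), `participation`
#'   (`"yes"`/`"no"`) and `outcome` (`"benefit"`/`"no_benefit"`).
#' @return The input as a tibble with logical columns `aligned`, `flipped`,
#'   `placebo_affected`, `nocebo_affected`, `harm_leaf`, `top_benefit_leaf`
#'   and `unlikely` appended (recomputed if already present).
#' @examples
#' library(tibble)
#' classify_leaves(tibble(
#'   intent = "yes", prediction = "no_improve",
#'   participation = "no", outcome = "benefit"
#' ))
#' @export
classify_leaves <- function(leaves) {
  leaves <- tibble::as_tibble(leaves)
  validate_leaf_attributes(leaves)
  dplyr::mutate(
    leaves,
    aligned          = .data$participation == .data$intent,
    flipped          = !.data$aligned,
    placebo_affected = .data$participation == "yes" & .data$prediction == "improve",
    nocebo_affected  = .data$participation == "yes" & .data$prediction == "no_improve",
    harm_leaf        = .data$intent == "yes" & .data$participation == "no" &
      .data$outcome == "benefit",
    top_benefit_leaf = .data$intent == "no" & .data$participation == "yes" &
      .data$outcome == "benefit",
    unlikely = (.data$intent == "yes" & .data$prediction == "improve" &
                  .data$participation == "no") |
      (.data$intent == "no" & .data$prediction == "no_improve" &
         .data$participation == "yes")
  )
}

# attribute levels shared by validators and the allocator
.brs_levels <- list(
  intent        = c("yes", "no"),
  prediction    = c("improve", "no_improve"),
  participation = c("yes", "no"),
  outcome       = c("benefit", "no_benefit")
)

validate_leaf_attributes <- function(leaves, call = rlang::caller_env()) {
  for (col in names(.brs_levels)) {
    if (!col %in% names(leaves)) {
      rlang::abort(
        sprintf("Leaf table is missing required column `%s`.", col),
        call = call
      )
    }
    bad <- setdiff(unique(leaves[[col]]), .brs_levels[[col]])
    if (length(bad) > 0) {
      rlang::abort(
        sprintf(
          "Invalid value%s in `%s`: %s. Allowed: %s.",
          if (length(bad) > 1) "s" else "", col,
          paste0("\"", bad, "\"", collapse = ", "),
          paste0("\"", .brs_levels[[col]], "\"", collapse = ", ")
        ),
        call = call
      )
    }
  }
  invisible(leaves)
}

# check that a table carries the complete canonical 16-leaf set
validate_full_tree <- function(data, call = rlang::caller_env()) {
  validate_leaf_attributes(data, call = call)
  key <- paste(data$intent, data$prediction, data$participation, data$outcome)
  ref <- brs_tree_keys()
  if (nrow(data) != 16L || !setequal(key, ref) || anyDuplicated(key) > 0) {
    rlang::abort(
      "Expected exactly the 16 canonical leaves (each attribute combination once).",
      call = call
    )
  }
  invisible(data)
}

brs_tree_keys <- function() {
  g <- tidyr::expand_grid(
    intent        = c("yes", "no"),
    prediction    = c("improve", "no_improve"),
    participation = c("yes", "no"),
    outcome       = c("benefit", "no_benefit")
  )
  paste(g$intent, g$prediction, g$participation, g$outcome)
}
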