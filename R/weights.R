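#' Rule-based default effect weights
#'
#' Derives the per-leaf effect-point triplet (`B`, `PNE`, `SE`) from the
#' leaf classification, encoding the scoring rules of the framework. All
#' weights are deltas against the follow-own-intent comparator world, on
#' one common additive scale:
#'
#' * **Benefit/harm `B`** — leaves where the tool did not change the
#'   decision score 0. A decision flipped *into* treatment that would
#'   benefit scores +3 (the top-benefit pattern); flipped *away from*
#'   treatment that would have benefited scores -3 (the harm pattern).
#'   Flips whose only consequence is avoided wasted effort (out of a
#'   non-beneficial treatment) score +1, and flips that only consume time
#'   (into a non-beneficial treatment) score -1.
#' * **Placebo/nocebo `PNE`** — participants under an improvement
#'   prediction gain +1 (personalized positive expectations strengthen the
#'   placebo effect, whatever the true benefit status). Participants under
#'   a no-improvement prediction lose -1 *if they would benefit*: the
#'   nocebo effect diminishes an improvement, so it needs an improvement to
#'   act on. Non-participants score 0.
#' * **Side effects `SE`** — only decision flips change side-effect
#'   exposure relative to the comparator. With a `"positive"` side-effect
#'   profile (e.g. exercise therapy, whose secondary effects on general
#'   health are favourable), flipping into treatment scores +1 and flipping
#'   out -1; a `"negative"` profile reverses the signs; `"neutral"` zeroes
#'   them. `se_scale` rescales the column (e.g. 3 for a treatment whose
#'   side effects weigh as much as the primary benefit).
#'
#' @param tree A classified leaf table from [brs_tree()].
#' @param profile Side-effect profile of the treatment for participants:
#'   `"positive"`, `"neutral"` or `"negative"`.
#' @param placebo Logical; whether communicated predictions can move the
#'   outcome through expectation effects. `FALSE` zeroes the `PNE` column.
#' @param se_scale Positive multiplier for the side-effect column.
#' @return The input tibble with numeric columns `B`, `PNE`, `SE` appended.
#' @examples
#' default_weights(brs_tree(), profile = "positive")
#' @export
default_weights <- function(tree, profile = c("positive", "neutral", "negative"),
                            placebo = TRUE, se_scale = 1) {
  profile <- rlang::arg_match(profile)
  if (!is.numeric(se_scale) || length(se_scale) != 1 || se_scale < 0) {
    rlang::abort("`se_scale` must be a single non-negative number.")
  }
  tree <- classify_leaves(tree)
  se_sign <- switch(profile, positive = 1, neutral = 0, negative = -1)
  dplyr::mutate(
    tree,
    B = dplyr::case_when(
      aligned                                        ~ 0,
      participation == "yes" & outcome == "benefit"  ~ 3,   # converted, benefits
      participation == "no" & outcome == "benefit"   ~ -3,  # forgoes real benefit
      participation == "no"                          ~ 1,   # avoided wasted effort
      TRUE                                           ~ -1   # wasted time
    ),
    PNE = dplyr::case_when(
      !placebo                                      ~ 0,
      placebo_affected                              ~ 1,
      nocebo_affected & outcome == "benefit"        ~ -1,
      TRUE                                          ~ 0
    ),
    SE = se_scale * se_sign *
      dplyr::case_when(
        flipped & participation == "yes" ~ 1,
        flipped & participation == "no"  ~ -1,
        TRUE                             ~ 0
      )
  )
}

#' Attach or validate a manual weight table
#'
#' Joins user-supplied per-leaf weights onto a leaf table. Weights must be
#' given for every canonical leaf exactly once, keyed by `leaf` index. A
#' logical `catastrophic` column may mark leaves whose harm is considered
#' beyond trade-off (e.g. death-like outcomes); [decide()] vetoes
#' implementation whenever such a leaf carries patients, regardless of the
#' score.
#'
#' @param tree A leaf table from [brs_tree()].
#' @param weights A data frame with columns `leaf`, `B`, `PNE`, `SE` (and
#'   optionally `catastrophic`), one row per leaf 1–16.
#' @return The tree tibble with the weight columns joined.
#' @export
brs_weights <- function(tree, weights) {
  tree <- tibble::as_tibble(tree)
  validate_full_tree(tree)
  weights <- tibble::as_tibble(weights)
  needed <- c("leaf", "B", "PNE", "SE")
  missing <- setdiff(needed, names(weights))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "Weight table is missing column(s): ", paste(missing, collapse = ", "), "."
    ))
  }
  if (!setequal(weights$leaf, 1:16) || nrow(weights) != 16L) {
    rlang::abort("Weight table must have one row per leaf index 1-16.")
  }
  for (col in c("B", "PNE", "SE")) {
    if (!is.numeric(weights[[col]]) || any(!is.finite(weights[[col]]))) {
      rlang::abort(sprintf("Weight column `%s` must be finite numeric.", col))
    }
  }
  keep <- intersect(c("leaf", "B", "PNE", "SE", "catastrophic"), names(weights))
  dplyr::left_join(
    dplyr::select(tree, -dplyr::any_of(c("B", "PNE", "SE", "catastrophic"))),
    weights[keep],
    by = "leaf"
  )
}
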