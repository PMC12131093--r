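#' Packaged osteoarthritis worked example
#'
#' Loads the packaged scenario for the knee-osteoarthritis first-line
#' treatment (patient education and exercise therapy) guided by a
#' survey-based prognostic model: 1000 patients, half a priori willing to
#' follow the recommendation; the model predicts improvement for
#' three-fourths; 29/30 follow a prediction that confirms their intent; a
#' positive prediction converts half of the a priori decliners while a
#' negative prediction fails to deter one-third of the willing; and
#' three-fifths of predictions are correct regarding benefit.
#'
#' The weight table is the rule-derived assignment of [default_weights()]
#' with a positive side-effect profile, and the allocation keeps whole
#' patients at every tree node (`allocation_rounding = "stagewise"`), the
#' convention under which the scenario's published totals — 832
#' effect-points, 1026 under side effects rescaled to +/-3, and 40 harmed
#' patients — are exact. On analytic fractional counts the same scenario
#' gives 825 effect-points and an expected 40.83 harmed patients.
#'
#' @return A validated [brs_scenario()] (the expected totals are re-checked
#'   at load time and carried in `$expected`).
#' @examples
#' oa <- osteoarthritis_scenario()
#' compute_brs(oa)
#' @export
osteoarthritis_scenario <- function() {
  path <- system.file("extdata", "osteoarthritis.yaml", package = "brscore")
  sc <- load_scenario(path)
  exp <- sc$expected
  if (!is.null(exp)) {
    res <- compute_brs(sc)
    ok <- isTRUE(all.equal(res$total_points, exp$total_points)) &&
      res$harmed_n == exp$harmed_n
    if (!ok) {
      rlang::abort("Packaged osteoarthritis fixture failed re-validation against its expected totals.")
    }
  }
  sc
}

#' Generate a random valid scenario
#'
#' Draws a complete scenario for property testing: branching probabilities
#' uniform on \[0, 1\], cohort size uniform on 100–5000 patients, and
#' per-leaf weights from the discrete effect-point palette (`B` from
#' \{-3, -1, 0, 1, 3\}; `PNE`, `SE` from \{-1, 0, 1\}). Deterministic per
#' seed; the caller's RNG state is left untouched.
#'
#' @param seed Integer seed.
#' @return A [brs_scenario()] with analytic (fractional) allocation.
#' @examples
#' random_scenario(7)
#' @export
random_scenario <- function(seed) {
  withr::with_seed(seed, {
    assumptions <- brs_assumptions(
      cohort_size = stats::runif(1, 100, 5000),
      p_intent    = stats::runif(1),
      p_positive  = stats::runif(1),
      adherence   = c(
        willing_positive  = stats::runif(1),
        willing_negative  = stats::runif(1),
        decliner_positive = stats::runif(1),
        decliner_negative = stats::runif(1)
      ),
      p_correct   = stats::runif(1)
    )
    weights <- tibble::tibble(
      leaf = 1:16,
      B    = sample(c(-3, -1, 0, 1, 3), 16, replace = TRUE),
      PNE  = sample(c(-1, 0, 1), 16, replace = TRUE),
      SE   = sample(c(-1, 0, 1), 16, replace = TRUE)
    )
    brs_scenario(assumptions, weights, name = sprintf("random-%d", seed))
  })
}

#' Patient-level microsimulation oracle
#'
#' Estimates the Benefit-Risk Score by simulating individual patients
#' instead of multiplying probabilities: each of `M` synthetic patients is
#' drawn through the tree by sequential Bernoulli draws (intent, then
#' prediction, then participation given the intent x prediction adherence
#' cell, then would-benefit status given the prediction), lands in one of
#' the 16 leaves, and contributes that leaf's `B + PNE + SE`. The mean
#' per-patient score is rescaled to the scenario's cohort size.
#'
#' This is an independent cross-check of the analytic allocation-based
#' score (it shares no code path with [allocate()]); agreement within a few
#' Monte-Carlo standard errors validates both.
#'
#' @param scenario A [brs_scenario()].
#' @param M Number of simulated patients (>= 1).
#' @param seed Integer seed.
#' @return A list with `total_points` (estimate on the cohort scale), `se`
#'   (its Monte-Carlo standard error), `M`, `cohort_size`, and
#'   `leaf_frequencies` (tibble of leaf, observed count and relative
#'   frequency).
#' @examples
#' microsim_oracle(osteoarthritis_scenario(), M = 10000, seed = 1)
#' @export
microsim_oracle <- function(scenario, M, seed) {
  stopifnot(inherits(scenario, "brs_scenario"))
  if (!is.numeric(M) || length(M) != 1 || M < 1) {
    rlang::abort("`M` must be a single integer >= 1.")
  }
  M <- as.integer(M)
  a <- scenario$assumptions

  leaf <- withr::with_seed(seed, {
    intent <- stats::runif(M) < a$p_intent                # TRUE = willing
    pred   <- stats::runif(M) < a$p_positive              # TRUE = improve
    p_part <- unname(a$adherence[adherence_cell(intent, pred)])
    part   <- stats::runif(M) < p_part
    p_ben  <- ifelse(pred, a$p_correct, 1 - a$p_correct)
    ben    <- stats::runif(M) < p_ben
    # canonical leaf index from the four binaries (first-listed value = 0)
    1L + 8L * (!intent) + 4L * (!pred) + 2L * (!part) + 1L * (!ben)
  })

  w <- brs_weights(brs_tree(), scenario$weights)
  w_total <- (w$B + w$PNE + w$SE)[order(w$leaf)]
  pts <- w_total[leaf]

  est <- a$cohort_size * mean(pts)
  se  <- a$cohort_size * stats::sd(pts) / sqrt(M)
  if (is.na(se)) se <- 0

  counts <- tabulate(leaf, nbins = 16L)
  freq <- tibble::tibble(leaf = 1:16, count = counts, frequency = counts / M)

  list(
    total_points = est,
    se = se,
    M = M,
    cohort_size = a$cohort_size,
    leaf_frequencies = freq
  )
}
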