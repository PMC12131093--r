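#' One-way sensitivity sweep
#'
#' Recomputes the Benefit-Risk Score across a grid of values for a single
#' parameter, holding everything else fixed. Sign changes along the grid
#' mark where the implement/refrain recommendation flips.
#'
#' @param scenario A [brs_scenario()].
#' @param parameter Parameter name (see [set_parameter()] for the
#'   recognised probability, scale and per-leaf weight identifiers).
#' @param grid Strictly increasing numeric vector of parameter values;
#'   probability parameters must stay in \[0, 1\].
#' @return A tibble of class `brs_sweep` with columns `value`,
#'   `total_points`, `per_capita`, `decision`, and attributes `parameter`
#'   and `crossings` (grid intervals where the sign of the total changes).
#'   Supports [ggplot2::autoplot()].
#' @examples
#' oa <- osteoarthritis_scenario()
#' sweep_brs(oa, "se_scale", c(1, 3))
#' @export
sweep_brs <- function(scenario, parameter, grid) {
  stopifnot(inherits(scenario, "brs_scenario"))
  if (!is.numeric(grid) || length(grid) < 1 || is.unsorted(grid, strictly = TRUE)) {
    rlang::abort("`grid` must be a strictly increasing numeric vector.")
  }
  invisible(get_parameter(scenario, parameter))  # errors on unknown parameter
  if (is_probability_parameter(parameter) && (min(grid) < 0 || max(grid) > 1)) {
    rlang::abort(sprintf(
      "Grid values for probability parameter `%s` must lie in [0, 1].", parameter
    ))
  }
  res <- purrr::map(grid, function(v) {
    glance(compute_brs(set_parameter(scenario, parameter, v)))
  })
  out <- dplyr::bind_rows(res)
  out <- tibble::tibble(
    value = grid,
    total_points = out$total_points,
    per_capita = out$per_capita,
    decision = out$decision
  )
  s <- sign(out$total_points)
  idx <- which(s[-1] * s[-length(s)] < 0)
  crossings <- tibble::tibble(
    lower = grid[idx], upper = grid[idx + 1L]
  )
  structure(out,
            class = c("brs_sweep", class(out)),
            parameter = parameter, crossings = crossings)
}

#' @export
print.brs_sweep <- function(x, ...) {
  cat(sprintf("<brs_sweep> parameter: %s\n", attr(x, "parameter")))
  NextMethod()
  cr <- attr(x, "crossings")
  if (nrow(cr) > 0) {
    cat(sprintf("Sign change%s in: %s\n", if (nrow(cr) > 1) "s" else "",
                paste(sprintf("(%g, %g)", cr$lower, cr$upper), collapse = ", ")))
  }
  invisible(x)
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.brs_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$total_points)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$decision)) +
    ggplot2::scale_colour_manual(
      values = c(implement = "#2166ac", refrain = "#b2182b")
    ) +
    ggplot2::labs(
      x = attr(object, "parameter"), y = "Benefit-Risk Score (effect-points)"
    ) +
    ggplot2::theme_minimal()
}

#' Decision-boundary threshold for one parameter
#'
#' Finds the parameter value at which the Benefit-Risk Score crosses zero
#' (the implement/refrain boundary) within a search interval. The score is
#' linear in any weight or scale parameter, so for those the root is
#' obtained in closed form from two evaluations; for probability
#' parameters — in which the score is multilinear, hence continuous — a
#' bisection search is used.
#'
#' For probability parameters the score is always evaluated on the
#' analytic (fractional) allocation, where continuity holds exactly;
#' whole-patient rounding would make the score a step function of the
#' probabilities.
#'
#' @param scenario A [brs_scenario()].
#' @param parameter Parameter name (see [set_parameter()]).
#' @param interval Length-2 numeric search interval.
#' @param tol Absolute tolerance on the score at the root; default
#'   `1e-6 * cohort_size` since effect-point totals are of order
#'   cohort_size.
#' @return A list with `root` (parameter value, or `NA` if the score does
#'   not change sign on the interval), `brs_at_root`, `method`
#'   (`"linear"`/`"bisection"`/`"none"`/`"degenerate"`) and `parameter`.
#'   A scenario whose score is identically zero on the interval returns
#'   the interval start with a degeneracy warning.
#' @examples
#' brs_threshold(osteoarthritis_scenario(), "p_correct", c(0, 1))
#' @export
brs_threshold <- function(scenario, parameter, interval,
                          tol = 1e-6 * scenario$assumptions$cohort_size) {
  stopifnot(inherits(scenario, "brs_scenario"))
  if (!is.numeric(interval) || length(interval) != 2 || interval[1] >= interval[2]) {
    rlang::abort("`interval` must be a length-2 increasing numeric vector.")
  }
  prob_par <- is_probability_parameter(parameter)
  f <- function(v) {
    sc <- set_parameter(scenario, parameter, v)
    if (prob_par) {
      sum(brs_calculation(sc, rounding = "none")$points)
    } else {
      compute_brs(sc)$total_points
    }
  }
  lo <- interval[1]; hi <- interval[2]
  flo <- f(lo); fhi <- f(hi)

  if (flo == 0 && fhi == 0) {
    # check an interior point to distinguish a degenerate flat zero
    if (f((lo + hi) / 2) == 0) {
      warning("BRS is identically zero on the interval: every value is a root.",
              call. = FALSE)
      return(list(root = lo, brs_at_root = 0, method = "degenerate",
                  parameter = parameter))
    }
  }
  if (sign(flo) * sign(fhi) > 0) {
    return(list(root = NA_real_, brs_at_root = NA_real_, method = "none",
                parameter = parameter))
  }

  if (!prob_par) {
    # linear in weights/scales: exact root from two evaluations
    slope <- (fhi - flo) / (hi - lo)
    root <- lo - flo / slope
    return(list(root = root, brs_at_root = f(root), method = "linear",
                parameter = parameter))
  }

  # bisection on the continuous analytic score
  for (iter in seq_len(200)) {
    mid <- (lo + hi) / 2
    fmid <- f(mid)
    if (abs(fmid) < tol) break
    if (sign(fmid) == sign(flo)) {
      lo <- mid; flo <- fmid
    } else {
      hi <- mid
    }
  }
  list(root = mid, brs_at_root = fmid, method = "bisection",
       parameter = parameter)
}

#' Partial (clinician-gatekept) implementation
#'
#' Scores a deployment in which the prognostic tool is offered only to a
#' subgroup defined by a priori intent, with clinicians acting as
#' gatekeepers. Exposed patients flow through the tool-influenced
#' allocation; unexposed patients simply follow their own intent, which is
#' the comparator world and therefore contributes zero delta
#' effect-points. The returned score is the exposed subgroup's
#' contribution. Offering the tool only to a priori decliners is the
#' paradigm case: it removes the harm and nocebo contributions that arise
#' from talking willing patients out of a beneficial treatment.
#'
#' Adherence probabilities within the exposed subgroup are kept unchanged —
#' how gatekeeping itself would shift adherence is not modelled.
#'
#' @param scenario A [brs_scenario()].
#' @param expose Which a priori intent subgroup receives the tool:
#'   `"decliners"`, `"willing"`, `"all"` (identical to [compute_brs()] on
#'   the full scenario) or `"none"`.
#' @return A `brs_result` for the exposed contribution (harmed counts are
#'   computed over exposed leaves only). An empty exposure yields a
#'   zero-score result with a warning.
#' @examples
#' partial_implementation(osteoarthritis_scenario(), expose = "decliners")
#' @export
partial_implementation <- function(scenario,
                                   expose = c("decliners", "willing", "all", "none")) {
  expose <- rlang::arg_match(expose)
  stopifnot(inherits(scenario, "brs_scenario"))
  tab <- brs_calculation(scenario)
  exposed <- switch(
    expose,
    decliners = tab$intent == "no",
    willing   = tab$intent == "yes",
    all       = rep(TRUE, nrow(tab)),
    none      = rep(FALSE, nrow(tab))
  )
  if (!any(exposed)) {
    warning("Empty exposure subgroup: BRS is 0.", call. = FALSE)
  }
  # unexposed leaves follow their own intent (zero-delta): zero their weights
  tab <- dplyr::mutate(
    tab,
    B = ifelse(exposed, .data$B, 0),
    PNE = ifelse(exposed, .data$PNE, 0),
    SE = ifelse(exposed, .data$SE, 0),
    n = ifelse(exposed, .data$n, 0),
    points = .data$n * (.data$B + .data$PNE + .data$SE)
  )
  brs_result(tab, cohort_size = scenario$assumptions$cohort_size,
             name = sprintf("%s (expose: %s)", scenario$name, expose))
}
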