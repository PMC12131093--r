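#' Compute the Benefit-Risk Score
#'
#' Condenses a weighted cohort allocation into the population-level
#' Benefit-Risk Score
#'
#' \deqn{BRS = \sum_{i=1}^{16} n_i (B_i + PNE_i + SE_i)}
#'
#' where `n_i` is the expected number of patients in leaf `i` and the
#' triplet `(B_i, PNE_i, SE_i)` quantifies benefit/harm, placebo/nocebo and
#' side-effect points on a common additive scale. A positive total
#' recommends implementing the prognostic tool; a non-positive total
#' recommends refraining.
#'
#' @param x A [brs_scenario()], or a data frame holding the 16 canonical
#'   leaves with an `n` column (from [allocate()]) and — unless `weights`
#'   is supplied — the weight columns `B`, `PNE`, `SE`.
#' @param weights Optional per-leaf weight table (columns `leaf`, `B`,
#'   `PNE`, `SE`) joined onto `x` by leaf attributes; an error is raised if
#'   the two tables do not cover the same 16 leaves.
#' @param ... Unused.
#' @return An object of class `brs_result` with fields `total_points`,
#'   `per_capita`, `decision` (`"implement"`/`"refrain"`), `harmed`
#'   (expected count), `harmed_n` (whole patients), `cohort_size` and the
#'   per-leaf `table`. Supports [print()], [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' compute_brs(osteoarthritis_scenario())
#' @export
compute_brs <- function(x, ...) UseMethod("compute_brs")

#' @rdname compute_brs
#' @export
compute_brs.brs_scenario <- function(x, ...) {
  brs_result(brs_calculation(x), cohort_size = x$assumptions$cohort_size,
             name = x$name)
}

#' @rdname compute_brs
#' @export
compute_brs.data.frame <- function(x, weights = NULL, ...) {
  tab <- tibble::as_tibble(x)
  validate_full_tree(tab)
  if (!"n" %in% names(tab)) {
    rlang::abort("Allocation table must carry an `n` column (see `allocate()`).")
  }
  if (!is.null(weights)) {
    if (!"leaf" %in% names(tab)) {
      tab <- dplyr::left_join(
        tab,
        dplyr::select(brs_tree(), "leaf", "intent", "prediction",
                      "participation", "outcome"),
        by = c("intent", "prediction", "participation", "outcome")
      )
    }
    tab <- brs_weights(tab, weights)
  }
  missing <- setdiff(c("B", "PNE", "SE"), names(tab))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "No weights for column(s) ", paste(missing, collapse = ", "),
      ": supply them in the table or via `weights`."
    ))
  }
  tab <- dplyr::mutate(tab, points = .data$n * (.data$B + .data$PNE + .data$SE))
  brs_result(tab, cohort_size = sum(tab$n))
}

brs_result <- function(table, cohort_size, name = NULL) {
  if (!"points" %in% names(table)) {
    table <- dplyr::mutate(
      table, points = .data$n * (.data$B + .data$PNE + .data$SE)
    )
  }
  table <- classify_leaves(table)
  total <- sum(table$points)
  harmed <- harmed_count(table)
  veto <- "catastrophic" %in% names(table) &&
    any(table$catastrophic %in% TRUE & table$n > 0)
  structure(
    list(
      total_points = total,
      per_capita   = total / cohort_size,
      decision     = if (veto) "refrain" else if (total > 0) "implement" else "refrain",
      veto         = veto,
      harmed       = harmed,
      harmed_n     = floor(harmed + 0.5),
      cohort_size  = cohort_size,
      name         = name,
      table        = table
    ),
    class = "brs_result"
  )
}

#' Expected number of harmed patients
#'
#' Sums the allocation over the harm leaves: a priori willing patients who
#' forgo treatment they would have benefited from (both the
#' false-negative-driven E7 pattern and the unlikely positive-prediction
#' flips). These patients lose a real improvement because of the tool.
#'
#' @param allocation A leaf table with an `n` column covering the 16
#'   canonical leaves (classification flags are recomputed as needed).
#' @return The expected harmed count (possibly fractional). Report-level
#'   whole-patient figures round half-up (see `harmed_n` in
#'   [compute_brs()] results).
#' @examples
#' harmed_count(brs_calculation(osteoarthritis_scenario()))
#' @export
harmed_count <- function(allocation) {
  tab <- classify_leaves(tibble::as_tibble(allocation))
  if (!"n" %in% names(tab)) {
    rlang::abort("Allocation table must carry an `n` column.")
  }
  sum(tab$n[tab$harm_leaf])
}

#' Implementation decision from a Benefit-Risk Score
#'
#' Applies the sign rule: implement if the total is strictly positive,
#' refrain otherwise. An exact zero is a boundary case and refrains with a
#' warning. If any populated leaf is marked `catastrophic` in the weight
#' table the decision is vetoed to `"refrain"` regardless of the score —
#' harms beyond trade-off cannot be outweighed by points.
#'
#' @param result A `brs_result` from [compute_brs()].
#' @return `"implement"` or `"refrain"`.
#' @examples
#' decide(compute_brs(osteoarthritis_scenario()))
#' @export
decide <- function(result) {
  stopifnot(inherits(result, "brs_result"))
  if (isTRUE(result$veto)) {
    warning("A populated leaf is marked catastrophic: decision vetoed to 'refrain'.",
            call. = FALSE)
    return("refrain")
  }
  if (result$total_points == 0) {
    warning("BRS is exactly 0: boundary case, refraining.", call. = FALSE)
    return("refrain")
  }
  if (result$total_points > 0) "implement" else "refrain"
}

#' @export
print.brs_result <- function(x, ...) {
  cat(sprintf("<brs_result>%s\n",
              if (!is.null(x$name)) paste0(" ", x$name) else ""))
  cat(sprintf("  cohort:        %s patients\n", fmt_count(x$cohort_size)))
  cat(sprintf("  total points:  %s\n", fmt_points(x$total_points)))
  cat(sprintf("  per capita:    %.4g\n", x$per_capita))
  cat(sprintf("  harmed:        %s (%d patients)\n",
              fmt_count(x$harmed), x$harmed_n))
  cat(sprintf("  decision:      %s%s\n", x$decision,
              if (isTRUE(x$veto)) " (catastrophic-leaf veto)" else ""))
  invisible(x)
}

# counts to one decimal; integers shown as integers
fmt_count <- function(x) {
  ifelse(abs(x - round(x)) < 1e-9, format(round(x)), sprintf("%.1f", x))
}
# effect-point totals as integers when within 1e-9 of one
fmt_points <- function(x) {
  ifelse(abs(x - round(x)) < 1e-9, format(round(x)), format(x))
}

#' @importFrom generics tidy
#' @export
tidy.brs_result <- function(x, ...) {
  dplyr::select(
    x$table, "leaf", dplyr::any_of(c("node", "d_node", "b_node")),
    "intent", "prediction", "participation", "outcome",
    "n", "B", "PNE", "SE", "points"
  )
}

#' @importFrom generics glance
#' @export
glance.brs_result <- function(x, ...) {
  tibble::tibble(
    total_points = x$total_points,
    per_capita   = x$per_capita,
    decision     = x$decision,
    harmed       = x$harmed,
    harmed_n     = x$harmed_n,
    cohort_size  = x$cohort_size
  )
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.brs_result <- function(object, ...) {
  tab <- tidy(object)
  lab <- if ("node" %in% names(tab)) tab$node else as.character(tab$leaf)
  tab$label <- factor(lab, levels = lab)
  ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$label, y = .data$points,
    fill = .data$points >= 0
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b")) +
    ggplot2::labs(
      x = "outcome possibility",
      y = "effect-points  n (B + PNE + SE)",
      title = sprintf("Benefit-Risk Score: %s (%s)",
                      fmt_points(object$total_points), object$decision)
    ) +
    ggplot2::theme_minimal()
}
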