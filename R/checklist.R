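#' Pre-implementation checklist
#'
#' Creates the eleven-question checklist to work through before any
#' best-/worst-case calculation or implementation decision. The first
#' seven questions gather the quantities and judgements that fill the
#' calculation table (counts benefited and harmed, side-effect counts,
#' placebo/nocebo influence, the uniform weighting scale, additional
#' health outcomes, and partial-implementation mitigation); the last four
#' cover barriers and facilitators at the tool, personal, institutional
#' and external-context levels.
#'
#' @param answers Optional named character vector of answers, keyed by the
#'   checklist `id` (e.g. `c(benefited = "about 115 of 1000")`).
#' @return A tibble of class `brs_checklist` with columns `item`, `id`,
#'   `topic`, `question`, `answer` and `answered`.
#' @examples
#' brs_checklist()
#' @export
brs_checklist <- function(answers = NULL) {
  items <- tibble::tribble(
    ~id,            ~topic,                      ~question,
    "benefited",    "benefit count",
    "How many patients could benefit from the personalized outcome prediction (by motivating them for or against a treatment that benefits or harms them)?",
    "harmed",       "harm count",
    "How many patients could be harmed by the personalized outcome prediction (by motivating them for or against a treatment that harms or benefits them)?",
    "side_effects", "side-effect counts",
    "How many patients would experience positive side effects, and how many would experience negative side effects?",
    "placebo_nocebo", "placebo/nocebo influence",
    "How would the placebo or nocebo effect influence the outcomes?",
    "weighting",    "uniform-scale weighting",
    "On a uniform scale, how much would the benefits, harms, nocebo or placebo effects, and side effects weigh?",
    "other_outcomes", "additional health outcomes",
    "Are there additional health outcomes to be considered (maybe as side effects)?",
    "partial",      "partial-implementation mitigation",
    "Can the harm for some patients be mediated by a partial implementation (only for clinicians)?",
    "barriers_tool", "barriers/facilitators: tool level",
    "Which barriers and facilitators exist at the tool or intervention level?",
    "barriers_personal", "barriers/facilitators: personal level",
    "Which barriers and facilitators exist at the personal level?",
    "barriers_institutional", "barriers/facilitators: institutional level",
    "Which barriers and facilitators exist at the institutional level?",
    "barriers_external", "barriers/facilitators: external context",
    "Which barriers and facilitators exist in the external context?"
  )
  items$item <- seq_len(nrow(items))
  items$answer <- NA_character_
  if (!is.null(answers)) {
    unknown <- setdiff(names(answers), items$id)
    if (length(unknown) > 0) {
      rlang::abort(paste0("Unknown checklist id(s): ",
                          paste(unknown, collapse = ", "), "."))
    }
    items$answer[match(names(answers), items$id)] <- unname(answers)
  }
  items$answered <- !is.na(items$answer) & nzchar(items$answer)
  out <- dplyr::select(items, "item", "id", "topic", "question",
                       "answer", "answered")
  class(out) <- c("brs_checklist", class(out))
  out
}

#' Format a checklist report
#'
#' Renders the checklist as a plain-markdown report listing every question
#' with its answer or open status. When a scenario is attached, a
#' Benefit-Risk Score summary and the implement/refrain recommendation are
#' appended.
#'
#' @param checklist A [brs_checklist()].
#' @param scenario Optional [brs_scenario()] to score and summarize.
#' @return A character vector of report lines (class `brs_report`; printed
#'   as text).
#' @examples
#' cat(checklist_report(brs_checklist(), osteoarthritis_scenario()), sep = "\n")
#' @export
checklist_report <- function(checklist, scenario = NULL) {
  stopifnot(inherits(checklist, "brs_checklist"))
  n_open <- sum(!checklist$answered)
  lines <- c(
    "# Benefit-risk implementation checklist",
    "",
    sprintf("%d of %d items answered, %d open.",
            sum(checklist$answered), nrow(checklist), n_open),
    ""
  )
  for (i in seq_len(nrow(checklist))) {
    lines <- c(
      lines,
      sprintf("%2d. [%s] %s", checklist$item[i],
              if (checklist$answered[i]) "answered" else "open",
              checklist$question[i]),
      if (checklist$answered[i]) sprintf("    Answer: %s", checklist$answer[i])
    )
  }
  if (!is.null(scenario)) {
    res <- compute_brs(scenario)
    recommendation <- if (res$decision == "implement") {
      sprintf(paste0(
        "The Benefit-Risk Score is positive (%s effect-points over %s ",
        "patients, %.3g per capita): creating and implementing the tool is ",
        "recommended at the population level, while the %d patients in harm ",
        "leaves warrant mitigation (e.g. partial implementation)."),
        fmt_points(res$total_points), fmt_count(res$cohort_size),
        res$per_capita, res$harmed_n)
    } else {
      sprintf(paste0(
        "The Benefit-Risk Score is not positive (%s effect-points): the ",
        "potential for harm outweighs the benefit, so refraining from ",
        "implementation is recommended."),
        fmt_points(res$total_points))
    }
    lines <- c(
      lines, "",
      sprintf("## Benefit-Risk Score: %s", scenario$name),
      "",
      sprintf("- total effect-points: %s", fmt_points(res$total_points)),
      sprintf("- per capita: %.4g", res$per_capita),
      sprintf("- harmed patients: %s (%d)", fmt_count(res$harmed), res$harmed_n),
      sprintf("- decision: %s", res$decision),
      "",
      recommendation
    )
  }
  structure(lines, class = "brs_report")
}

#' @export
print.brs_report <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}
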