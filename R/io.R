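#' Read a scenario configuration file
#'
#' Parses a YAML scenario config into a validated [brs_scenario()].
#' Probabilities may be written as plain numbers or as exact fraction
#' strings (`"29/30"`), which keeps hand-authored configs lossless and
#' diff-able. Field-level validation errors name the offending field.
#'
#' Expected layout:
#' ```yaml
#' name: my-scenario
#' cohort_size: 1000
#' allocation_rounding: stagewise   # or none
#' probabilities: {p_intent: 1/2, p_positive: 3/4, p_correct: 3/5}
#' adherence:
#'   willing_positive: 29/30
#'   willing_negative: 1/3
#'   decliner_positive: 1/2
#'   decliner_negative: 1/30
#' weights:
#'   - {leaf: 1, B: 0, PNE: 1, SE: 0}
#'   # ... one entry per leaf 1-16
#' expected:            # optional provenance block
#'   total_points: 832
#'   harmed_n: 40
#' ```
#'
#' @param path Path to a YAML scenario file.
#' @return A [brs_scenario()]; any `expected` block is attached as
#'   `$expected` for fixture re-validation.
#' @seealso [write_scenario()], [osteoarthritis_scenario()]
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Scenario file not found: %s", path))
  }
  cfg <- yaml::read_yaml(path)

  need <- function(block, field, where = "") {
    if (is.null(block[[field]])) {
      rlang::abort(sprintf("Scenario config is missing field `%s%s`.", where, field))
    }
    block[[field]]
  }
  if (!is.null(cfg$intent_prediction_correlation) &&
      !isTRUE(all.equal(parse_fraction(cfg$intent_prediction_correlation), 0))) {
    rlang::abort(paste0(
      "`intent_prediction_correlation` is reserved and must be 0 or absent: ",
      "the allocation assumes prediction independent of intent."
    ))
  }
  probs <- need(cfg, "probabilities")
  adh <- need(cfg, "adherence")
  cells <- c("willing_positive", "willing_negative",
             "decliner_positive", "decliner_negative")
  for (cell in cells) need(adh, cell, "adherence.")
  assumptions <- brs_assumptions(
    cohort_size = parse_fraction(need(cfg, "cohort_size")),
    p_intent    = parse_fraction(need(probs, "p_intent", "probabilities.")),
    p_positive  = parse_fraction(need(probs, "p_positive", "probabilities.")),
    adherence   = vapply(stats::setNames(cells, cells),
                         function(cell) parse_fraction(adh[[cell]]), numeric(1)),
    p_correct   = parse_fraction(need(probs, "p_correct", "probabilities."))
  )
  wlist <- need(cfg, "weights")
  weights <- dplyr::bind_rows(lapply(wlist, function(row) {
    tibble::tibble(
      leaf = as.integer(need(row, "leaf", "weights.")),
      B    = parse_fraction(need(row, "B", "weights.")),
      PNE  = parse_fraction(need(row, "PNE", "weights.")),
      SE   = parse_fraction(need(row, "SE", "weights.")),
      catastrophic = isTRUE(row$catastrophic)
    )
  }))
  if (!any(weights$catastrophic)) weights$catastrophic <- NULL

  sc <- brs_scenario(
    assumptions = assumptions,
    weights = weights,
    name = cfg$name %||% "scenario",
    allocation_rounding = cfg$allocation_rounding %||% "none",
    notes = cfg$notes
  )
  if (!is.null(cfg$expected)) sc$expected <- cfg$expected
  sc
}

#' Write a scenario configuration file
#'
#' Serializes a scenario to the YAML layout read by [load_scenario()].
#' Numbers are written with full double precision so a write/read round
#' trip reproduces the scenario bit-identically.
#'
#' @param scenario A [brs_scenario()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "brs_scenario"))
  a <- scenario$assumptions
  w <- scenario$weights
  cfg <- list(
    name = scenario$name,
    cohort_size = num_repr(a$cohort_size),
    allocation_rounding = scenario$allocation_rounding,
    probabilities = list(
      p_intent = num_repr(a$p_intent),
      p_positive = num_repr(a$p_positive),
      p_correct = num_repr(a$p_correct)
    ),
    adherence = lapply(as.list(a$adherence), num_repr),
    weights = lapply(seq_len(nrow(w)), function(i) {
      row <- list(leaf = w$leaf[i], B = w$B[i], PNE = w$PNE[i], SE = w$SE[i])
      if ("catastrophic" %in% names(w) && isTRUE(w$catastrophic[i])) {
        row$catastrophic <- TRUE
      }
      row
    })
  )
  if (!is.null(scenario$notes)) cfg$notes <- scenario$notes
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# full-precision decimal string (round-trips doubles exactly)
num_repr <- function(x) {
  if (abs(x - round(x)) < .Machine$double.eps * max(1, abs(x))) {
    return(as.integer(round(x)))
  }
  format(x, digits = 17, scientific = FALSE)
}

# accept 0.5, "0.5" or "29/30"
parse_fraction <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.character(x) && length(x) == 1) {
    if (grepl("^\\s*-?[0-9.eE+-]+\\s*/\\s*-?[0-9.eE+-]+\\s*$", x)) {
      parts <- strsplit(x, "/")[[1]]
      return(as.numeric(parts[1]) / as.numeric(parts[2]))
    }
    val <- suppressWarnings(as.numeric(x))
    if (!is.na(val)) return(val)
  }
  rlang::abort(sprintf("Cannot interpret `%s` as a number or fraction.",
                       paste(format(x), collapse = ", ")))
}

#' Export the per-leaf calculation table
#'
#' Writes the complete Benefit-Risk calculation as a self-contained CSV:
#' one row per leaf (index, figure label, the four attributes, `n`, `B`,
#' `PNE`, `SE`, and the row product `points`), preceded by `#`-prefixed
#' header comments carrying the scenario parameters at full precision and
#' followed by `#`-prefixed summary comments (total, per-capita, decision,
#' harmed). [import_table()] reads the file back into an identical
#' scenario and result.
#'
#' @param scenario A [brs_scenario()].
#' @param path Output CSV path.
#' @param result Optional precomputed `brs_result`; computed from the
#'   scenario if omitted.
#' @return `path`, invisibly.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' export_table(osteoarthritis_scenario(), path)
#' readLines(path, n = 5)
#' @export
export_table <- function(scenario, path, result = NULL) {
  stopifnot(inherits(scenario, "brs_scenario"))
  result <- result %||% compute_brs(scenario)
  a <- scenario$assumptions
  # %.17g round-trips doubles exactly through decimal text
  fmt <- function(x) {
    if (is.numeric(x)) {
      out <- sprintf("%.17g", x)
      int <- abs(x - round(x)) < .Machine$double.eps * pmax(1, abs(x)) &
        abs(x) < 2^53
      out[int] <- sprintf("%.0f", x[int])
      out
    } else {
      as.character(x)
    }
  }
  header <- c(
    sprintf("# brscore calculation table"),
    sprintf("# name: %s", scenario$name),
    sprintf("# cohort_size: %s", fmt(a$cohort_size)),
    sprintf("# allocation_rounding: %s", scenario$allocation_rounding),
    sprintf("# p_intent: %s", fmt(a$p_intent)),
    sprintf("# p_positive: %s", fmt(a$p_positive)),
    sprintf("# p_correct: %s", fmt(a$p_correct)),
    sprintf("# adherence_%s: %s", names(a$adherence),
            vapply(a$adherence, fmt, character(1)))
  )
  tab <- dplyr::select(
    result$table, "leaf", dplyr::any_of("node"),
    "intent", "prediction", "participation", "outcome",
    "n", "B", "PNE", "SE", "points"
  )
  footer <- c(
    sprintf("# total_points: %s", fmt(result$total_points)),
    sprintf("# per_capita: %s", fmt(result$per_capita)),
    sprintf("# decision: %s", result$decision),
    sprintf("# harmed: %s", fmt(result$harmed)),
    sprintf("# harmed_n: %d", result$harmed_n)
  )
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines(header, con)
  body <- utils::capture.output(
    utils::write.csv(
      dplyr::mutate(tab, dplyr::across(dplyr::where(is.numeric), fmt)),
      row.names = FALSE, quote = FALSE
    )
  )
  writeLines(body, con)
  writeLines(footer, con)
  invisible(path)
}

#' Re-import an exported calculation table
#'
#' Reads a CSV written by [export_table()] back into the scenario, the
#' per-leaf table and the summary it was produced from. The totals are
#' recomputed from the imported scenario and checked against the file's
#' summary comments.
#'
#' @param path Path to a calculation-table CSV.
#' @return A list with `scenario` (a [brs_scenario()]; weights and
#'   assumptions as exported), `table` (16-row tibble) and `result` (the
#'   recomputed `brs_result`).
#' @export
import_table <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("File not found: %s", path))
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- grep("^# [A-Za-z_]+: ", meta_lines, value = TRUE)
  keys <- sub("^# ([A-Za-z_]+): .*$", "\\1", kv)
  vals <- sub("^# [A-Za-z_]+: ", "", kv)
  meta <- stats::setNames(as.list(vals), keys)

  # base R parser: correctly-rounded doubles, so re-imports are bit-exact
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  tab <- tibble::as_tibble(tab)
  tab$leaf <- as.integer(tab$leaf)
  for (col in intersect(c("n", "B", "PNE", "SE", "points"), names(tab))) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  validate_full_tree(tab)

  cells <- c("willing_positive", "willing_negative",
             "decliner_positive", "decliner_negative")
  assumptions <- brs_assumptions(
    cohort_size = as.numeric(meta$cohort_size),
    p_intent = as.numeric(meta$p_intent),
    p_positive = as.numeric(meta$p_positive),
    adherence = vapply(stats::setNames(cells, cells), function(cell) {
      as.numeric(meta[[paste0("adherence_", cell)]])
    }, numeric(1)),
    p_correct = as.numeric(meta$p_correct)
  )
  scenario <- brs_scenario(
    assumptions = assumptions,
    weights = dplyr::select(tab, "leaf", "B", "PNE", "SE"),
    name = meta$name %||% "imported",
    allocation_rounding = meta$allocation_rounding %||% "none"
  )
  result <- compute_brs(scenario)
  if (!is.null(meta$total_points)) {
    stated <- as.numeric(meta$total_points)
    if (!isTRUE(all.equal(result$total_points, stated, tolerance = 1e-12))) {
      rlang::abort(sprintf(
        "Recomputed total (%s) does not match the table's stated total (%s).",
        format(result$total_points), format(stated)
      ))
    }
  }
  list(scenario = scenario, table = tab, result = result)
}
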