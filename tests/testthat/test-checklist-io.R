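test_that("the packaged scenario config loads and scores the worked example", {
  path <- system.file("extdata", "osteoarthritis.yaml", package = "brscore")
  sc <- load_scenario(path)
  expect_s3_class(sc, "brs_scenario")
  expect_equal(sc$assumptions$p_correct, 3 / 5)
  expect_equal(compute_brs(sc)$total_points, 832)
})

test_that("config validation errors name the offending field", {
  sc <- osteoarthritis_scenario()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)

  drop_field <- function(path, pattern) {
    lines <- readLines(path)
    out <- withr::local_tempfile(fileext = ".yaml", .local_envir = parent.frame())
    writeLines(lines[!grepl(pattern, lines)], out)
    out
  }
  expect_error(load_scenario(drop_field(path, "^  p_positive:")), "p_positive")
  expect_error(load_scenario(drop_field(path, "^  willing_negative:")),
               "willing_negative")

  bad <- withr::local_tempfile(fileext = ".yaml")
  lines <- readLines(path)
  writeLines(sub("^  p_intent:.*$", "  p_intent: 1.5", lines), bad)
  expect_error(load_scenario(bad), "p_intent")

  expect_error(load_scenario(withr::local_tempfile(fileext = ".yaml")),
               "not found")
})

test_that("scenario write/read round trip is exact", {
  sc <- random_scenario(31)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  back <- load_scenario(path)
  expect_equal(back$assumptions$cohort_size, sc$assumptions$cohort_size)
  expect_equal(back$assumptions$adherence, sc$assumptions$adherence)
  expect_identical(compute_brs(back)$total_points, compute_brs(sc)$total_points)
})

test_that("fraction strings parse exactly in configs", {
  expect_equal(brscore:::parse_fraction("29/30"), 29 / 30)
  expect_equal(brscore:::parse_fraction("0.25"), 0.25)
  expect_equal(brscore:::parse_fraction(0.25), 0.25)
  expect_error(brscore:::parse_fraction("one half"), "Cannot interpret")
})

test_that("exported calculation table has 16 rows and the stated totals", {
  sc <- osteoarthritis_scenario()
  path <- withr::local_tempfile(fileext = ".csv")
  export_table(sc, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# total_points: 832$", lines)))
  expect_true(any(grepl("^# harmed_n: 40$", lines)))
  expect_true(any(grepl("^# decision: implement$", lines)))
  body <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  expect_equal(nrow(body), 16L)
  expect_equal(sum(body$points), 832)
})

test_that("export/import round trip reproduces scenario and totals exactly", {
  for (sc in list(osteoarthritis_scenario(), random_scenario(55))) {
    path <- withr::local_tempfile(fileext = ".csv")
    res <- compute_brs(sc)
    export_table(sc, path, result = res)
    back <- import_table(path)
    expect_identical(back$result$total_points, res$total_points)
    expect_identical(back$result$harmed, res$harmed)
    expect_identical(back$result$decision, res$decision)
    expect_equal(back$scenario$assumptions$adherence, sc$assumptions$adherence)
    expect_equal(back$table$n, res$table$n)
    # re-export of the re-import is byte-identical
    path2 <- withr::local_tempfile(fileext = ".csv")
    export_table(back$scenario, path2)
    expect_identical(readLines(path2)[-2], readLines(path)[-2])  # name line differs
  }
})

test_that("the checklist has eleven questions and tracks completion", {
  cl <- brs_checklist()
  expect_equal(nrow(cl), 11L)
  expect_true(all(!cl$answered))
  rep_lines <- checklist_report(cl)
  expect_equal(sum(grepl("\\[open\\]", rep_lines)), 11L)
  expect_false(any(grepl("Benefit-Risk Score:", rep_lines)))

  answered <- brs_checklist(answers = c(
    benefited = "115 converted decliners benefit",
    harmed = "about 40 forgo a beneficial treatment"
  ))
  expect_equal(sum(answered$answered), 2L)
  expect_error(brs_checklist(answers = c(nonsense = "x")), "Unknown checklist id")
})

test_that("a report with an attached scenario includes the decision", {
  rep_lines <- checklist_report(brs_checklist(), osteoarthritis_scenario())
  expect_true(any(grepl("decision: implement", rep_lines)))
  expect_true(any(grepl("832", rep_lines)))
})

test_that("the CLI driver runs subcommands and signals failures", {
  cfg <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(osteoarthritis_scenario(), cfg)
  out <- withr::local_tempfile(fileext = ".csv")

  expect_output(status <- brs_cli(c("run", "--config", cfg, "--out", out)), "832")
  expect_identical(status, 0L)
  expect_true(file.exists(out))
  expect_output(status <- brs_cli(c("example")), "implement")
  expect_identical(status, 0L)
  expect_output(
    status <- brs_cli(c("sweep", "--config", cfg,
                        "--parameter", "se_scale", "--grid", "1,3")),
    "1026"
  )
  expect_identical(status, 0L)
  expect_output(status <- brs_cli(c("partial", "--config", cfg,
                                    "--expose", "decliners")), "646")
  expect_identical(status, 0L)
  expect_output(status <- brs_cli(c("checklist")), "open")
  expect_identical(status, 0L)

  # validation failures exit nonzero
  expect_message(status <- brs_cli(c("run", "--config", "/no/such/file.yaml")),
                 "error")
  expect_identical(status, 1L)
  expect_message(status <- brs_cli(c("frobnicate")), "Unknown subcommand")
  expect_identical(status, 1L)
})
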