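test_that("default weights encode the scoring rules", {
  w <- default_weights(brs_tree(), profile = "positive")
  expect_true(all(w$B[w$aligned] == 0))
  expect_true(all(w$B[w$harm_leaf] == -3))
  expect_true(all(w$B[w$top_benefit_leaf] == 3))
  # flips that only avoid wasted effort / only consume time
  expect_true(all(w$B[w$flipped & w$participation == "no" &
                        w$outcome == "no_benefit"] == 1))
  expect_true(all(w$B[w$flipped & w$participation == "yes" &
                        w$outcome == "no_benefit"] == -1))
  # placebo for all treated under a positive prediction
  expect_true(all(w$PNE[w$placebo_affected] == 1))
  # nocebo only where an improvement exists to diminish
  expect_true(all(w$PNE[w$nocebo_affected & w$outcome == "benefit"] == -1))
  expect_true(all(w$PNE[w$nocebo_affected & w$outcome == "no_benefit"] == 0))
  expect_true(all(w$PNE[w$participation == "no"] == 0))
  # side effects follow the flipped participation delta
  expect_true(all(w$SE[w$flipped & w$participation == "yes"] == 1))
  expect_true(all(w$SE[w$flipped & w$participation == "no"] == -1))
  expect_true(all(w$SE[w$aligned] == 0))
  # profile variants
  expect_equal(default_weights(brs_tree(), "negative")$SE,
               -default_weights(brs_tree(), "positive")$SE)
  expect_true(all(default_weights(brs_tree(), "neutral")$SE == 0))
  expect_error(default_weights(brs_tree(), "sideways"))
})

test_that("no decision flips means zero benefit and side-effect deltas", {
  alloc <- allocate(brs_tree(), make_assumptions(adherence = no_flip_adherence))
  tab <- default_weights(alloc)
  expect_true(all(tab$n[tab$flipped] == 0))
  res <- compute_brs(tab)
  expect_equal(harmed_count(tab), 0)
  # remaining score is pure expectation effect on aligned participants
  expect_equal(res$total_points, sum(tab$n * tab$PNE))
})

test_that("the worked example scores 832 points, implement, 40 harmed", {
  res <- compute_brs(osteoarthritis_scenario())
  expect_identical(res$total_points, 832)
  expect_equal(res$per_capita, 0.832)
  expect_identical(res$decision, "implement")
  expect_identical(decide(res), "implement")
  expect_identical(res$harmed_n, 40)
})

test_that("rescaling side effects to +/-3 gives the published variant", {
  oa3 <- set_parameter(osteoarthritis_scenario(), "se_scale", 3)
  expect_identical(compute_brs(oa3)$total_points, 1026)
})

# tiny constructor for sign-rule checks: a one-sided table with total `x`
brs_result_for_total <- function(x) {
  tab <- allocate(brs_tree(), make_assumptions(cohort_size = 1))
  tab <- brs_weights(tab, zero_weights())
  tab$B[tab$leaf == 1] <- x / tab$n[tab$leaf == 1]
  compute_brs(tab)
}

test_that("zero weights give a zero score and a boundary refrain", {
  sc <- brs_scenario(make_assumptions(), zero_weights())
  res <- compute_brs(sc)
  expect_identical(res$total_points, 0)
  expect_identical(res$decision, "refrain")
  expect_warning(d <- decide(res), "boundary")
  expect_identical(d, "refrain")
  expect_identical(decide(brs_result_for_total(-1)), "refrain")
})

test_that("the score is linear in the weights", {
  sc <- random_scenario(12)
  base <- compute_brs(sc)$total_points
  for (alpha in c(0, 0.5, 2, -1)) {
    w <- sc$weights
    w$B <- alpha * w$B; w$PNE <- alpha * w$PNE; w$SE <- alpha * w$SE
    scaled <- compute_brs(brs_scenario(sc$assumptions, w))$total_points
    expect_equal(scaled, alpha * base, tolerance = 1e-12)
  }
})

test_that("the score is additive over disjoint subpopulations", {
  sc <- random_scenario(23)
  a <- sc$assumptions
  total <- compute_brs(sc)$total_points
  parts <- vapply(c(0.3, 0.7), function(frac) {
    sub <- brs_assumptions(frac * a$cohort_size, a$p_intent, a$p_positive,
                           a$adherence, a$p_correct)
    compute_brs(brs_scenario(sub, sc$weights))$total_points
  }, numeric(1))
  expect_equal(sum(parts), total, tolerance = 1e-9)
})

test_that("increasing a weight with positive leaf count strictly increases the score", {
  oa <- osteoarthritis_scenario()
  tab <- brs_calculation(oa)
  for (leaf in c(1, 7, 9, 16)) {
    expect_gt(tab$n[tab$leaf == leaf], 0)
    bumped <- set_parameter(oa, paste0("B_", leaf),
                            get_parameter(oa, paste0("B_", leaf)) + 1)
    expect_gt(compute_brs(bumped)$total_points, compute_brs(oa)$total_points)
  }
})

test_that("perfect predictions with full adherence leave nobody harmed", {
  a <- brs_assumptions(
    1000, p_intent = 1 / 2, p_positive = 3 / 4,
    adherence = c(willing_positive = 1, willing_negative = 0,
                  decliner_positive = 1, decliner_negative = 0),
    p_correct = 1
  )
  alloc <- allocate(brs_tree(), a)
  # forgone treatment only follows a negative prediction, which is now
  # always correct: the patient would not have benefited
  expect_equal(harmed_count(alloc), 0)
})

test_that("allocation/weight leaf-set mismatches are validation errors", {
  alloc <- allocate(brs_tree(), make_assumptions())
  expect_error(compute_brs(alloc[-1, ]), "16 canonical leaves")
  bad_w <- zero_weights()[-3, ]
  expect_error(compute_brs(alloc, weights = bad_w), "one row per leaf")
  expect_error(compute_brs(dplyr::select(alloc, -dplyr::any_of("n"))), "`n` column")
})

test_that("a populated catastrophic leaf vetoes implementation", {
  w <- zero_weights()
  w$B[w$leaf == 9] <- 3          # big benefit, positive score
  w$catastrophic <- w$leaf == 7  # but the harm leaf is beyond trade-off
  res <- compute_brs(brs_scenario(make_assumptions(), w))
  expect_gt(res$total_points, 0)
  expect_identical(res$decision, "refrain")
  expect_warning(decide(res), "catastrophic")
})

test_that("tidy and glance expose the calculation table and summary", {
  res <- compute_brs(osteoarthritis_scenario())
  td <- tidy(res)
  expect_equal(nrow(td), 16L)
  expect_true(all(c("leaf", "n", "B", "PNE", "SE", "points") %in% names(td)))
  expect_equal(sum(td$points), 832)
  gl <- glance(res)
  expect_equal(gl$total_points, 832)
  expect_equal(gl$harmed_n, 40)
  expect_identical(gl$decision, "implement")
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
})
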