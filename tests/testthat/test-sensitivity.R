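test_that("side-effect scale sweep reproduces both published totals", {
  sw <- sweep_brs(osteoarthritis_scenario(), "se_scale", c(1, 3))
  expect_equal(sw$total_points, c(832, 1026))
  expect_equal(sw$decision, c("implement", "implement"))
})

test_that("a single-point sweep at the current value is the identity", {
  oa <- osteoarthritis_scenario()
  for (par in c("se_scale", "p_correct", "adherence_decliner_positive")) {
    sw <- sweep_brs(oa, par, get_parameter(oa, par))
    expect_equal(sw$total_points, compute_brs(oa)$total_points)
  }
})

test_that("benefit-scale sweep decomposes the score linearly", {
  oa <- osteoarthritis_scenario()
  sw <- sweep_brs(oa, "b_scale", c(0, 1))
  tab <- brs_calculation(oa)
  # independent recomputation by direct column sums
  expect_equal(sw$total_points[1], sum(tab$n * (tab$PNE + tab$SE)))
  expect_equal(sw$total_points[2], sum(tab$n * (tab$B + tab$PNE + tab$SE)))
})

test_that("sweep validates its inputs and records sign crossings", {
  oa <- osteoarthritis_scenario()
  expect_error(sweep_brs(oa, "no_such_knob", c(0, 1)), "Unknown parameter")
  expect_error(sweep_brs(oa, "p_correct", c(0.5, 1.5)), "\\[0, 1\\]")
  expect_error(sweep_brs(oa, "se_scale", c(3, 1)), "increasing")
  sw <- sweep_brs(oa, "b_scale", seq(-5, 1, by = 1))
  cr <- attr(sw, "crossings")
  expect_gt(nrow(cr), 0)
  s <- sign(sw$total_points)
  expect_true(any(s[-1] * s[-length(s)] < 0))
  expect_s3_class(ggplot2::autoplot(sw), "ggplot")
})

test_that("closed-form and bisection threshold solvers agree", {
  oa <- osteoarthritis_scenario()
  # force a sign change in the benefit scale: heavily negative at -5
  th <- brs_threshold(oa, "b_scale", c(-5, 1))
  expect_identical(th$method, "linear")
  expect_false(is.na(th$root))
  expect_lt(abs(th$brs_at_root), 1e-6 * 1000)

  # independent bisection on the same function
  f <- function(v) compute_brs(set_parameter(oa, "b_scale", v))$total_points
  lo <- -5; hi <- 1
  flo <- f(lo)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(flo)) {
      lo <- mid; flo <- f(mid)
    } else {
      hi <- mid
    }
  }
  expect_equal(th$root, mid, tolerance = 1e-8)
})

test_that("probability thresholds are found on the continuous score", {
  # a scenario whose score crosses zero in p_correct: harm-dominated weights
  w <- zero_weights()
  w$B <- c(0, 0, -3, 1, 0, 0, -3, 1, 3, -1, 0, 0, 3, -1, 0, 0)
  sc <- brs_scenario(make_assumptions(), w)
  f <- function(v) sum(brs_calculation(set_parameter(sc, "p_correct", v),
                                       rounding = "none")$points)
  expect_lt(f(0) * f(1), 0)
  th <- brs_threshold(sc, "p_correct", c(0, 1))
  expect_identical(th$method, "bisection")
  expect_lt(abs(th$brs_at_root), 1e-6 * 1000)
  expect_equal(f(th$root), th$brs_at_root)
})

test_that("threshold reports no root without a sign change, degenerate flat zero with warning", {
  oa <- osteoarthritis_scenario()
  none <- brs_threshold(oa, "p_correct", c(0, 1))  # positive throughout
  expect_true(is.na(none$root))
  expect_identical(none$method, "none")

  flat <- brs_scenario(make_assumptions(), zero_weights())
  expect_warning(th0 <- brs_threshold(flat, "se_scale", c(0, 2)), "identically zero")
  expect_equal(th0$root, 0)
  expect_identical(th0$method, "degenerate")
})

test_that("partial implementation for decliners removes all harm-leaf points", {
  oa <- osteoarthritis_scenario()
  res <- partial_implementation(oa, expose = "decliners")
  expect_equal(res$harmed, 0)
  harm_rows <- res$table$harm_leaf
  expect_true(all(res$table$points[harm_rows] == 0))
  expect_equal(res$total_points, 646)
  expect_identical(res$decision, "implement")
})

test_that("exposing everyone equals the full scenario; nobody gives zero", {
  oa <- osteoarthritis_scenario()
  full <- compute_brs(oa)
  all_exposed <- partial_implementation(oa, expose = "all")
  expect_equal(all_exposed$total_points, full$total_points)
  expect_equal(all_exposed$harmed, full$harmed)
  expect_warning(none <- partial_implementation(oa, expose = "none"), "Empty")
  expect_equal(none$total_points, 0)
})

test_that("the score decomposes over the a priori intent partition", {
  for (seed in c(5, 19, 77)) {
    sc <- random_scenario(seed)
    full <- compute_brs(sc)$total_points
    decl <- partial_implementation(sc, "decliners")$total_points
    will <- partial_implementation(sc, "willing")$total_points
    expect_equal(decl + will, full, tolerance = 1e-9)
  }
})
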