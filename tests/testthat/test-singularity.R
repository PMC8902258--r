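# GHK singularity detection and piecewise repair.

test_that("the four GHK form variants and K-factored spellings match", {
  # pure non-dimensional form: U = V, B = 1, v0 = 0, f = 1
  m <- find_singularity_matches(expr_parse("V / (exp(V) - 1)"), "V")
  expect_length(m, 1L)
  expect_equal(m[[1]]$B, 1)
  expect_equal(m[[1]]$v0, 0)
  expect_identical(fold_constants(m[[1]]$f), 1)

  # Hodgkin-Huxley-style rate: B = 0.1, v0 = -10
  m <- find_singularity_matches(
    expr_parse("0.1 * (V + 10) / (exp((V + 10) / 10) - 1)"), "V"
  )
  expect_length(m, 1L)
  expect_equal(m[[1]]$B, 0.1)
  expect_equal(m[[1]]$v0, -10)

  variants <- c(
    "(V - 5) / (exp(0.2 * (V - 5)) - 1)",
    "(V - 5) / (-1 + exp(0.2 * (V - 5)))",
    "(exp(0.2 * (V - 5)) - 1) / (V - 5)",
    "(-1 + exp(0.2 * (V - 5))) / (V - 5)",
    "2.5 * x * (V - 5) / (3 * exp(0.2 * (V - 5)) - 3)",
    "(V - 5) / (1 - exp(0.2 * (V - 5)))",
    "(V - 5) / expm1(0.2 * (V - 5))"
  )
  for (s in variants) {
    m <- find_singularity_matches(expr_parse(s), "V")
    expect_length(m, 1L)
    expect_equal(m[[1]]$v0, 5)
    expect_equal(abs(m[[1]]$B), 0.2)
  }
})

test_that("non-singular and manually fixed terms are not matched", {
  # denominator never zero on the reals
  expect_length(find_singularity_matches(expr_parse("V / (exp(V) + 1)"),
                                         "V"), 0L)
  # numerator root does not cancel the denominator root
  expect_length(find_singularity_matches(
    expr_parse("(V - 3) / (exp(V - 7) - 1)"), "V"
  ), 0L)
  # piecewise-wrapped terms are assumed manually fixed and skipped
  expect_length(find_singularity_matches(
    expr_parse("piecewise(abs(V) < 1e-6, 1, V / (exp(V) - 1))"), "V"
  ), 0L)
  # sigmoid rates and ohmic currents are clean
  expect_length(find_singularity_matches(
    expr_parse("0.07 * exp(V / 20) + g * x * (V - 40)"), c("V", "x")
  ), 0L)
})

test_that("singular points solve only for linear constant-coefficient U", {
  expect_equal(solve_singular_point(expr_parse("0.1 * (V + 10)"), "V"),
               -10)
  expect_equal(solve_singular_point(expr_parse("2 * V"), "V"), 0)
  expect_null(solve_singular_point(expr_parse("V * W"), "V"))
  expect_null(solve_singular_point(expr_parse("V^2 - 1"), "V"))
})

test_that("the piecewise fix interpolates the original at the bounds", {
  e <- expr_parse("V / (exp(V) - 1)")
  m <- find_singularity_matches(e, "V")[[1]]
  fx <- build_piecewise_fix(e, m, fix_config(1e-7))
  expect_equal(fx$bounds, c(-1e-7, 1e-7))
  # oracle: interpolated midpoint value is (g(eps) + g(-eps))/2 = 1 + eps^2/12
  mid <- expr_eval(fx$fixed_expr, list(V = 0))
  expect_lt(abs(mid - (1 + 1e-14 / 12)), 1e-15)
  # C0: the interpolant reproduces the endpoint values exactly
  for (b in fx$bounds) {
    expect_equal(expr_eval(fx$interpolant, list(V = b)),
                 b / expm1(b), tolerance = 1e-15)
  }
  # outside the region the original expression is returned verbatim
  expect_identical(fx$fixed_expr[[4]], e)
})

test_that("fix-region width in voltage is eps / |B|", {
  # GHK calcium term: U = (2F/RT) * V at T = 310 K, B per millivolt
  B <- 2 * 96485 / (8.314 * 310) / 1000
  e <- fold_constants(expr_parse(sprintf("V / (exp(%.17g * V) - 1)", B)))
  m <- find_singularity_matches(e, "V")[[1]]
  fx <- build_piecewise_fix(e, m, fix_config(1e-7))
  expect_equal(diff(fx$bounds) / 2, 1e-7 / B, tolerance = 1e-12)
})

test_that("model-level fixing recovers planted ground truth bottom-up", {
  gm <- generate_model(generator_spec(seed = 7, n_ghk_currents = 3))
  res <- fix_singularities_in_model(gm$model)
  expect_length(res$report, 3L)
  rep <- as.data.frame(res$report)
  truth <- gm$truth[order(gm$truth$equation), ]
  rep <- rep[order(rep$equation), ]
  expect_identical(rep$equation, truth$equation)
  expect_equal(rep$v0, truth$v0, tolerance = 1e-9)
  expect_equal(rep$B, truth$B, tolerance = 1e-9)

  # clamping V exactly at each planted v0 is finite only after fixing
  f_fixed <- model_rhs_function(res$model)
  f_orig <- model_rhs_function(gm$model)
  for (v0 in truth$v0) {
    y <- model_initial_state(gm$model)
    y["V"] <- v0
    expect_true(all(is.finite(f_fixed(0, y))))
    expect_false(all(is.finite(f_orig(0, y))))
  }
})

test_that("pre-wrapped manual fixes are honoured and skipped", {
  gm <- generate_model(generator_spec(seed = 8, n_ghk_currents = 2,
                                      prefixed_fraction = 1))
  res <- fix_singularities_in_model(gm$model)
  expect_length(res$report, 0L)
})

test_that("singularities hidden behind intermediates are fixed once", {
  # the GHK term materialises only after substituting w = V + 10
  vars <- list(
    new_variable("t", kind = "free", tags = "time"),
    new_variable("V", init = -80, kind = "state",
                 tags = "membrane_voltage"),
    new_variable("w", kind = "computed"),
    new_variable("r", kind = "computed")
  )
  m <- new_model("hidden", vars, list(
    new_equation("w", "V + 10"),
    new_equation("r", "0.3 * w / (exp(w / 10) - 1)"),
    new_equation("V", "-r * V", ode = TRUE)
  ), free_variable = "t")
  res <- fix_singularities_in_model(m)
  expect_length(res$report, 1L)
  expect_equal(res$report[[1]]$v0, -10)
  expect_identical(res$report[[1]]$equation, "r")
  # the fix lands at the defining node: the ODE equation itself still has
  # a single piecewise (via r), not one per use
  f <- model_rhs_function(res$model)
  expect_true(is.finite(f(0, c(V = -10))[["V"]]))
})

test_that("overlapping fix regions in one expression are a hard error", {
  e <- expr_parse(paste0(
    "(V - 1e-8) / (exp(V - 1e-8) - 1) + V / (exp(V) - 1)"
  ))
  matches <- find_singularity_matches(e, "V")
  expect_length(matches, 2L)
  vars <- list(
    new_variable("t", kind = "free", tags = "time"),
    new_variable("V", init = -80, kind = "state",
                 tags = "membrane_voltage")
  )
  m <- new_model("overlap", vars,
                 list(new_equation("V", e, ode = TRUE)),
                 free_variable = "t")
  expect_error(fix_singularities_in_model(m), "overlapping fix regions")
})

test_that("fixed and original expressions agree exactly outside the region", {
  set.seed(42)
  gm <- generate_model(generator_spec(seed = 13, n_ghk_currents = 2))
  res <- fix_singularities_in_model(gm$model)
  for (fx in res$report) {
    # the otherwise-branch is the original expression, so any point with
    # |U| > eps evaluates through identical code
    expect_identical(fx$fixed_expr[[4]], fx$original)
    for (dv in c(-0.5, -2e-6, 2e-6, 0.5)) {
      v <- fx$v0 + dv + sign(dv) * fx$eps / abs(fx$B)
      a <- eval_with_defaults(fx$fixed_expr, fx$variable, v)
      b <- eval_with_defaults(fx$original, fx$variable, v)
      expect_identical(a, b)
    }
  }
})

test_that("trajectories with and without fixes agree away from clamps", {
  skip_if_not_installed("deSolve")
  hh <- make_hh_1952_fixture()
  fixed <- fix_singularities_in_model(hh)$model
  f0 <- model_rhs_function(hh)
  f1 <- model_rhs_function(fixed)
  times <- seq(0, 30, 0.05)
  run <- function(f, y0) {
    deSolve::lsoda(y0, times, function(t, y, p) list(f(t, y)), NULL,
                   rtol = 1e-10, atol = 1e-10)
  }
  s0 <- run(f0, model_initial_state(hh))
  s1 <- run(f1, model_initial_state(fixed))
  # the action potential crosses both singular voltages ...
  expect_true(any(s0[, "V"] < -25) && any(s0[, "V"] > -10))
  # ... yet the fixed model reproduces the unfixed trajectory
  expect_lt(max(abs(s0[, -1] - s1[, -1])), 1e-6)
})
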