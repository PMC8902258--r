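# Code generation: expm1 rewriting, common-subexpression extraction, and
# the scheme-specific method sets in both dialects.

fixed_hh <- function() fix_singularities_in_model(make_hh_1952_fixture())

test_that("expm1 rewriting covers plain and K-factored differences", {
  expect_identical(apply_expm1_rewrite(expr_parse("exp(V) - 1")),
                   expr_parse("expm1(V)"))
  expect_identical(apply_expm1_rewrite(expr_parse("exp(V) + 1")),
                   expr_parse("exp(V) + 1"))
  e <- apply_expm1_rewrite(expr_parse("3 * exp(0.1 * V) - 3"))
  # numeric equivalence at random points against series-backed evaluation
  set.seed(5)
  for (v in stats::runif(100, -50, 50)) {
    want <- 3 * expm1(0.1 * v)
    expect_lt(rel_err(expr_eval(e, list(V = v)), want, floor = 1e-300),
              1e-15)
  }
  # rewriting preserves precision where the raw form loses it
  g <- apply_expm1_rewrite(expr_parse("V / (exp(V) - 1)"))
  u <- 1e-9
  expect_lt(rel_err(expr_eval(g, list(V = u)), g_series(u)), 1e-14)
})

test_that("common subexpressions are shared and back-substitute exactly", {
  res <- extract_common_subexpressions(list(expr_parse("a * b + c"),
                                            expr_parse("a * b - c")))
  expect_length(res$definitions, 1L)
  expect_identical(res$definitions[[1]], expr_parse("a * b"))
  nm <- names(res$definitions)
  expect_true(all(vapply(res$exprs, function(e) nm %in% expr_vars(e),
                         TRUE)))

  expect_length(extract_common_subexpressions(list(expr_parse("x")))$
                  definitions, 0L)

  # random generator expressions: substituting definitions back reproduces
  # the originals numerically
  gm <- generate_model(generator_spec(seed = 6))
  sf <- substitute_to_state_form(gm$model)
  res <- extract_common_subexpressions(unname(sf))
  set.seed(6)
  params <- Filter(function(v) v$kind == "parameter", gm$model$variables)
  for (i in seq_len(50)) {
    y <- random_state(gm$model)
    vals <- stats::setNames(lapply(params, `[[`, "init"), names(params))
    vals$time <- stats::runif(1, 0, 5)
    for (s in names(y)) vals[[s]] <- y[[s]]
    # evaluate definitions in order, then the rewritten expressions
    for (nm in names(res$definitions)) {
      vals[[nm]] <- expr_eval(res$definitions[[nm]], vals)
    }
    for (j in seq_along(res$exprs)) {
      want <- expr_eval(sf[[j]], vals)
      expect_lt(rel_err(expr_eval(res$exprs[[j]], vals), want,
                        floor = 1e-12), 1e-12)
    }
  }
  # every emitted definition is referenced at least twice
  uses <- table(unlist(lapply(c(res$definitions, res$exprs), expr_vars)))
  for (nm in names(res$definitions)) expect_gte(uses[[nm]], 2L)
})

test_that("scheme manifests match the required method sets", {
  hh <- fixed_hh()
  plain <- render(hh$model, options = codegen_options("plain"),
                  fix_report = hh$report)
  expect_setequal(plain$manifest, c(
    "constructor", "destructor", "UseCellMLDefaultStimulus", "GetIIonic",
    "ComputeDerivedQuantities", "OdeSystemInformation::Initialise",
    "EvaluateYDerivatives"
  ))
  jac <- compute_jacobian(hh$model)
  cv <- render(hh$model, jac,
               codegen_options("cvode", use_jacobian = TRUE))
  expect_true("EvaluateAnalyticJacobian" %in% cv$manifest)
  be <- render(hh$model, options = codegen_options("backward_euler"))
  expect_false("EvaluateYDerivatives" %in% be$manifest)
  expect_true(all(c("UpdateTransmembranePotential",
                    "ComputeOneStepExceptVoltage") %in% be$manifest))
  rl <- render(hh$model, options = codegen_options("rush_larsen"))
  expect_true(all(c("EvaluateEquations", "ComputeOneStepExceptVoltage")
                  %in% rl$manifest))
  expect_false("EvaluateYDerivatives" %in% rl$manifest)
  expect_error(codegen_options("plain", use_jacobian = TRUE),
               "cvode")
})

test_that("rendering is deterministic and annotation failures are loud", {
  hh <- fixed_hh()
  a <- render(hh$model, options = codegen_options("plain"))
  b <- render(hh$model, options = codegen_options("plain"))
  expect_identical(a$files, b$files)

  bare <- hh$model
  bare$variables$V$tags <- character()
  expect_error(render(bare, options = codegen_options("plain")),
               "membrane_voltage")
})

test_that("executable code reproduces direct symbolic evaluation", {
  hh <- fixed_hh()
  code <- render(hh$model, options = codegen_options(
    "plain", dialect = "executable"
  ), fix_report = hh$report)
  mod <- eval(parse(text = code$files[[1]]))
  f <- model_rhs_function(hh$model)
  set.seed(31)
  for (i in seq_len(20)) {
    y <- random_state(hh$model)
    t <- stats::runif(1, 0, 20)
    got <- mod$EvaluateYDerivatives(t, y)
    want <- f(t, y)
    expect_lt(max(rel_err(got[names(want)], want, floor = 1e-12)), 1e-12)
  }
  # stimulus pulse from tagged parameters
  expect_identical(mod$UseCellMLDefaultStimulus(5.2), 20)
  expect_identical(mod$UseCellMLDefaultStimulus(3), 0)
  info <- mod$OdeSystemInformation_Initialise()
  expect_identical(info$state_names, hh$model$states)
})

test_that("generated analytic Jacobian and implicit schemes execute", {
  hh <- fixed_hh()
  jac <- compute_jacobian(hh$model)
  code <- render(hh$model, jac, codegen_options(
    "cvode", use_jacobian = TRUE, dialect = "executable"
  ))
  mod <- eval(parse(text = code$files[[1]]))
  y <- model_initial_state(hh$model)
  y["V"] <- -33.3
  expect_equal(mod$EvaluateAnalyticJacobian(0, y),
               unname(eval_jacobian(jac, hh$model, y, 0)) * 1 +
                 matrix(0, 4, 4),
               tolerance = 1e-14, ignore_attr = TRUE)

  be <- eval(parse(text = render(hh$model, options = codegen_options(
    "backward_euler", dialect = "executable"
  ))$files[[1]]))
  y1 <- be$ComputeOneStepExceptVoltage(0, be$UpdateTransmembranePotential(
    0, y, 0.005
  ), 0.005)
  expect_true(all(is.finite(y1)))
  gates <- setdiff(names(y1), "V")
  expect_true(all(y1[gates] >= 0 & y1[gates] <= 1))

  rl <- eval(parse(text = render(hh$model, options = codegen_options(
    "rush_larsen", dialect = "executable"
  ))$files[[1]]))
  y2 <- rl$ComputeOneStepExceptVoltage(0, rl$EvaluateEquations(0, y,
                                                               0.005),
                                       0.005)
  expect_true(all(is.finite(y2)))
})

test_that("generated-code trajectories match direct integration", {
  skip_if_not_installed("deSolve")
  hh <- fixed_hh()
  code <- render(hh$model, options = codegen_options(
    "plain", dialect = "executable", expm1 = FALSE
  ))
  mod <- eval(parse(text = code$files[[1]]))
  f <- model_rhs_function(hh$model)
  times <- seq(0, 20, 0.1)
  y0 <- model_initial_state(hh$model)
  s1 <- deSolve::lsoda(y0, times, function(t, y, p) {
    list(mod$EvaluateYDerivatives(t, y))
  }, NULL, rtol = 1e-9, atol = 1e-9)
  s2 <- deSolve::lsoda(y0, times, function(t, y, p) list(f(t, y)), NULL,
                       rtol = 1e-9, atol = 1e-9)
  expect_lt(max(abs(s1[, -1] - s2[, -1])), 1e-8)
})

test_that("C++-like output carries the class structure and 17-digit literals", {
  hh <- fixed_hh()
  code <- render(hh$model, options = codegen_options("plain"))
  expect_named(code$files, c(
    "CellHodgkinHuxleySquidAxonModel1952FromCellML.hpp",
    "CellHodgkinHuxleySquidAxonModel1952FromCellML.cpp"
  ))
  hpp <- code$files[[1]]
  expect_match(hpp, "class CellHodgkinHuxleySquidAxonModel1952FromCellML")
  expect_match(hpp, "public AbstractCardiacCell")
  cpp <- code$files[[2]]
  expect_match(cpp, "EvaluateYDerivatives")
  expect_match(cpp, "pow\\(")
  # literals carry 17 significant digits for binary64 round-trip
  expect_match(cpp, "0.29999999999999999", fixed = TRUE)  # g_L = 0.3
  expect_match(cpp, "const double E_L = -10.613;", fixed = TRUE)
  expect_match(cpp, "Singularity fixes applied")
  cv <- render(hh$model, compute_jacobian(hh$model),
               codegen_options("cvode", use_jacobian = TRUE))
  expect_match(cv$files[[1]], "AbstractCvodeCell")
})

test_that("expression printing respects precedence in both dialects", {
  e <- expr_parse("-(a + b) * c^(d + 1) / (a - 2)")
  set.seed(8)
  for (i in 1:10) {
    vals <- list(a = stats::runif(1, 3, 5), b = stats::runif(1),
                 c = stats::runif(1, 1, 2), d = stats::runif(1))
    r_code <- expr_to_code(e, "r")
    expect_equal(eval(parse(text = r_code), vals), expr_eval(e, vals))
  }
  cxx <- expr_to_code(e, "cxx")
  expect_match(cxx, "pow\\(c, d \\+ 1\\)")
  pw <- expr_to_code(expr_parse("piecewise(V < 0, 1, 2)"), "cxx")
  expect_identical(pw, "(V < 0 ? 1 : 2)")
})
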