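# Core IR: dependency graph, state-form substitution, tagged lookup.

toy_model <- function() {
  new_model(
    "toy",
    list(
      new_variable("t", kind = "free"),
      new_variable("x", init = 1, kind = "state"),
      new_variable("V", init = -80, kind = "state"),
      new_variable("b", kind = "computed"),
      new_variable("a", kind = "computed"),
      new_variable("k", init = 2, kind = "parameter")
    ),
    list(
      new_equation("b", 2),
      new_equation("a", "b + 1"),
      new_equation("x", "a * x", ode = TRUE),
      new_equation("V", "-k * V", ode = TRUE)
    ),
    free_variable = "t"
  )
}

test_that("dependency graph orders definitions before their users", {
  m <- toy_model()
  dg <- build_dependency_graph(m)
  lhs <- vapply(m$equations[dg$order], `[[`, "", "lhs")
  is_ode <- vapply(m$equations[dg$order], `[[`, TRUE, "ode")
  expect_lt(match("b", lhs), match("a", lhs))
  # the ODE for x uses a, so it must come after a's definition
  expect_gt(which(lhs == "x" & is_ode), match("a", lhs))
  expect_setequal(dg$order, seq_along(m$equations))
})

test_that("cyclic algebraic dependencies raise an error naming variables", {
  expect_error(
    new_model(
      "cyc",
      list(new_variable("t", kind = "free"),
           new_variable("x", init = 0, kind = "state"),
           new_variable("a", kind = "computed"),
           new_variable("b", kind = "computed")),
      list(new_equation("a", "b"), new_equation("b", "a"),
           new_equation("x", "a", ode = TRUE)),
      free_variable = "t"
    ),
    "cyclic algebraic dependency.*a.*b"
  )
})

test_that("generated models topologically order rates before gate ODEs", {
  gm <- generate_model(generator_spec(seed = 1))
  dg <- build_dependency_graph(gm$model)
  eqs <- gm$model$equations[dg$order]
  lhs <- vapply(eqs, `[[`, "", "lhs")
  is_ode <- vapply(eqs, `[[`, TRUE, "ode")
  # independent oracle: in the generator wiring each gate ODE depends on
  # alpha_*/beta_*, each current on its driving potential, dV/dt on all
  # currents; so every definition must precede its user
  defined <- character()
  for (i in seq_along(eqs)) {
    if (!is_ode[[i]]) {
      deps <- intersect(expr_vars(eqs[[i]]$rhs), lhs[!is_ode])
      expect_true(all(deps %in% defined))
      defined <- c(defined, lhs[[i]])
    } else {
      deps <- intersect(expr_vars(eqs[[i]]$rhs), lhs[!is_ode])
      expect_true(all(deps %in% defined))
    }
  }
})

test_that("substitution to state form is semantics-preserving", {
  m <- toy_model()
  sf <- substitute_to_state_form(m)
  expect_identical(sf$b, 2)
  expect_identical(sf$a, 3)
  # an equation already in state form is returned unchanged
  expect_true(expr_identical(sf$d_V, expr_parse("-k * V")))

  # chained vs substituted evaluation on a deeper synthetic model
  gm <- generate_model(generator_spec(seed = 2))
  sf <- substitute_to_state_form(gm$model)
  f <- model_rhs_function(gm$model)
  set.seed(2)
  params <- Filter(function(v) v$kind == "parameter", gm$model$variables)
  for (i in seq_len(50)) {
    y <- random_state(gm$model)
    vals <- stats::setNames(lapply(params, `[[`, "init"),
                            vapply(params, `[[`, "", "name"))
    vals[[gm$model$free_variable]] <- stats::runif(1, 0, 100)
    for (s in names(y)) vals[[s]] <- y[[s]]
    chained <- f(vals[[gm$model$free_variable]], y)
    for (s in gm$model$states) {
      direct <- expr_eval(sf[[paste0("d_", s)]], vals)
      expect_lt(rel_err(direct, chained[[s]], floor = 1e-12), 1e-12)
    }
  }
})

test_that("substitution reports unresolved symbols", {
  m <- toy_model()
  m$equations[[2]]$rhs <- expr_parse("b + ghost")
  expect_error(substitute_to_state_form(m), "unresolved symbol 'ghost'")
})

test_that("tagged-variable lookup enforces uniqueness", {
  m <- toy_model()
  m$variables$V$tags <- "membrane_voltage"
  expect_identical(get_tagged_variable(m, "membrane_voltage")$name, "V")
  expect_error(get_tagged_variable(m, "membrane_potassium_current"),
               "tag not found")
  m$variables$x$tags <- "membrane_voltage"
  expect_error(get_tagged_variable(m, "membrane_voltage"), "ambiguous")
})

test_that("unused equations are flagged but retained", {
  m <- toy_model()
  m$variables[[length(m$variables) + 1]] <- new_variable("orphan",
                                                         kind = "computed")
  names(m$variables)[length(m$variables)] <- "orphan"
  m$equations[[length(m$equations) + 1]] <- new_equation("orphan", "k + 1")
  dg <- build_dependency_graph(m)
  expect_identical(sum(dg$unused), 1L)
  lhs <- vapply(m$equations, `[[`, "", "lhs")
  expect_identical(lhs[dg$unused], "orphan")
})

test_that("symbolic derivative matches base D() on smooth expressions", {
  exprs <- list(
    expr_parse("x^3 + 2 * x"),
    expr_parse("exp(-x / 5) * sin(x)"),
    expr_parse("1 / (1 + exp((x - 3) / 7))"),
    expr_parse("sqrt(x^2 + 1) * log(x + 10)")
  )
  set.seed(1)
  for (e in exprs) {
    mine <- sym_deriv(e, "x")
    base <- stats::D(e, "x")
    for (x in stats::runif(10, 0.5, 5)) {
      expect_lt(rel_err(expr_eval(mine, list(x = x)),
                        eval(base, list(x = x)), floor = 1e-12), 1e-12)
    }
  }
})

test_that("piecewise expressions evaluate, fold and differentiate", {
  e <- expr_parse("piecewise(x < 0, -x, x^2)")
  expect_identical(expr_eval(e, list(x = -3)), 3)
  expect_identical(expr_eval(e, list(x = 2)), 4)
  d <- sym_deriv(e, "x")
  expect_identical(expr_eval(d, list(x = -3)), -1)
  expect_identical(expr_eval(d, list(x = 2)), 4)
  # constant-condition folding
  expect_identical(fold_constants(expr_parse("piecewise(1 < 0, 5, 7)")), 7)
  expect_identical(fold_constants(expr_parse("piecewise(x > 0, 3, 3)")), 3)
  expect_error(sym_deriv(expr_parse("floor(x)"), "x"), "floor")
})
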