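# Shared test oracles and utilities.

# High-precision limit-completed g(U) = U / (exp(U) - 1) via its Bernoulli
# series around U = 0.  For |U| <= 1e-3 the truncation error is below
# 1e-24, far under double-precision resolution, so this is an exact oracle
# on the fix region without any dependence on the package's evaluation
# path.
g_series <- function(u) {
  stopifnot(all(abs(u) <= 1e-3))
  1 - u / 2 + u^2 / 12 - u^4 / 720 + u^6 / 30240
}

rel_err <- function(got, want, floor = 0) {
  abs(got - want) / pmax(abs(want), floor, .Machine$double.xmin)
}

# Evaluate an expression at a point, supplying mid-range values for any
# other free symbols (gates etc.).
eval_with_defaults <- function(e, var, value, defaults = list()) {
  env <- defaults
  env[[var]] <- value
  for (s in setdiff(expr_vars(e), names(env))) env[[s]] <- 0.5
  expr_eval(e, env)
}

# Random admissible state for a generated model: voltage in physiological
# range, gates within (0, 1).
random_state <- function(model) {
  y <- model_initial_state(model)
  for (s in names(y)) {
    y[[s]] <- if (s == "V") stats::runif(1, -90, 50) else
      stats::runif(1, 0.05, 0.95)
  }
  y
}

expect_expr_equal_numerically <- function(a, b, vars, n = 20,
                                          tol = 1e-12, range = c(-2, 2)) {
  for (i in seq_len(n)) {
    vals <- stats::setNames(
      as.list(stats::runif(length(vars), range[1L], range[2L])), vars
    )
    va <- expr_eval(a, vals)
    vb <- expr_eval(b, vals)
    expect_lt(rel_err(va, vb, floor = 1e-12), tol)
  }
}
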