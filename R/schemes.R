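# Linear-in-self classification of state equations and the update
# expressions for the backward-Euler and Rush-Larsen schemes.  A gating
# equation dx/dt = alpha*(1 - x) - beta*x is affine in x with x-free
# coefficients a = alpha, b = -(alpha + beta); both schemes exploit this by
# freezing a and b over a step.

#' Decompose a state equation as dx/dt = a + b*x
#'
#' Returns the affine decomposition of the state's right-hand side (in state
#' form) when it is affine in the state with coefficients free of it, and
#' `NULL` otherwise.  The voltage-tagged state is always classified
#' nonlinear: it is updated separately by the voltage step of each scheme.
#'
#' @param model A `cellml_model`.
#' @param state Name of a state variable.
#' @return A `linear_decomposition` (list with `state`, `a`, `b`) or `NULL`.
#' @export
decompose_linear <- function(model, state) {
  stopifnot(state %in% model$states)
  vtag <- get_tagged_variable(model, "membrane_voltage", required = FALSE)
  if (!is.null(vtag) && identical(vtag$name, state)) return(NULL)
  sf <- substitute_to_state_form(model)
  rhs <- sf[[paste0("d_", state)]]
  b <- sym_deriv(rhs, state)
  if (contains_var(b, state)) return(NULL)
  a <- fold_constants(sub_vars(rhs, stats::setNames(list(0), state)))
  if (contains_var(a, state)) return(NULL)
  # piecewise conditions on the state itself would make b discontinuous in x
  structure(list(state = state, a = a, b = b),
            class = "linear_decomposition")
}

#' @export
print.linear_decomposition <- function(x, ...) {
  cat(sprintf("<linear_decomposition> d%s/dt = a + b*%s\n  a = %s\n  b = %s\n",
              x$state, x$state, expr_text(x$a), expr_text(x$b)))
  invisible(x)
}

#' Backward-Euler update expression
#'
#' For the affine ODE dx/dt = a + b*x with coefficients frozen over the
#' step, the implicit Euler step solves x_new = x + dt*(a + b*x_new), giving
#' `(x + a*dt) / (1 - b*dt)`.
#'
#' @param decomp A [decompose_linear()] result.
#' @param dt Time-step symbol name (default `"dt"`) or a number.
#' @return A symbolic expression for the updated state.
#' @export
backward_euler_update <- function(decomp, dt = "dt") {
  stopifnot(inherits(decomp, "linear_decomposition"))
  dts <- if (is.character(dt)) as.name(dt) else dt
  x <- as.name(decomp$state)
  fold_constants(bin(
    "/",
    bin("+", x, bin("*", decomp$a, dts)),
    bin("-", 1, bin("*", decomp$b, dts))
  ))
}

#' Rush-Larsen update expression
#'
#' The exact solution of dx/dt = a + b*x over a step with frozen
#' coefficients: `x_inf + (x - x_inf) * exp(b*dt)` where `x_inf = -a/b`.
#' When `b` folds to zero the update degenerates to the explicit step
#' `x + a*dt`.
#'
#' @param decomp A [decompose_linear()] result.
#' @param dt Time-step symbol name (default `"dt"`) or a number.
#' @return A symbolic expression for the updated state.
#' @export
rush_larsen_update <- function(decomp, dt = "dt") {
  stopifnot(inherits(decomp, "linear_decomposition"))
  dts <- if (is.character(dt)) as.name(dt) else dt
  x <- as.name(decomp$state)
  b <- fold_constants(decomp$b)
  if (is_num(b) && b == 0) {
    return(fold_constants(bin("+", x, bin("*", decomp$a, dts))))
  }
  x_inf <- fold_constants(neg(bin("/", decomp$a, b)))
  fold_constants(bin(
    "+", x_inf,
    bin("*", bin("-", x, x_inf), fun1("exp", bin("*", b, dts)))
  ))
}

#' Classify all states of a model for an implicit scheme
#'
#' @param model A `cellml_model`.
#' @return Named list over states: each a `linear_decomposition` or `NULL`
#'   (nonlinear / voltage).
#' @export
classify_states <- function(model) {
  out <- lapply(model$states, function(s) decompose_linear(model, s))
  stats::setNames(out, model$states)
}
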