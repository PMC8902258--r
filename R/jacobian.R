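# Analytic Jacobian of the ODE system: symbolic partial derivatives of each
# state derivative with respect to each state, computed after full
# substitution to state form (so no chain-rule bookkeeping across
# intermediate variables is needed).  Piecewise right-hand sides are
# differentiated branch-wise with their conditions kept.

#' Compute the analytic Jacobian of a model
#'
#' Entry (i, j) is the partial derivative of `d(state_i)/dt` with respect to
#' `state_j`, as a symbolic expression over states, the free variable and
#' parameters.  Singularity fixes already present in the model are
#' differentiated as-is (branch-wise); within a fix region the interpolant's
#' constant slope is used.
#'
#' @param model A `cellml_model` (fixed/converted as desired).
#' @return A `jacobian_matrix`: list with `states` and `entries` (row-major
#'   list of lists of expressions).
#' @export
compute_jacobian <- function(model) {
  sf <- substitute_to_state_form(model)
  states <- model$states
  entries <- lapply(states, function(si) {
    rhs <- sf[[paste0("d_", si)]]
    lapply(states, function(sj) sym_deriv(rhs, sj))
  })
  structure(list(states = states, entries = entries),
            class = "jacobian_matrix")
}

#' @export
print.jacobian_matrix <- function(x, ...) {
  n <- length(x$states)
  cat(sprintf("<jacobian_matrix> %d x %d over states: %s\n", n, n,
              paste(x$states, collapse = ", ")))
  invisible(x)
}

#' Evaluate a Jacobian numerically
#'
#' @param jac A `jacobian_matrix`.
#' @param model The model it was derived from (for parameter values).
#' @param state Named numeric vector of state values.
#' @param t Value of the free variable (default 0).
#' @return Numeric matrix with dimnames equal to the state order.
#' @export
eval_jacobian <- function(jac, model, state, t = 0) {
  vals <- list()
  for (p in Filter(function(v) v$kind == "parameter", model$variables)) {
    vals[[p$name]] <- p$init
  }
  vals[[model$free_variable]] <- t
  for (s in jac$states) vals[[s]] <- unname(state[[s]])
  n <- length(jac$states)
  out <- matrix(0, n, n, dimnames = list(jac$states, jac$states))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- expr_eval(jac$entries[[i]][[j]], vals)
    }
  }
  out
}

#' Finite-difference Jacobian (validation oracle)
#'
#' Central finite differences of the model right-hand side, used to validate
#' analytic Jacobians numerically.
#'
#' @param model A `cellml_model`.
#' @param state Named numeric state vector.
#' @param t Free-variable value.
#' @param rel_step Relative step size (default `1e-6`).
#' @return Numeric matrix matching [eval_jacobian()] layout.
#' @export
fd_jacobian <- function(model, state, t = 0, rel_step = 1e-6) {
  f <- model_rhs_function(model)
  n <- length(model$states)
  out <- matrix(0, n, n, dimnames = list(model$states, model$states))
  for (j in seq_len(n)) {
    h <- rel_step * max(1, abs(state[[j]]))
    yp <- state; yp[[j]] <- yp[[j]] + h
    ym <- state; ym[[j]] <- ym[[j]] - h
    out[, j] <- (f(t, yp) - f(t, ym)) / (2 * h)
  }
  out
}
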