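# Detection and repair of removable 0/0 singularities of
# Goldman-Hodgkin-Katz form.  Ion-current equations frequently contain terms
#
#   C(V) = f(V) * (V - v0) / (exp(B*(V - v0)) - 1)
#
# which tend to 0/0 as V -> v0 even though the limit f(v0)/B is finite.
# Writing U = B*(V - v0), the dimensionless factor g(U) = U/(exp(U) - 1)
# becomes numerically unstable within roughly |U| <= 1e-7 in double
# precision.  The fixer locates such terms (all four variants: U/(e^U - 1),
# U/(-1 + e^U), (e^U - 1)/U, (-1 + e^U)/U, including K*e^U - K spellings),
# and replaces each with a piecewise expression that linearly interpolates
# the original expression between its values at the region boundaries
# U = -eps and U = +eps, giving C0 continuity at both edges.

#' Singularity-fix configuration
#'
#' @param eps Half-width of the fix region in dimensionless U-space.  The
#'   default `1e-7` is the width of the numerically unstable band around
#'   `U = 0` in double precision; the same fixed range works for all GHK-form
#'   singularities because U is non-dimensional.
#' @return A `fix_config` list.
#' @export
fix_config <- function(eps = 1e-7) {
  stopifnot(is.numeric(eps), length(eps) == 1L, eps > 0)
  structure(list(eps = eps), class = "fix_config")
}

# Match the two-term pattern K*exp(W) - K (covering exp(W) - 1, -1 + exp(W),
# 1 - exp(W), K*expm1(W), ...).  Returns list(K, W, exp_first) or NULL.
match_exp_minus_k <- function(e) {
  if (is.call(e) && call_name(e) == "expm1") {
    return(list(K = 1, W = e[[2L]], exp_first = TRUE))
  }
  terms <- flatten_sum(e)
  if (length(terms) == 1L) {
    fp <- flatten_product(terms[[1L]]$term)
    if (length(fp$factors) == 1L && is.call(fp$factors[[1L]]) &&
        call_name(fp$factors[[1L]]) == "expm1") {
      return(list(K = terms[[1L]]$sign * fp$coef,
                  W = fp$factors[[1L]][[2L]], exp_first = TRUE))
    }
    return(NULL)
  }
  if (length(terms) != 2L) return(NULL)
  k_exp <- NULL; w <- NULL; k_const <- NULL; exp_first <- NA
  for (i in seq_along(terms)) {
    t <- terms[[i]]
    fp <- flatten_product(t$term)
    cf <- t$sign * fp$coef
    if (length(fp$factors) == 0L) {
      if (!is.null(k_const)) return(NULL)
      k_const <- cf
    } else if (length(fp$factors) == 1L && is.call(fp$factors[[1L]]) &&
               call_name(fp$factors[[1L]]) == "exp") {
      if (!is.null(k_exp)) return(NULL)
      k_exp <- cf
      w <- fp$factors[[1L]][[2L]]
      exp_first <- (i == 1L)
    } else {
      return(NULL)
    }
  }
  if (is.null(k_exp) || is.null(k_const) || k_exp == 0) return(NULL)
  if (abs(k_const + k_exp) > 1e-12 * abs(k_exp)) return(NULL)
  list(K = k_exp, W = w, exp_first = exp_first)
}

# Within a product, find a factor affine in `var` whose root is v0.
# Returns list(index, slope) or NULL.
find_affine_factor <- function(factors, var, v0) {
  for (i in seq_along(factors)) {
    ac <- affine_coeffs(factors[[i]], var)
    if (is.null(ac) || ac[["slope"]] == 0) next
    root <- -ac[["intercept"]] / ac[["slope"]]
    if (abs(root - v0) <= 1e-9 * max(1, abs(v0))) {
      return(list(index = i, slope = ac[["slope"]]))
    }
  }
  NULL
}

new_match <- function(expr, variant, var, B, v0, U, f) {
  structure(
    list(expr = expr, variant = variant, var = var, B = B, v0 = v0,
         U = U, f = f, A = fold_constants(bin("/", f, B))),
    class = "singularity_match"
  )
}

#' @export
print.singularity_match <- function(x, ...) {
  cat(sprintf("<singularity_match> %s at %s = %g (B = %g)\n",
              x$variant, x$var, x$v0, x$B))
  invisible(x)
}

# Attempt a GHK-form match at a single quotient node num/den.
match_ghk_quotient <- function(expr, num, den, candidates) {
  for (var in candidates) {
    # direct variants: affine-root numerator over K*(exp(W) - 1)
    dk <- match_exp_minus_k(den)
    if (!is.null(dk)) {
      ac <- affine_coeffs(dk$W, var)
      if (!is.null(ac) && ac[["slope"]] != 0) {
        B <- ac[["slope"]]
        v0 <- -ac[["intercept"]] / B
        fp <- flatten_product(num)
        hit <- find_affine_factor(fp$factors, var, v0)
        if (!is.null(hit)) {
          rest <- fp$factors[-hit$index]
          f <- fold_constants(
            rebuild_product(fp$coef * hit$slope / dk$K, rest)
          )
          variant <- if (dk$exp_first) "U/(exp(U)-1)" else "U/(-1+exp(U))"
          return(new_match(expr, variant, var, B, v0, dk$W, f))
        }
      }
    }
    # reciprocal variants: K*(exp(W) - 1) over affine-root denominator
    nk <- match_exp_minus_k(num)
    if (!is.null(nk)) {
      ac <- affine_coeffs(nk$W, var)
      if (!is.null(ac) && ac[["slope"]] != 0) {
        B <- ac[["slope"]]
        v0 <- -ac[["intercept"]] / B
        fp <- flatten_product(den)
        hit <- find_affine_factor(fp$factors, var, v0)
        if (!is.null(hit)) {
          rest <- fp$factors[-hit$index]
          f <- fold_constants(
            bin("/", nk$K, rebuild_product(fp$coef * hit$slope, rest))
          )
          variant <- if (nk$exp_first) "(exp(U)-1)/U" else "(-1+exp(U))/U"
          return(new_match(expr, variant, var, B, v0, nk$W, f))
        }
      }
    }
  }
  NULL
}

#' Find GHK-form removable singularities in an expression
#'
#' Recursively scans an expression, term by term, for quotients matching one
#' of the four GHK singularity variants in any of the candidate variables.
#' Subtrees under `piecewise` nodes are never matched: a piecewise around a
#' singular term is taken to be a manual fix already applied by the model
#' author.
#'
#' @param expr A symbolic expression.
#' @param candidates Character vector of variable names that may carry the
#'   singularity (usually the membrane voltage first, then other states).
#' @return List of `singularity_match` objects (empty if none).
#' @export
find_singularity_matches <- function(expr, candidates) {
  out <- list()
  walk <- function(e) {
    if (!is.call(e)) return()
    op <- call_name(e)
    if (op == "piecewise") return() # assumed manually fixed
    if (op == "/") {
      m <- match_ghk_quotient(e, e[[2L]], e[[3L]], candidates)
      if (!is.null(m)) {
        out[[length(out) + 1L]] <<- m
        return() # do not descend into a matched term
      }
    }
    for (a in call_args(e)) walk(a)
  }
  walk(fold_constants(expr))
  out
}

#' Solve U = 0 for the singular point
#'
#' @param U A symbolic expression linear in `var` with constant coefficients.
#' @param var Variable name.
#' @return The value `v0` with `U(v0) = 0`, or `NULL` (no-constant-root
#'   signal) when `U` is not linear in `var` with constant coefficients.
#' @export
solve_singular_point <- function(U, var) {
  ac <- affine_coeffs(fold_constants(U), var)
  if (is.null(ac) || ac[["slope"]] == 0) return(NULL)
  -ac[["intercept"]] / ac[["slope"]]
}

#' Build the piecewise linear-interpolation fix for one match
#'
#' Replaces the matched expression with a piecewise statement: within the
#' closed region `v0 - eps/|B| <= var <= v0 + eps/|B|` (i.e. `|U| <= eps`)
#' the value is the unique line through the original expression evaluated at
#' the two region boundaries; outside, the original expression is returned
#' unchanged.  Endpoint evaluation uses the full original expression (so a
#' voltage-dependent prefactor costs nothing) with `exp(U) - 1` rewritten
#' through `expm1` for full precision at `|U| = eps`.
#'
#' @param expr The expression containing the matched term (often the matched
#'   quotient itself).
#' @param match A `singularity_match`.
#' @param config A [fix_config()].
#' @return A `piecewise_fix` list with fields `bounds`, `endpoints`,
#'   `interpolant`, `fixed_expr`, `eps`, plus the match metadata.
#' @export
build_piecewise_fix <- function(expr, match, config = fix_config()) {
  eps <- config$eps
  half_width <- eps / abs(match$B)
  vl <- match$v0 - half_width
  vr <- match$v0 + half_width
  precise <- apply_expm1_rewrite(expr)
  yl <- fold_constants(sub_vars(precise, stats::setNames(list(vl),
                                                         match$var)))
  yr <- fold_constants(sub_vars(precise, stats::setNames(list(vr),
                                                         match$var)))
  for (y in list(yl, yr)) {
    if (is_num(y) && !is.finite(y)) {
      stop("fix failure: endpoint evaluation of the original expression ",
           "is non-finite at ", match$var, " = ", if (identical(y, yl)) vl
           else vr)
    }
    vs <- expr_vars(y)
    if (length(vs) == 0L && !is_num(y)) {
      val <- expr_eval(y)
      if (!is.finite(val)) {
        stop("fix failure: endpoint evaluation is non-finite")
      }
    }
  }
  slope <- fold_constants(bin("/", bin("-", yr, yl), vr - vl))
  interpolant <- fold_constants(
    bin("+", yl, bin("*", slope, bin("-", as.name(match$var), vl)))
  )
  cond <- bin("&", bin(">=", as.name(match$var), vl),
              bin("<=", as.name(match$var), vr))
  fixed <- as.call(list(as.name("piecewise"), cond, interpolant, expr))
  structure(
    list(variable = match$var, v0 = match$v0, B = match$B,
         variant = match$variant, bounds = c(vl, vr),
         endpoints = list(left = yl, right = yr),
         interpolant = interpolant, original = expr, fixed_expr = fixed,
         eps = eps, U = match$U, f = match$f, A = match$A),
    class = "piecewise_fix"
  )
}

#' @export
print.piecewise_fix <- function(x, ...) {
  cat(sprintf(
    "<piecewise_fix> %s: %s = %g (B = %g), region [%.6g, %.6g]\n",
    x$variant, x$variable, x$v0, x$B, x$bounds[1L], x$bounds[2L]
  ))
  invisible(x)
}

subtree_present <- function(e, target) {
  if (identical(e, target)) return(TRUE)
  if (!is.call(e)) return(FALSE)
  for (a in call_args(e)) if (subtree_present(a, target)) return(TRUE)
  FALSE
}

# Replace one subtree (located by structural identity) with another.
replace_subtree <- function(e, target, replacement) {
  if (identical(e, target)) return(replacement)
  if (!is.call(e)) return(e)
  as.call(c(e[[1L]], lapply(call_args(e), replace_subtree,
                            target = target, replacement = replacement)))
}

#' Detect and fix all GHK singularities in a model
#'
#' Walks the equation dependency graph bottom-up (leaf definitions first).
#' Each equation is rewritten in terms of state variables for detection, so
#' that the voltage appears explicitly wherever there is any dependence on
#' it; a detected fix is applied once, at the stored defining equation (not
#' at every substituted occurrence).  Equations at higher levels then see the
#' already-fixed (piecewise, hence skipped) lower-level terms, so no
#' singularity is fixed twice.
#'
#' @param model A `cellml_model`.
#' @param config A [fix_config()].
#' @param candidates Candidate singular variables; defaults to the states
#'   with the `membrane_voltage`-tagged variable (if any) first.
#' @return List with `model` (fixed) and `report`, a `singularity_report`
#'   (list of `piecewise_fix`, with any per-equation failures attached as
#'   `warnings`).
#' @export
fix_singularities_in_model <- function(model, config = fix_config(),
                                       candidates = NULL) {
  if (is.null(candidates)) {
    vtag <- get_tagged_variable(model, "membrane_voltage", required = FALSE)
    candidates <- model$states
    if (!is.null(vtag)) {
      candidates <- c(vtag$name, setdiff(candidates, vtag$name))
    }
  }
  dg <- build_dependency_graph(model)
  fixes <- list()
  warnings_out <- character()

  # state-form substitution map maintained incrementally from the (possibly
  # already fixed) lower-level equations
  sub_map <- list()
  keep <- c(model$states, model$free_variable,
            names(Filter(function(v) v$kind == "parameter",
                         model$variables)))
  for (i in dg$order) {
    eq <- model$equations[[i]]
    state_form <- fold_constants(sub_vars(eq$rhs, sub_map))
    matches <- find_singularity_matches(state_form, candidates)
    if (length(matches) > 0L) {
      check_disjoint_regions(matches, config)
      # detection ran on the state form; the fix is applied once, at this
      # defining equation — in place when the matched term appears in the
      # stored right-hand side, otherwise on the state-form rewrite
      stored <- fold_constants(model$equations[[i]]$rhs)
      for (m in matches) {
        fx <- tryCatch(build_piecewise_fix(m$expr, m, config),
                       error = function(err) conditionMessage(err))
        if (is.character(fx)) {
          warnings_out <- c(warnings_out,
                            sprintf("equation '%s': %s", eq$lhs, fx))
          next
        }
        fx$equation <- eq$lhs
        fx$ode <- eq$ode
        if (subtree_present(stored, m$expr)) {
          stored <- replace_subtree(stored, m$expr, fx$fixed_expr)
        } else {
          stored <- replace_subtree(state_form, m$expr, fx$fixed_expr)
        }
        state_form <- replace_subtree(state_form, m$expr, fx$fixed_expr)
        fixes[[length(fixes) + 1L]] <- fx
      }
      model$equations[[i]]$rhs <- stored
    }
    if (!eq$ode) sub_map[[eq$lhs]] <- state_form
  }
  report <- structure(fixes, class = "singularity_report")
  attr(report, "warnings") <- warnings_out
  list(model = model, report = report)
}

check_disjoint_regions <- function(matches, config) {
  if (length(matches) < 2L) return(invisible())
  for (i in seq_along(matches)) {
    for (j in seq_len(i - 1L)) {
      mi <- matches[[i]]; mj <- matches[[j]]
      if (!identical(mi$var, mj$var)) next
      sep <- abs(mi$v0 - mj$v0)
      if (sep < config$eps / abs(mi$B) + config$eps / abs(mj$B)) {
        stop("overlapping fix regions: singular points ", mi$v0, " and ",
             mj$v0, " in variable ", mi$var,
             " are closer than the combined region widths")
      }
    }
  }
  invisible()
}

#' @export
print.singularity_report <- function(x, ...) {
  cat(sprintf("Singularity fixes applied: %d\n", length(x)))
  for (fx in x) {
    cat(sprintf(
      "  %-12s %s = %-8g B = %-8g region [%.6g, %.6g]  (%s)\n",
      paste0(fx$equation, ":"), fx$variable, fx$v0, fx$B,
      fx$bounds[1L], fx$bounds[2L], fx$variant
    ))
  }
  w <- attr(x, "warnings")
  if (length(w)) cat("Warnings:\n", paste(" ", w, collapse = "\n"), "\n")
  invisible(x)
}

#' Tabulate a singularity report
#'
#' @param x A `singularity_report`.
#' @param ... Unused.
#' @return A data.frame with one row per fix: equation, variable, v0, B,
#'   lower/upper bounds and form variant.
#' @export
as.data.frame.singularity_report <- function(x, ...) {
  if (length(x) == 0L) {
    return(data.frame(equation = character(), variable = character(),
                      v0 = numeric(), B = numeric(), lower = numeric(),
                      upper = numeric(), variant = character()))
  }
  data.frame(
    equation = vapply(x, `[[`, "", "equation"),
    variable = vapply(x, `[[`, "", "variable"),
    v0 = vapply(x, `[[`, 0, "v0"),
    B = vapply(x, `[[`, 0, "B"),
    lower = vapply(x, function(f) f$bounds[1L], 0),
    upper = vapply(x, function(f) f$bounds[2L], 0),
    variant = vapply(x, `[[`, "", "variant")
  )
}
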