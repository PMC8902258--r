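# Symbolic expressions are plain R language objects: numeric literals,
# symbols (variable references) and calls.  This gives us an operator tree
# with evaluation for free via eval(), while all structural transforms
# (substitution, folding, differentiation, pattern matching) walk the tree
# explicitly.  piecewise() is the single non-base primitive; it is an
# ordinary R function so expressions containing it remain evaluable.

#' Piecewise conditional expression
#'
#' Evaluates an alternating sequence of `(condition, value)` pairs followed by
#' a final otherwise-value, returning the value of the first true condition.
#' This is the runtime counterpart of the MathML `<piecewise>` element and the
#' node used by the singularity fixer.  Vectorised over conditions and values.
#'
#' @param ... An odd number of arguments: `cond1, val1, ..., condK, valK,
#'   otherwise`.
#' @return The selected value(s).
#' @examples
#' piecewise(FALSE, 1, TRUE, 2, 3) # 2
#' piecewise(c(TRUE, FALSE), 1, 0) # c(1, 0)
#' @export
piecewise <- function(...) {
  args <- list(...)
  n <- length(args)
  if (n < 1L || n %% 2L != 1L) {
    stop("piecewise() needs cond/value pairs plus an otherwise value")
  }
  out <- args[[n]]
  k <- (n - 1L) %/% 2L
  for (i in rev(seq_len(k))) {
    cond <- args[[2L * i - 1L]]
    val <- args[[2L * i]]
    if (length(cond) == 1L && length(val) <= 1L && length(out) <= 1L) {
      if (isTRUE(cond)) out <- val
    } else {
      out <- ifelse(cond, val, out)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_num <- function(e) is.numeric(e) && length(e) == 1L
is_sym <- function(e) is.symbol(e)

call_name <- function(e) {
  if (!is.call(e)) return(NA_character_)
  as.character(e[[1L]])
}

call_args <- function(e) as.list(e)[-1L]

#' Parse an expression from text
#'
#' Convenience wrapper used throughout: parses R expression syntax into the
#' symbolic tree form, stripping grouping parentheses.
#'
#' @param text A single string of R expression syntax.
#' @return A symbolic expression (language object).
#' @examples
#' expr_parse("0.1 * (V + 10) / (exp((V + 10) / 10) - 1)")
#' @export
expr_parse <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  strip_parens(str2lang(text))
}

#' Render an expression as text
#'
#' @param e A symbolic expression.
#' @return A single string.
#' @export
expr_text <- function(e) {
  paste(deparse(e, width.cutoff = 500L), collapse = " ")
}

# Remove grouping `(` nodes the R parser inserts; they carry no semantics.
strip_parens <- function(e) {
  if (is.call(e)) {
    if (identical(e[[1L]], as.name("("))) return(strip_parens(e[[2L]]))
    as.call(c(e[[1L]], lapply(call_args(e), strip_parens)))
  } else {
    e
  }
}

#' Variables referenced by an expression
#'
#' @param e A symbolic expression.
#' @return Character vector of unique symbol names, in first-appearance order.
#' @export
expr_vars <- function(e) {
  out <- character()
  walk <- function(x) {
    if (is.symbol(x)) {
      out[[length(out) + 1L]] <<- as.character(x)
    } else if (is.call(x)) {
      for (a in call_args(x)) walk(a)
    }
  }
  walk(e)
  unique(out)
}

contains_var <- function(e, name) {
  if (is.symbol(e)) return(identical(as.character(e), name))
  if (is.call(e)) {
    for (a in call_args(e)) if (contains_var(a, name)) return(TRUE)
  }
  FALSE
}

#' Substitute variables in an expression
#'
#' @param e A symbolic expression.
#' @param map Named list; each element a number or symbolic expression that
#'   replaces the symbol of that name.
#' @return The rewritten expression (no folding applied).
#' @export
sub_vars <- function(e, map) {
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (nm %in% names(map)) {
      r <- map[[nm]]
      if (is.numeric(r)) return(as.numeric(r))
      return(r)
    }
    return(e)
  }
  if (is.call(e)) {
    return(as.call(c(e[[1L]], lapply(call_args(e), sub_vars, map = map))))
  }
  e
}

# Operators the folder/evaluator understand.  Everything else is passed
# through untouched by folding and rejected loudly by differentiation.
.arith_ops <- c("+", "-", "*", "/", "^")
.fun_ops <- c(
  "exp", "expm1", "log", "log10", "log2", "sqrt", "abs",
  "floor", "ceiling", "sign",
  "sin", "cos", "tan", "asin", "acos", "atan",
  "sinh", "cosh", "tanh"
)
.rel_ops <- c("<", "<=", ">", ">=", "==", "!=")
.bool_ops <- c("&", "|", "!")

known_operator <- function(op) {
  op %in% c(.arith_ops, .fun_ops, .rel_ops, .bool_ops, "piecewise", "(")
}

#' Fold constant subexpressions
#'
#' Recursively evaluates subtrees whose arguments are all numeric, and applies
#' safe algebraic identities (`x*1`, `x+0`, `x^1`, `0*x`, double negation).
#' Subtrees whose numeric value would be non-finite (e.g. `0/0`) are left
#' symbolic so that downstream checks can detect them.
#'
#' @param e A symbolic expression.
#' @return The folded expression.
#' @export
fold_constants <- function(e) {
  if (!is.call(e)) return(e)
  op <- call_name(e)
  if (identical(op, "(")) return(fold_constants(e[[2L]]))
  args <- lapply(call_args(e), fold_constants)
  ee <- as.call(c(e[[1L]], args))

  all_const <- all(vapply(args, function(a) is_num(a) || is.logical(a), TRUE))
  if (all_const && known_operator(op) && op != "piecewise") {
    v <- tryCatch(eval(ee, baseenv()), error = function(err) NULL)
    if (!is.null(v) && length(v) == 1L &&
        (is.logical(v) || (is.numeric(v) && is.finite(v)))) {
      return(if (is.logical(v)) v else as.numeric(v))
    }
    return(ee)
  }

  # algebraic identities on partially-constant nodes
  if (op == "*" && length(args) == 2L) {
    a <- args[[1L]]; b <- args[[2L]]
    if (is_num(a) && a == 0) return(0)
    if (is_num(b) && b == 0) return(0)
    if (is_num(a) && a == 1) return(b)
    if (is_num(b) && b == 1) return(a)
  } else if (op == "+" && length(args) == 2L) {
    a <- args[[1L]]; b <- args[[2L]]
    if (is_num(a) && a == 0) return(b)
    if (is_num(b) && b == 0) return(a)
  } else if (op == "-" && length(args) == 2L) {
    a <- args[[1L]]; b <- args[[2L]]
    if (is_num(b) && b == 0) return(a)
    if (is_num(a) && a == 0) return(fold_constants(as.call(list(as.name("-"), b))))
  } else if (op == "-" && length(args) == 1L) {
    a <- args[[1L]]
    if (is.call(a) && call_name(a) == "-" && length(call_args(a)) == 1L) {
      return(call_args(a)[[1L]])
    }
  } else if (op == "/" && length(args) == 2L) {
    a <- args[[1L]]; b <- args[[2L]]
    if (is_num(b) && b == 1) return(a)
    if (is_num(a) && a == 0 && !is_num(b)) return(0)
  } else if (op == "^" && length(args) == 2L) {
    a <- args[[1L]]; b <- args[[2L]]
    if (is_num(b) && b == 1) return(a)
    if (is_num(b) && b == 0) return(1)
    if (is_num(a) && a == 1) return(1)
  } else if (op == "piecewise") {
    # drop pairs with constant-FALSE conditions; collapse on constant-TRUE
    n <- length(args)
    k <- (n - 1L) %/% 2L
    kept <- list()
    for (i in seq_len(k)) {
      cond <- args[[2L * i - 1L]]
      val <- args[[2L * i]]
      if (isFALSE(cond)) next
      if (isTRUE(cond) && length(kept) == 0L) return(val)
      kept <- c(kept, list(cond, val))
    }
    if (length(kept) == 0L) return(args[[n]])
    vals <- c(kept[seq(2L, length(kept), by = 2L)], args[n])
    if (all(vapply(vals, identical, TRUE, y = vals[[1L]]))) {
      return(vals[[1L]]) # all branches agree; condition is irrelevant
    }
    return(as.call(c(as.name("piecewise"), kept, args[n])))
  }
  ee
}

#' Evaluate an expression numerically
#'
#' @param e A symbolic expression.
#' @param values Named list or numeric vector of variable values.
#' @return A numeric value (may be `NaN`/`Inf` if the expression is singular
#'   at that point).
#' @export
expr_eval <- function(e, values = list()) {
  env <- list2env(as.list(values), parent = baseenv())
  env$piecewise <- piecewise
  eval(e, env)
}

bin <- function(op, a, b) as.call(list(as.name(op), a, b))
neg <- function(a) {
  if (is_num(a)) return(-a)
  as.call(list(as.name("-"), a))
}
fun1 <- function(f, a) as.call(list(as.name(f), a))

#' Symbolic derivative
#'
#' Differentiates an expression with respect to one variable.  Piecewise
#' expressions are differentiated branch-wise with their conditions kept;
#' `abs` is differentiated as `sign(u) * u'`; `floor`/`ceiling` are rejected
#' with an error naming the operator.
#'
#' @param e A symbolic expression.
#' @param var Variable name (string) to differentiate with respect to.
#' @return The derivative expression, constant-folded.
#' @export
sym_deriv <- function(e, var) {
  fold_constants(sym_deriv_raw(e, var))
}

sym_deriv_raw <- function(e, var) {
  if (is_num(e) || is.logical(e)) return(0)
  if (is.symbol(e)) return(if (identical(as.character(e), var)) 1 else 0)
  if (!is.call(e)) stop("cannot differentiate object of class ", class(e)[1L])
  op <- call_name(e)
  args <- call_args(e)
  d <- function(x) sym_deriv_raw(x, var)
  if (op == "(") return(d(args[[1L]]))
  if (op == "+") {
    if (length(args) == 1L) return(d(args[[1L]]))
    return(bin("+", d(args[[1L]]), d(args[[2L]])))
  }
  if (op == "-") {
    if (length(args) == 1L) return(neg(d(args[[1L]])))
    return(bin("-", d(args[[1L]]), d(args[[2L]])))
  }
  if (op == "*") {
    u <- args[[1L]]; v <- args[[2L]]
    return(bin("+", bin("*", d(u), v), bin("*", u, d(v))))
  }
  if (op == "/") {
    u <- args[[1L]]; v <- args[[2L]]
    return(bin(
      "-",
      bin("/", d(u), v),
      bin("/", bin("*", u, d(v)), bin("^", v, 2))
    ))
  }
  if (op == "^") {
    u <- args[[1L]]; v <- args[[2L]]
    if (!contains_var(v, var)) {
      return(bin("*", bin("*", v, bin("^", u, bin("-", v, 1))), d(u)))
    }
    if (!contains_var(u, var)) {
      return(bin("*", bin("*", e, fun1("log", u)), d(v)))
    }
    return(bin("*", e, bin(
      "+",
      bin("*", d(v), fun1("log", u)),
      bin("/", bin("*", v, d(u)), u)
    )))
  }
  if (op == "exp") return(bin("*", e, d(args[[1L]])))
  if (op == "expm1") return(bin("*", fun1("exp", args[[1L]]), d(args[[1L]])))
  if (op == "log") {
    if (length(args) == 1L) return(bin("/", d(args[[1L]]), args[[1L]]))
    return(bin("/", d(args[[1L]]),
               bin("*", args[[1L]], fun1("log", args[[2L]]))))
  }
  if (op == "log10") {
    return(bin("/", d(args[[1L]]), bin("*", args[[1L]], log(10))))
  }
  if (op == "log2") {
    return(bin("/", d(args[[1L]]), bin("*", args[[1L]], log(2))))
  }
  if (op == "sqrt") {
    return(bin("/", d(args[[1L]]), bin("*", 2, fun1("sqrt", args[[1L]]))))
  }
  if (op == "abs") return(bin("*", fun1("sign", args[[1L]]), d(args[[1L]])))
  if (op %in% c("floor", "ceiling")) {
    stop("cannot differentiate non-smooth operator '", op, "'")
  }
  if (op == "sin") return(bin("*", fun1("cos", args[[1L]]), d(args[[1L]])))
  if (op == "cos") return(bin("*", neg(fun1("sin", args[[1L]])), d(args[[1L]])))
  if (op == "tan") {
    return(bin("/", d(args[[1L]]), bin("^", fun1("cos", args[[1L]]), 2)))
  }
  if (op == "asin") {
    return(bin("/", d(args[[1L]]),
               fun1("sqrt", bin("-", 1, bin("^", args[[1L]], 2)))))
  }
  if (op == "acos") {
    return(neg(bin("/", d(args[[1L]]),
                   fun1("sqrt", bin("-", 1, bin("^", args[[1L]], 2))))))
  }
  if (op == "atan") {
    return(bin("/", d(args[[1L]]), bin("+", 1, bin("^", args[[1L]], 2))))
  }
  if (op == "sinh") return(bin("*", fun1("cosh", args[[1L]]), d(args[[1L]])))
  if (op == "cosh") return(bin("*", fun1("sinh", args[[1L]]), d(args[[1L]])))
  if (op == "tanh") {
    return(bin("/", d(args[[1L]]), bin("^", fun1("cosh", args[[1L]]), 2)))
  }
  if (op == "piecewise") {
    n <- length(args)
    k <- (n - 1L) %/% 2L
    out <- list()
    for (i in seq_len(k)) {
      out <- c(out, list(args[[2L * i - 1L]], d(args[[2L * i]])))
    }
    return(as.call(c(as.name("piecewise"), out, list(d(args[[n]])))))
  }
  if (op %in% c(.rel_ops, .bool_ops)) {
    stop("cannot differentiate relational/logical operator '", op, "'")
  }
  stop("cannot differentiate unknown operator '", op, "'")
}

# ---- structural helpers used by pattern matching and codegen ----------------

# Flatten nested `+`/`-` into a list of (sign, term) pairs, preserving
# left-to-right order.
flatten_sum <- function(e, sign = 1) {
  if (is.call(e)) {
    op <- call_name(e)
    args <- call_args(e)
    if (op == "+" && length(args) == 2L) {
      return(c(flatten_sum(args[[1L]], sign), flatten_sum(args[[2L]], sign)))
    }
    if (op == "-" && length(args) == 2L) {
      return(c(flatten_sum(args[[1L]], sign), flatten_sum(args[[2L]], -sign)))
    }
    if (op == "-" && length(args) == 1L) {
      return(flatten_sum(args[[1L]], -sign))
    }
    if (op == "+" && length(args) == 1L) {
      return(flatten_sum(args[[1L]], sign))
    }
  }
  list(list(sign = sign, term = e))
}

# Flatten nested `*` (and unary minus) into factors; numeric factors are
# accumulated into a leading coefficient.
flatten_product <- function(e) {
  coef <- 1
  factors <- list()
  walk <- function(x) {
    if (is_num(x)) {
      coef <<- coef * x
    } else if (is.call(x) && call_name(x) == "*" && length(call_args(x)) == 2L) {
      walk(x[[2L]]); walk(x[[3L]])
    } else if (is.call(x) && call_name(x) == "-" && length(call_args(x)) == 1L) {
      coef <<- -coef
      walk(x[[2L]])
    } else {
      factors[[length(factors) + 1L]] <<- x
    }
  }
  walk(e)
  list(coef = coef, factors = factors)
}

rebuild_product <- function(coef, factors) {
  out <- NULL
  for (f in factors) out <- if (is.null(out)) f else bin("*", out, f)
  if (is.null(out)) return(coef)
  if (coef == 1) return(out)
  if (coef == -1) return(neg(out))
  bin("*", coef, out)
}

# If `e` is affine in `var` with numeric coefficients and references no other
# symbol, return c(intercept, slope); otherwise NULL.
affine_coeffs <- function(e, var) {
  vs <- expr_vars(e)
  if (length(vs) != 1L || vs != var) return(NULL)
  slope <- fold_constants(sym_deriv_raw(e, var))
  if (!is_num(slope)) return(NULL)
  intercept <- fold_constants(sub_vars(e, stats::setNames(list(0), var)))
  if (!is_num(intercept)) return(NULL)
  # guard against non-affine shapes whose folded derivative happens numeric
  for (x in c(-1.7, 0.9, 2.3)) {
    lhs <- expr_eval(e, stats::setNames(list(x), var))
    rhs <- intercept + slope * x
    if (!is.finite(lhs) ||
        abs(lhs - rhs) > 1e-9 * max(1, abs(lhs), abs(rhs))) {
      return(NULL)
    }
  }
  c(intercept = intercept, slope = slope)
}

expr_key <- function(e) paste(deparse(e, width.cutoff = 500L), collapse = "")

#' Structural equality of expressions after constant folding
#'
#' @param a,b Symbolic expressions.
#' @return `TRUE` if the folded trees are identical.
#' @export
expr_identical <- function(a, b) {
  identical(fold_constants(a), fold_constants(b))
}
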