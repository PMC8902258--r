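# Template-based code generation.  A (fixed, converted) model is rendered
# into solver-ready source text for one of four schemes; two output dialects
# are supported: a C++-like pair of header/implementation units mirroring
# the cardiac-cell class layout, and an executable R module so generated
# code can be numerically exercised in tests without a compiler toolchain.

#' Code-generation options
#'
#' @param scheme One of `"plain"`, `"cvode"`, `"backward_euler"`,
#'   `"rush_larsen"`.
#' @param use_jacobian Emit `EvaluateAnalyticJacobian` (only valid with the
#'   `"cvode"` scheme).
#' @param expm1 Rewrite `exp(U) - 1` terms through `expm1` for precision.
#' @param dialect `"cxx"` (header/implementation text) or `"executable"`
#'   (an R module evaluable with `eval(parse(...))`).
#' @return A `codegen_options` list.
#' @export
codegen_options <- function(scheme = c("plain", "cvode", "backward_euler",
                                       "rush_larsen"),
                            use_jacobian = FALSE, expm1 = TRUE,
                            dialect = c("cxx", "executable")) {
  scheme <- match.arg(scheme)
  dialect <- match.arg(dialect)
  if (use_jacobian && scheme != "cvode") {
    stop("an analytic Jacobian is only emitted with the cvode scheme")
  }
  structure(list(scheme = scheme, use_jacobian = use_jacobian,
                 expm1 = isTRUE(expm1), dialect = dialect),
            class = "codegen_options")
}

#' Rewrite exp(U) - 1 through expm1
#'
#' Every subterm of shape `K*exp(U) - K` (including `exp(U) - 1`,
#' `-1 + exp(U)` and `1 - exp(U)`) is rewritten to `K * expm1(U)`, which is
#' numerically equivalent but fully precise for small `U`.
#'
#' @param expr A symbolic expression.
#' @return The rewritten expression.
#' @export
apply_expm1_rewrite <- function(expr) {
  if (!is.call(expr)) return(expr)
  rebuilt <- as.call(c(expr[[1L]], lapply(call_args(expr),
                                          apply_expm1_rewrite)))
  op <- call_name(rebuilt)
  if (op %in% c("+", "-")) {
    mk <- match_exp_minus_k(rebuilt)
    if (!is.null(mk) && !(is.call(rebuilt) && op == "expm1")) {
      core <- fun1("expm1", mk$W)
      if (mk$K == 1) return(core)
      if (mk$K == -1) return(neg(core))
      return(bin("*", mk$K, core))
    }
  }
  rebuilt
}

#' Extract common subexpressions from a set of expressions
#'
#' Every compound subtree occurring at least twice across the input
#' expressions becomes a named definition; the expressions (and later
#' definitions) reference it by name.  Substituting the definitions back
#' reproduces the originals exactly; no emitted definition is referenced
#' fewer than two times.
#'
#' @param exprs List of symbolic expressions.
#' @param prefix Name prefix for generated definitions.
#' @return List with `definitions` (named, in dependency order) and `exprs`
#'   (rewritten).
#' @export
extract_common_subexpressions <- function(exprs, prefix = "cse_") {
  counts <- new.env(parent = emptyenv())
  count_walk <- function(e) {
    if (!is.call(e)) return()
    for (a in call_args(e)) count_walk(a)
    k <- expr_key(e)
    assign(k, (get0(k, envir = counts, ifnotfound = 0L)) + 1L,
           envir = counts)
  }
  for (e in exprs) count_walk(e)

  sym_of <- new.env(parent = emptyenv())
  defs <- list()
  idx <- 0L
  rebuild <- function(e) {
    if (!is.call(e)) return(e)
    k <- expr_key(e)
    if (!is.null(s <- get0(k, envir = sym_of, ifnotfound = NULL))) return(s)
    node <- as.call(c(e[[1L]], lapply(call_args(e), rebuild)))
    if (get0(k, envir = counts, ifnotfound = 0L) >= 2L) {
      idx <<- idx + 1L
      nm <- paste0(prefix, idx - 1L)
      defs[[nm]] <<- node
      s <- as.name(nm)
      assign(k, s, envir = sym_of)
      return(s)
    }
    node
  }
  out <- lapply(exprs, rebuild)

  # inline definitions referenced fewer than twice
  repeat {
    all_rhs <- c(defs, out)
    uses <- stats::setNames(integer(length(defs)), names(defs))
    for (e in all_rhs) {
      for (v in expr_vars(e)) {
        if (v %in% names(uses)) uses[[v]] <- uses[[v]] + 1L
      }
    }
    drop <- names(uses)[uses < 2L]
    if (length(drop) == 0L) break
    for (nm in drop) {
      repl <- stats::setNames(defs[nm], nm)
      defs[[nm]] <- NULL
      defs <- lapply(defs, sub_vars, map = repl)
      out <- lapply(out, sub_vars, map = repl)
    }
  }
  list(definitions = defs, exprs = out)
}

# ---- expression printers ----------------------------------------------------

fmt_num <- function(x) {
  if (is.logical(x)) return(if (isTRUE(x)) "TRUE" else "FALSE")
  if (x == floor(x) && abs(x) < 1e15) {
    return(trimws(formatC(x, format = "d")))
  }
  trimws(formatC(x, digits = 17, format = "g"))
}

.prec <- c("|" = 1, "&" = 2, "==" = 3, "!=" = 3, "<" = 3, "<=" = 3,
           ">" = 3, ">=" = 3, "+" = 4, "-" = 4, "*" = 5, "/" = 5,
           "u-" = 6, "^" = 7)

#' Render an expression as source code
#'
#' @param e A symbolic expression.
#' @param dialect `"r"` or `"cxx"`.
#' @return A single string of source text; numeric literals carry 17
#'   significant digits for binary64 round-trip exactness.
#' @export
expr_to_code <- function(e, dialect = c("r", "cxx")) {
  dialect <- match.arg(dialect)
  render <- function(e, parent_prec = 0) {
    if (is_num(e) || is.logical(e)) {
      s <- fmt_num(e)
      if (dialect == "cxx" && is.logical(e)) {
        s <- tolower(s)
      }
      if (is.numeric(e) && e < 0 && parent_prec > .prec[["+"]]) {
        s <- paste0("(", s, ")")
      }
      return(s)
    }
    if (is.symbol(e)) return(as.character(e))
    op <- call_name(e)
    args <- call_args(e)
    if (op %in% names(.prec) && length(args) == 2L) {
      if (op == "^" && dialect == "cxx") {
        return(sprintf("pow(%s, %s)", render(args[[1L]]),
                       render(args[[2L]])))
      }
      p <- .prec[[op]]
      lhs <- render(args[[1L]], if (op == "^") p + 1 else p)
      rhs <- render(args[[2L]], p + if (op == "^") 0 else 1)
      cxx_op <- c("&" = "&&", "|" = "||")
      sop <- if (dialect == "cxx" && op %in% names(cxx_op))
        cxx_op[[op]] else op
      s <- paste(lhs, sop, rhs)
      if (p < parent_prec) s <- paste0("(", s, ")")
      return(s)
    }
    if (op == "-" && length(args) == 1L) {
      s <- paste0("-", render(args[[1L]], .prec[["u-"]]))
      if (.prec[["u-"]] < parent_prec) s <- paste0("(", s, ")")
      return(s)
    }
    if (op == "!" && length(args) == 1L) {
      return(paste0("!(", render(args[[1L]]), ")"))
    }
    if (op == "piecewise") {
      if (dialect == "r") {
        return(sprintf("piecewise(%s)",
                       paste(vapply(args, render, ""), collapse = ", ")))
      }
      n <- length(args)
      k <- (n - 1L) %/% 2L
      s <- render(args[[n]])
      for (i in rev(seq_len(k))) {
        s <- sprintf("(%s ? %s : %s)", render(args[[2L * i - 1L]]),
                     render(args[[2L * i]]), s)
      }
      return(s)
    }
    if (op == "log" && length(args) == 2L) {
      if (dialect == "cxx") {
        return(sprintf("(log(%s) / log(%s))", render(args[[1L]]),
                       render(args[[2L]])))
      }
      return(sprintf("log(%s, %s)", render(args[[1L]]), render(args[[2L]])))
    }
    fname <- op
    if (dialect == "cxx") {
      cmap <- c(abs = "fabs", ceiling = "ceil", sign = "copysign_one")
      if (op %in% names(cmap)) fname <- cmap[[op]]
    }
    sprintf("%s(%s)", fname,
            paste(vapply(args, render, ""), collapse = ", "))
  }
  render(e)
}

# ---- model rendering --------------------------------------------------------

required_methods <- function(options) {
  base <- c("constructor", "destructor", "UseCellMLDefaultStimulus",
            "GetIIonic", "ComputeDerivedQuantities",
            "OdeSystemInformation::Initialise")
  switch(options$scheme,
    plain = c(base, "EvaluateYDerivatives"),
    cvode = c(base, "EvaluateYDerivatives",
              if (options$use_jacobian) "EvaluateAnalyticJacobian"),
    backward_euler = c(base, "UpdateTransmembranePotential",
                       "ComputeOneStepExceptVoltage"),
    rush_larsen = c(base, "EvaluateEquations",
                    "ComputeOneStepExceptVoltage")
  )
}

camel_case <- function(x) {
  parts <- strsplit(gsub("[^A-Za-z0-9]+", " ", x), " ")[[1L]]
  parts <- parts[nzchar(parts)]
  paste(toupper(substring(parts, 1, 1)), substring(parts, 2), sep = "",
        collapse = "")
}

ionic_current_variables <- function(model) {
  vars <- Filter(function(v) {
    any(grepl("_current$", v$tags)) &&
      !"membrane_stimulus_current" %in% v$tags
  }, model$variables)
  vapply(vars, `[[`, "", "name")
}

stimulus_parameters <- function(model) {
  get <- function(tag) {
    v <- get_tagged_variable(model, tag, required = FALSE)
    if (is.null(v)) NULL else v$name
  }
  list(
    amplitude = get("membrane_stimulus_current_amplitude"),
    duration = get("membrane_stimulus_current_duration"),
    offset = get("membrane_stimulus_current_offset"),
    period = get("membrane_stimulus_current_period"),
    end = get("membrane_stimulus_current_end")
  )
}

stimulus_expression <- function(model) {
  sp <- stimulus_parameters(model)
  if (is.null(sp$amplitude) || is.null(sp$duration) || is.null(sp$offset)) {
    return(NULL)
  }
  t <- as.name(model$free_variable)
  amp <- as.name(sp$amplitude); dur <- as.name(sp$duration)
  off <- as.name(sp$offset)
  tlocal <- if (!is.null(sp$period)) {
    # time within the current stimulus cycle
    bin("-", bin("-", t, off),
        bin("*", as.name(sp$period),
            fun1("floor", bin("/", bin("-", t, off), as.name(sp$period)))))
  } else {
    bin("-", t, off)
  }
  cond <- bin("&", bin(">=", tlocal, 0), bin("<", tlocal, dur))
  if (is.null(sp$period)) {
    cond <- bin("&", bin(">=", t, off), cond)
  }
  if (!is.null(sp$end)) cond <- bin("&", cond, bin("<=", t, as.name(sp$end)))
  as.call(list(as.name("piecewise"), cond, amp, 0))
}

derived_quantity_variables <- function(model) {
  vars <- Filter(function(v) {
    length(v$tags) > 0L && v$kind == "computed"
  }, model$variables)
  vapply(vars, `[[`, "", "name")
}

#' Render a model into solver-ready code
#'
#' Generates source text for the requested scheme.  The plain scheme emits a
#' constructor/destructor, `UseCellMLDefaultStimulus`, `GetIIonic`,
#' `EvaluateYDerivatives`, `ComputeDerivedQuantities` and
#' `OdeSystemInformation::Initialise`; the cvode scheme additionally emits
#' `EvaluateAnalyticJacobian` when an analytic Jacobian is supplied; the
#' backward-Euler scheme replaces `EvaluateYDerivatives` with
#' `UpdateTransmembranePotential` plus `ComputeOneStepExceptVoltage`; the
#' Rush-Larsen scheme emits `EvaluateEquations` plus
#' `ComputeOneStepExceptVoltage`.  Output is deterministic for a fixed
#' (model, options) pair.
#'
#' @param model A `cellml_model`, already singularity-fixed and
#'   unit-converted as desired.
#' @param jac Optional `jacobian_matrix`; required iff
#'   `options$use_jacobian`.
#' @param options A [codegen_options()].
#' @param fix_report Optional `singularity_report` summarised in the
#'   provenance header.
#' @return A `generated_code` list: `files` (named character vector of file
#'   name to text), `manifest` (emitted method names), `meta`.
#' @export
render <- function(model, jac = NULL, options = codegen_options(),
                   fix_report = NULL) {
  missing_tags <- character()
  for (tag in c("membrane_voltage", "membrane_stimulus_current")) {
    if (is.null(get_tagged_variable(model, tag, required = FALSE))) {
      missing_tags <- c(missing_tags, tag)
    }
  }
  if (length(missing_tags)) {
    stop("cannot generate code: required annotation(s) missing: ",
         paste(missing_tags, collapse = ", "))
  }
  if (options$use_jacobian && is.null(jac)) {
    stop("analytic-jacobian output requested but no Jacobian supplied")
  }

  manifest <- required_methods(options)
  stim <- stimulus_expression(model)
  if (is.null(stim)) {
    warning("stimulus parameters (amplitude/duration/offset) not all ",
            "tagged; UseCellMLDefaultStimulus omitted")
    manifest <- setdiff(manifest, "UseCellMLDefaultStimulus")
  }
  ionic <- ionic_current_variables(model)
  if (length(ionic) == 0L) {
    stop("cannot generate GetIIonic: no variables tagged as ionic currents")
  }

  maybe_expm1 <- function(e) if (options$expm1) apply_expm1_rewrite(e) else e
  meta <- list(
    model = model$name,
    scheme = options$scheme,
    dialect = options$dialect,
    n_fixes = length(fix_report %||% list()),
    generator = paste0("cellmlgen ",
                       as.character(utils::packageVersion("cellmlgen")))
  )
  ctx <- list(model = model, jac = jac, options = options, stim = stim,
              ionic = ionic, manifest = manifest, meta = meta,
              maybe_expm1 = maybe_expm1)
  files <- if (options$dialect == "executable") {
    render_executable(ctx)
  } else {
    render_cxx(ctx)
  }
  structure(list(files = files, manifest = manifest, meta = meta),
            class = "generated_code")
}

#' @export
print.generated_code <- function(x, ...) {
  cat(sprintf("<generated_code> %s (%s/%s): %s\n", x$meta$model,
              x$meta$scheme, x$meta$dialect,
              paste(names(x$files), collapse = ", ")))
  cat("methods:", paste(x$manifest, collapse = ", "), "\n")
  invisible(x)
}

provenance_lines <- function(ctx, comment) {
  sprintf(
    "%s %s", comment,
    c(paste0("Generated by ", ctx$meta$generator),
      paste0("Model: ", ctx$meta$model),
      paste0("Scheme: ", ctx$meta$scheme, "; dialect: ", ctx$meta$dialect),
      paste0("Singularity fixes applied: ", ctx$meta$n_fixes))
  )
}

# Assignment sequencing: given named (name -> expr) assignments (algebraic
# equations plus CSE definitions), order them so every assignment follows
# the assignments it references, keeping the incoming order among
# independent ones.
order_assignments <- function(assigns) {
  nms <- names(assigns)
  n <- length(assigns)
  deps <- lapply(assigns, function(e) intersect(expr_vars(e), nms))
  placed <- character()
  order <- integer()
  remaining <- seq_len(n)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) {
      all(deps[[i]] %in% placed)
    }, TRUE)]
    if (length(ready) == 0L) {
      stop("cyclic assignment dependencies in code generation")
    }
    order <- c(order, ready[[1L]])
    placed <- c(placed, nms[[ready[[1L]]]])
    remaining <- setdiff(remaining, ready[[1L]])
  }
  assigns[order]
}
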