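# Dialect-specific rendering backends for render(): an executable R module
# (numerically exercisable in tests) and a C++-like header/implementation
# pair mirroring the cardiac-cell class layout.

# Build the shared method ingredients: chained algebraic assignments with
# common subexpressions extracted, plus rendered final expressions.
method_parts <- function(ctx, finals, dialect) {
  model <- ctx$model
  dg <- build_dependency_graph(model)
  alg <- Filter(function(e) !e$ode, model$equations[dg$order])
  alg_exprs <- lapply(alg, function(e) ctx$maybe_expm1(
    fold_constants(e$rhs)
  ))
  names(alg_exprs) <- vapply(alg, `[[`, "", "lhs")
  finals <- lapply(finals, function(e) ctx$maybe_expm1(fold_constants(e)))
  cse <- extract_common_subexpressions(c(unname(alg_exprs), unname(finals)))
  n_alg <- length(alg_exprs)
  assigns <- c(cse$definitions,
               stats::setNames(cse$exprs[seq_len(n_alg)], names(alg_exprs)))
  assigns <- order_assignments(assigns)
  list(
    assigns = vapply(names(assigns), function(nm) {
      expr_to_code(assigns[[nm]], dialect)
    }, ""),
    finals = vapply(cse$exprs[n_alg + seq_along(finals)], expr_to_code,
                    "", dialect = dialect)
  )
}

state_form_parts <- function(ctx, finals, dialect) {
  finals <- lapply(finals, function(e) ctx$maybe_expm1(fold_constants(e)))
  cse <- extract_common_subexpressions(unname(finals))
  list(
    assigns = vapply(names(cse$definitions), function(nm) {
      expr_to_code(cse$definitions[[nm]], dialect)
    }, ""),
    finals = vapply(cse$exprs, expr_to_code, "", dialect = dialect)
  )
}

ode_rhs_exprs <- function(model) {
  odes <- Filter(function(e) e$ode, model$equations)
  stats::setNames(lapply(odes, `[[`, "rhs"),
                  vapply(odes, `[[`, "", "lhs"))[model$states]
}

# ---- executable R dialect ---------------------------------------------------

render_executable <- function(ctx) {
  model <- ctx$model
  states <- model$states
  free <- model$free_variable
  params <- Filter(function(v) v$kind == "parameter", model$variables)
  ind <- "  "

  unpack <- c(
    sprintf("%s%s <- t", ind, free),
    vapply(seq_along(states), function(i) {
      sprintf("%s%s <- y[[%d]]", ind, states[[i]], i)
    }, "")
  )
  emit_fun <- function(name, args, body) {
    c(sprintf("%s <- function(%s) {", name, paste(args, collapse = ", ")),
      body, "}", "")
  }
  asn_lines <- function(assigns) {
    if (length(assigns) == 0L) return(character())
    sprintf("%s%s <- %s", ind, names(assigns), assigns)
  }

  lines <- c(provenance_lines(ctx, "#"), "", "local({", "")
  lines <- c(lines, sprintf("model_name <- \"%s\"", model$name), "")
  for (p in params) {
    lines <- c(lines, sprintf("%s <- %s", p$name, fmt_num(p$init)))
  }
  lines <- c(lines, "")

  derivs <- ode_rhs_exprs(model)
  rhs_parts <- method_parts(ctx, derivs, "r")
  manifest <- ctx$manifest

  if ("EvaluateYDerivatives" %in% manifest) {
    body <- c(unpack, asn_lines(rhs_parts$assigns),
              sprintf("%sc(%s)", ind,
                      paste(sprintf("%s = %s", states, rhs_parts$finals),
                            collapse = ", ")))
    lines <- c(lines, emit_fun("EvaluateYDerivatives", c("t", "y"), body))
  }

  if ("UseCellMLDefaultStimulus" %in% manifest) {
    body <- c(sprintf("%s%s <- t", ind, free),
              sprintf("%s%s", ind, expr_to_code(ctx$stim, "r")))
    lines <- c(lines, emit_fun("UseCellMLDefaultStimulus", "t", body))
  }

  ionic_sum <- Reduce(function(a, b) bin("+", a, b),
                      lapply(ctx$ionic, as.name))
  gi <- method_parts(ctx, list(ionic_sum), "r")
  body <- c(unpack, asn_lines(gi$assigns),
            sprintf("%s%s", ind, gi$finals[[1L]]))
  lines <- c(lines, emit_fun("GetIIonic", c("t", "y"), body))

  derived <- derived_quantity_variables(model)
  dq <- method_parts(ctx, stats::setNames(lapply(derived, as.name),
                                          derived), "r")
  body <- c(unpack, asn_lines(dq$assigns),
            if (length(derived)) {
              sprintf("%sc(%s)", ind,
                      paste(sprintf("%s = %s", derived, dq$finals),
                            collapse = ", "))
            } else sprintf("%snumeric(0)", ind))
  lines <- c(lines, emit_fun("ComputeDerivedQuantities", c("t", "y"), body))

  init <- model_initial_state(model)
  lines <- c(lines, emit_fun(
    "OdeSystemInformation_Initialise", character(),
    c(sprintf("%slist(", ind),
      sprintf("%s  name = \"%s\",", ind, model$name),
      sprintf("%s  free_variable = \"%s\",", ind, free),
      sprintf("%s  state_names = c(%s),", ind,
              paste(sprintf("\"%s\"", states), collapse = ", ")),
      sprintf("%s  initial_state = c(%s),", ind,
              paste(sprintf("%s = %s", states,
                            vapply(init, fmt_num, "")), collapse = ", ")),
      sprintf("%s  parameter_names = c(%s),", ind,
              paste(sprintf("\"%s\"", vapply(params, `[[`, "", "name")),
                    collapse = ", ")),
      sprintf("%s  derived_quantity_names = c(%s)", ind,
              paste(sprintf("\"%s\"", derived), collapse = ", ")),
      sprintf("%s)", ind))
  ))

  if ("EvaluateAnalyticJacobian" %in% manifest) {
    n <- length(states)
    entries <- unlist(ctx$jac$entries, recursive = FALSE)
    jp <- state_form_parts(ctx, entries, "r")
    body <- c(unpack, asn_lines(jp$assigns),
              sprintf("%smatrix(c(", ind),
              sprintf("%s  %s%s", ind, jp$finals,
                      c(rep(",", length(jp$finals) - 1L), "")),
              sprintf("%s), nrow = %d, byrow = TRUE)", ind, n))
    lines <- c(lines, emit_fun("EvaluateAnalyticJacobian", c("t", "y"),
                               body))
  }

  if (ctx$options$scheme %in% c("backward_euler", "rush_larsen")) {
    lines <- c(lines, render_scheme_methods_r(ctx, unpack, ind, emit_fun,
                                              asn_lines))
  }

  exported <- intersect(
    c("EvaluateYDerivatives", "UseCellMLDefaultStimulus", "GetIIonic",
      "ComputeDerivedQuantities", "OdeSystemInformation_Initialise",
      "EvaluateAnalyticJacobian", "UpdateTransmembranePotential",
      "ComputeOneStepExceptVoltage", "EvaluateEquations"),
    c(sub("::", "_", manifest), "GetIIonic", "ComputeDerivedQuantities")
  )
  lines <- c(lines,
             "list(",
             sprintf("  model_name = model_name,"),
             paste0("  ", exported, " = ", exported,
                    c(rep(",", length(exported) - 1L), "")),
             ")", "})")
  fname <- paste0(camel_case(model$name), ".R")
  stats::setNames(paste(lines, collapse = "\n"), fname)
}

render_scheme_methods_r <- function(ctx, unpack, ind, emit_fun, asn_lines) {
  model <- ctx$model
  states <- model$states
  vtag <- get_tagged_variable(model, "membrane_voltage")
  cls <- classify_states(model)
  sf <- substitute_to_state_form(model)
  lines <- character()

  if (ctx$options$scheme == "backward_euler") {
    dv <- sf[[paste0("d_", vtag$name)]]
    vp <- state_form_parts(ctx, list(dv), "r")
    body <- c(unpack, asn_lines(vp$assigns),
              sprintf("%sy[[\"%s\"]] <- %s + dt * (%s)", ind, vtag$name,
                      vtag$name, vp$finals[[1L]]),
              sprintf("%sy", ind))
    lines <- c(lines, emit_fun("UpdateTransmembranePotential",
                               c("t", "y", "dt"), body))
    updates <- scheme_updates(model, cls, sf, vtag$name, backward = TRUE)
  } else {
    nonlinear <- states[vapply(states, function(s) is.null(cls[[s]]), TRUE)]
    dexprs <- lapply(nonlinear, function(s) sf[[paste0("d_", s)]])
    ep <- state_form_parts(ctx, dexprs, "r")
    body <- c(unpack, asn_lines(ep$assigns),
              vapply(seq_along(nonlinear), function(i) {
                sprintf("%sy[[\"%s\"]] <- %s + dt * (%s)", ind,
                        nonlinear[[i]], nonlinear[[i]], ep$finals[[i]])
              }, ""),
              sprintf("%sy", ind))
    lines <- c(lines, emit_fun("EvaluateEquations", c("t", "y", "dt"),
                               body))
    updates <- scheme_updates(model, cls, sf, vtag$name, backward = FALSE)
  }

  up <- state_form_parts(ctx, updates, "r")
  body <- c(unpack, asn_lines(up$assigns),
            vapply(seq_along(updates), function(i) {
              sprintf("%sy[[\"%s\"]] <- %s", ind, names(updates)[[i]],
                      up$finals[[i]])
            }, ""),
            sprintf("%sy", ind))
  lines <- c(lines, emit_fun("ComputeOneStepExceptVoltage",
                             c("t", "y", "dt"), body))
  lines
}

# Per-state update expressions for ComputeOneStepExceptVoltage: implicit
# (backward-Euler) or exact (Rush-Larsen) updates for linear states, a
# forward-Euler step for nonlinear non-voltage states.
scheme_updates <- function(model, cls, sf, voltage, backward) {
  out <- list()
  for (s in setdiff(model$states, voltage)) {
    d <- cls[[s]]
    if (!is.null(d)) {
      out[[s]] <- if (backward) backward_euler_update(d) else
        rush_larsen_update(d)
    } else {
      out[[s]] <- fold_constants(
        bin("+", as.name(s), bin("*", as.name("dt"),
                                 sf[[paste0("d_", s)]]))
      )
    }
  }
  out
}

# ---- C++-like dialect -------------------------------------------------------

render_cxx <- function(ctx) {
  model <- ctx$model
  states <- model$states
  cname <- paste0("Cell", camel_case(model$name), "FromCellML")
  base_class <- switch(ctx$options$scheme,
    plain = "AbstractCardiacCell",
    cvode = "AbstractCvodeCell",
    backward_euler = "AbstractBackwardEulerCardiacCell",
    rush_larsen = "AbstractRushLarsenCardiacCell"
  )
  ind <- "    "
  manifest <- ctx$manifest

  sig <- c(
    "UseCellMLDefaultStimulus" = "double UseCellMLDefaultStimulus(double t)",
    "GetIIonic" = "double GetIIonic(double t, const std::vector<double>& rY)",
    "EvaluateYDerivatives" = paste0(
      "void EvaluateYDerivatives(double t, const std::vector<double>& rY, ",
      "std::vector<double>& rDY)"),
    "ComputeDerivedQuantities" = paste0(
      "std::vector<double> ComputeDerivedQuantities(double t, ",
      "const std::vector<double>& rY)"),
    "EvaluateAnalyticJacobian" = paste0(
      "void EvaluateAnalyticJacobian(double t, ",
      "const std::vector<double>& rY, double** rJacobian)"),
    "UpdateTransmembranePotential" = paste0(
      "void UpdateTransmembranePotential(double t, ",
      "std::vector<double>& rY, double dt)"),
    "ComputeOneStepExceptVoltage" = paste0(
      "void ComputeOneStepExceptVoltage(double t, ",
      "std::vector<double>& rY, double dt)"),
    "EvaluateEquations" = paste0(
      "void EvaluateEquations(double t, std::vector<double>& rY, ",
      "double dt)")
  )

  hpp <- c(
    provenance_lines(ctx, "//"),
    sprintf("#ifndef %s_HPP_", toupper(cname)),
    sprintf("#define %s_HPP_", toupper(cname)),
    "#include <vector>",
    "#include <cmath>",
    sprintf("class %s : public %s", cname, base_class),
    "{",
    "public:",
    sprintf("%s%s();", ind, cname),
    sprintf("%s~%s();", ind, cname)
  )
  for (m in manifest) {
    if (m %in% names(sig)) hpp <- c(hpp, sprintf("%s%s;", ind, sig[[m]]))
  }
  hpp <- c(hpp, "};",
           "template<> void OdeSystemInformation::Initialise(void);",
           "#endif")

  unpack <- c(
    vapply(seq_along(states), function(i) {
      sprintf("%sconst double %s = rY[%d];", ind, states[[i]], i - 1L)
    }, ""),
    sprintf("%sconst double %s = t;", ind, model$free_variable)
  )
  params <- Filter(function(v) v$kind == "parameter", model$variables)
  pdecl <- vapply(params, function(p) {
    sprintf("%sconst double %s = %s;", ind, p$name, fmt_num(p$init))
  }, "")

  cpp <- c(provenance_lines(ctx, "//"),
           sprintf("#include \"%s.hpp\"", cname),
           "")
  open_method <- function(name) {
    decl <- sig[[name]]
    # inject ClassName:: before the method name
    sub("^(\\S+(?:<double>)?\\s+|void |double |std::vector<double> )",
        sprintf("\\1%s::", cname), decl)
  }
  cpp <- c(cpp,
           sprintf("%s::%s() {}", cname, cname),
           sprintf("%s::~%s() {}", cname, cname), "")

  derivs <- ode_rhs_exprs(model)
  rhs_parts <- method_parts(ctx, derivs, "cxx")
  asn <- function(assigns) {
    if (length(assigns) == 0L) return(character())
    sprintf("%sconst double %s = %s;", ind, names(assigns), assigns)
  }

  if ("EvaluateYDerivatives" %in% manifest) {
    cpp <- c(cpp, paste0(open_method("EvaluateYDerivatives"), " {"),
             pdecl, unpack, asn(rhs_parts$assigns),
             vapply(seq_along(states), function(i) {
               sprintf("%srDY[%d] = %s;", ind, i - 1L,
                       rhs_parts$finals[[i]])
             }, ""),
             "}", "")
  }
  if ("UseCellMLDefaultStimulus" %in% manifest) {
    cpp <- c(cpp, paste0(open_method("UseCellMLDefaultStimulus"), " {"),
             pdecl,
             sprintf("%sconst double %s = t;", ind, model$free_variable),
             sprintf("%sreturn %s;", ind, expr_to_code(ctx$stim, "cxx")),
             "}", "")
  }
  ionic_sum <- Reduce(function(a, b) bin("+", a, b),
                      lapply(ctx$ionic, as.name))
  gi <- method_parts(ctx, list(ionic_sum), "cxx")
  cpp <- c(cpp, paste0(open_method("GetIIonic"), " {"),
           pdecl, unpack, asn(gi$assigns),
           sprintf("%sreturn %s;", ind, gi$finals[[1L]]),
           "}", "")

  derived <- derived_quantity_variables(model)
  dq <- method_parts(ctx, stats::setNames(lapply(derived, as.name),
                                          derived), "cxx")
  cpp <- c(cpp, paste0(open_method("ComputeDerivedQuantities"), " {"),
           pdecl, unpack, asn(dq$assigns),
           sprintf("%sstd::vector<double> dqs(%d);", ind, length(derived)),
           vapply(seq_along(derived), function(i) {
             sprintf("%sdqs[%d] = %s;", ind, i - 1L, dq$finals[[i]])
           }, ""),
           sprintf("%sreturn dqs;", ind),
           "}", "")

  if ("EvaluateAnalyticJacobian" %in% manifest) {
    entries <- unlist(ctx$jac$entries, recursive = FALSE)
    jp <- state_form_parts(ctx, entries, "cxx")
    n <- length(states)
    cpp <- c(cpp, paste0(open_method("EvaluateAnalyticJacobian"), " {"),
             pdecl, unpack, asn(jp$assigns),
             unlist(lapply(seq_len(n), function(i) {
               vapply(seq_len(n), function(j) {
                 sprintf("%srJacobian[%d][%d] = %s;", ind, i - 1L, j - 1L,
                         jp$finals[[(i - 1L) * n + j]])
               }, "")
             })),
             "}", "")
  }

  if (ctx$options$scheme %in% c("backward_euler", "rush_larsen")) {
    cpp <- c(cpp, render_scheme_methods_cxx(ctx, pdecl, unpack, ind, asn,
                                            open_method))
  }

  cpp <- c(cpp, "template<>", "void OdeSystemInformation::Initialise(void)",
           "{",
           sprintf("%sthis->mSystemName = \"%s\";", ind, model$name),
           sprintf("%sthis->mFreeVariableName = \"%s\";", ind,
                   model$free_variable),
           vapply(seq_along(states), function(i) {
             sprintf("%sthis->mVariableNames.push_back(\"%s\"); %s", ind,
                     states[[i]],
                     sprintf("this->mInitialConditions.push_back(%s);",
                             fmt_num(model_initial_state(model)[[i]])))
           }, ""),
           "}")

  stats::setNames(
    c(paste(hpp, collapse = "\n"), paste(cpp, collapse = "\n")),
    c(paste0(cname, ".hpp"), paste0(cname, ".cpp"))
  )
}

render_scheme_methods_cxx <- function(ctx, pdecl, unpack, ind, asn,
                                      open_method) {
  model <- ctx$model
  states <- model$states
  vtag <- get_tagged_variable(model, "membrane_voltage")
  cls <- classify_states(model)
  sf <- substitute_to_state_form(model)
  vi <- match(vtag$name, states)
  out <- character()

  if (ctx$options$scheme == "backward_euler") {
    dv <- sf[[paste0("d_", vtag$name)]]
    vp <- state_form_parts(ctx, list(dv), "cxx")
    out <- c(out, paste0(open_method("UpdateTransmembranePotential"), " {"),
             pdecl, unpack, asn(vp$assigns),
             sprintf("%srY[%d] = %s + dt * (%s);", ind, vi - 1L,
                     vtag$name, vp$finals[[1L]]),
             "}", "")
    updates <- scheme_updates(model, cls, sf, vtag$name, backward = TRUE)
  } else {
    nonlinear <- states[vapply(states, function(s) is.null(cls[[s]]), TRUE)]
    dexprs <- lapply(nonlinear, function(s) sf[[paste0("d_", s)]])
    ep <- state_form_parts(ctx, dexprs, "cxx")
    out <- c(out, paste0(open_method("EvaluateEquations"), " {"),
             pdecl, unpack, asn(ep$assigns),
             vapply(seq_along(nonlinear), function(i) {
               sprintf("%srY[%d] = %s + dt * (%s);", ind,
                       match(nonlinear[[i]], states) - 1L, nonlinear[[i]],
                       ep$finals[[i]])
             }, ""),
             "}", "")
    updates <- scheme_updates(model, cls, sf, vtag$name, backward = FALSE)
  }
  up <- state_form_parts(ctx, updates, "cxx")
  out <- c(out, paste0(open_method("ComputeOneStepExceptVoltage"), " {"),
           pdecl, unpack, asn(up$assigns),
           vapply(seq_along(updates), function(i) {
             sprintf("%srY[%d] = %s;", ind,
                     match(names(updates)[[i]], states) - 1L,
                     up$finals[[i]])
           }, ""),
           "}", "")
  out
}
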