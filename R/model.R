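# Core intermediate representation: variables, equations, models, and the
# equation dependency graph.  A model is an ordinary list with class
# "cellml_model"; equations hold symbolic expressions (see expr.R).

#' Create a model variable
#'
#' @param name Identifier (unique within the model after connection merging).
#' @param component Name of the component the variable belongs to.
#' @param units Unit name, resolved against the model's units registry.
#' @param init Initial value (states, parameters) or `NA`.
#' @param kind One of `"state"`, `"free"`, `"parameter"`, `"computed"`.
#' @param tags Character vector of ontology tags (e.g. `"membrane_voltage"`).
#' @return A `cellml_variable` list.
#' @export
new_variable <- function(name, component = "main", units = "dimensionless",
                         init = NA_real_, kind = "computed",
                         tags = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  kind <- match.arg(kind, c("state", "free", "parameter", "computed"))
  structure(
    list(name = name, component = component, units = units,
         init = as.numeric(init), kind = kind, tags = unique(tags)),
    class = "cellml_variable"
  )
}

#' Create an equation
#'
#' @param lhs Name of the defined variable.
#' @param rhs Symbolic expression (language object) or a number.
#' @param ode `TRUE` if the equation defines `d(lhs)/d(free variable)`.
#' @return A `cellml_equation` list.
#' @export
new_equation <- function(lhs, rhs, ode = FALSE) {
  if (is.character(rhs)) rhs <- expr_parse(rhs)
  if (is.numeric(rhs)) rhs <- as.numeric(rhs)
  structure(list(lhs = lhs, rhs = rhs, ode = isTRUE(ode)),
            class = "cellml_equation")
}

#' Assemble a model
#'
#' @param name Model name.
#' @param variables List of [new_variable()] objects.
#' @param equations List of [new_equation()] objects.
#' @param free_variable Name of the free (differentiation) variable.
#' @param units A units registry from [units_registry()]; defaults to the
#'   CellML built-in registry.
#' @param validate Run [validate_model()] (default `TRUE`).
#' @return A `cellml_model` object.
#' @export
new_model <- function(name, variables, equations, free_variable,
                      units = units_registry(), validate = TRUE) {
  names(variables) <- vapply(variables, `[[`, "", "name")
  m <- structure(
    list(
      name = name,
      variables = variables,
      equations = equations,
      free_variable = free_variable,
      # document order of ODE declarations fixes the state ordering
      states = vapply(Filter(function(e) e$ode, equations), `[[`, "", "lhs"),
      units = units
    ),
    class = "cellml_model"
  )
  if (validate) validate_model(m)
  m
}

#' @export
print.cellml_model <- function(x, ...) {
  n_ode <- sum(vapply(x$equations, `[[`, TRUE, "ode"))
  cat(sprintf(
    "<cellml_model> %s: %d variables, %d equations (%d ODEs), states: %s\n",
    x$name, length(x$variables), length(x$equations), n_ode,
    paste(x$states, collapse = ", ")
  ))
  invisible(x)
}

#' Validate model invariants
#'
#' Checks that every right-hand-side symbol resolves to a declared variable,
#' every variable has exactly one defining source (ODE, algebraic equation or
#' literal initial value), each state is the subject of exactly one ODE, and
#' the algebraic dependency graph is acyclic.
#'
#' @param model A `cellml_model`.
#' @return The model, invisibly; errors otherwise.
#' @export
validate_model <- function(model) {
  vnames <- names(model$variables)
  defined <- character()
  for (eq in model$equations) {
    if (!eq$lhs %in% vnames) {
      stop("equation defines undeclared variable '", eq$lhs, "'")
    }
    for (s in expr_vars(eq$rhs)) {
      if (!s %in% vnames) {
        stop("undefined variable '", s, "' referenced in equation for '",
             eq$lhs, "'")
      }
    }
    key <- paste0(if (eq$ode) "d/dt " else "", eq$lhs)
    if (key %in% defined) stop("variable '", eq$lhs, "' defined twice")
    defined <- c(defined, key)
  }
  alg_lhs <- vapply(Filter(function(e) !e$ode, model$equations), `[[`, "",
                    "lhs")
  for (v in model$variables) {
    if (v$kind == "state" && !v$name %in% model$states) {
      stop("state variable '", v$name, "' has no ODE")
    }
    if (v$kind == "computed" && !v$name %in% alg_lhs) {
      stop("variable '", v$name, "' has neither definition nor initial value")
    }
    if (v$kind == "parameter" && v$name %in% alg_lhs) {
      stop("parameter '", v$name, "' also has a defining equation")
    }
  }
  build_dependency_graph(model) # errors on algebraic cycles
  invisible(model)
}

#' Build the equation dependency graph
#'
#' Constructs a directed graph whose nodes are the model's equations, with an
#' edge from the equation defining a variable to every equation using it, and
#' computes a topological ordering with leaf definitions first and ODEs last.
#' Equations not reachable from any ODE are retained but flagged unused.
#'
#' @param model A `cellml_model`.
#' @return A `dependency_graph` list with elements `order` (equation indices,
#'   dependencies first), `levels` (topological depth per equation, leaves at
#'   level 1), `unused` (logical per equation) and `graph` (the igraph
#'   object).
#' @export
build_dependency_graph <- function(model) {
  eqs <- model$equations
  n <- length(eqs)
  def_of <- list() # variable name -> algebraic equation index
  for (i in seq_len(n)) {
    if (!eqs[[i]]$ode) def_of[[eqs[[i]]$lhs]] <- i
  }
  edges <- integer(0) # pairs (from=definition, to=user)
  for (i in seq_len(n)) {
    for (s in expr_vars(eqs[[i]]$rhs)) {
      j <- def_of[[s]]
      if (!is.null(j) && j != i) edges <- c(edges, j, i)
    }
  }
  g <- igraph::make_graph(edges = edges, n = n, directed = TRUE)
  # cycle detection over algebraic equations only (ODEs may feed back freely
  # through states, which are not algebraic definitions)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    bad <- which(comp$membership %in% which(comp$csize > 1L))
    cyc_vars <- vapply(eqs[bad], `[[`, "", "lhs")
    stop("cyclic algebraic dependency involving: ",
         paste(sort(unique(cyc_vars)), collapse = ", "))
  }
  order <- as.integer(igraph::topo_sort(g, mode = "out"))
  # stable tie-break: among equal depths keep document order
  depth <- rep(1L, n)
  for (i in order) {
    preds <- as.integer(igraph::neighbors(g, i, mode = "in"))
    if (length(preds)) depth[i] <- max(depth[preds]) + 1L
  }
  order <- order(depth, seq_len(n))
  # reachability: an equation is used if an ODE depends (transitively) on it
  ode_idx <- which(vapply(eqs, `[[`, TRUE, "ode"))
  used <- rep(FALSE, n)
  used[ode_idx] <- TRUE
  for (oi in ode_idx) {
    used[as.integer(igraph::subcomponent(g, oi, mode = "in"))] <- TRUE
  }
  structure(
    list(order = order, levels = depth, unused = !used, graph = g),
    class = "dependency_graph"
  )
}

#' Rewrite all equations in terms of state variables
#'
#' Substitutes intermediate (computed) variables into every equation, in
#' dependency order, so each returned expression references only state
#' variables, the free variable and parameters.
#'
#' @param model A `cellml_model`.
#' @param fold Constant-fold the substituted expressions (default `TRUE`).
#' @return Named list mapping each equation's lhs (ODE lhs names prefixed
#'   `"d_"`) to its state-form expression.
#' @export
substitute_to_state_form <- function(model, fold = TRUE) {
  dg <- build_dependency_graph(model)
  eqs <- model$equations
  keep <- c(model$states, model$free_variable,
            names(Filter(function(v) v$kind == "parameter", model$variables)))
  sub_map <- list() # computed variable -> state-form expression
  out <- list()
  for (i in dg$order) {
    eq <- eqs[[i]]
    e <- sub_vars(eq$rhs, sub_map)
    for (s in expr_vars(e)) {
      if (!s %in% keep) {
        stop("unresolved symbol '", s, "' while substituting '", eq$lhs, "'")
      }
    }
    if (fold) e <- fold_constants(e)
    if (eq$ode) {
      out[[paste0("d_", eq$lhs)]] <- e
    } else {
      sub_map[[eq$lhs]] <- e
      out[[eq$lhs]] <- e
    }
  }
  out
}

#' Look up a variable by ontology tag
#'
#' @param model A `cellml_model`.
#' @param tag Ontology tag string (e.g. `"membrane_voltage"`).
#' @param required Error if missing (default `TRUE`); otherwise return `NULL`.
#' @return The tagged `cellml_variable`.
#' @export
get_tagged_variable <- function(model, tag, required = TRUE) {
  hits <- Filter(function(v) tag %in% v$tags, model$variables)
  if (length(hits) == 0L) {
    if (required) stop("tag not found: no variable tagged '", tag, "'")
    return(NULL)
  }
  if (length(hits) > 1L) {
    stop("ambiguous tag '", tag, "': variables ",
         paste(vapply(hits, `[[`, "", "name"), collapse = ", "))
  }
  hits[[1L]]
}

model_tag_map <- function(model) {
  out <- list()
  for (v in model$variables) for (tg in v$tags) out[[tg]] <- v$name
  out
}

# Equation index defining a variable (algebraic), or NA.
defining_equation <- function(model, name, ode = FALSE) {
  for (i in seq_along(model$equations)) {
    eq <- model$equations[[i]]
    if (eq$lhs == name && eq$ode == ode) return(i)
  }
  NA_integer_
}

#' Numeric right-hand-side function of a model
#'
#' Returns a function `f(t, y)` evaluating the state derivatives by chained
#' evaluation of the algebraic equations in dependency order — the reference
#' evaluation path used to cross-check substitution, Jacobians and generated
#' code.
#'
#' @param model A `cellml_model`.
#' @return A function of `(t, y)` with `y` named by state.
#' @export
model_rhs_function <- function(model) {
  dg <- build_dependency_graph(model)
  eqs <- model$equations[dg$order]
  params <- Filter(function(v) v$kind == "parameter", model$variables)
  base_env <- list()
  for (p in params) base_env[[p$name]] <- p$init
  free <- model$free_variable
  states <- model$states
  function(t, y) {
    vals <- base_env
    vals[[free]] <- t
    for (s in states) vals[[s]] <- unname(y[[s]])
    derivs <- stats::setNames(numeric(length(states)), states)
    for (eq in eqs) {
      v <- expr_eval(eq$rhs, vals)
      if (eq$ode) derivs[[eq$lhs]] <- v else vals[[eq$lhs]] <- v
    }
    derivs
  }
}

#' Initial state vector of a model
#'
#' @param model A `cellml_model`.
#' @return Named numeric vector of state initial values, in state order.
#' @export
model_initial_state <- function(model) {
  stats::setNames(
    vapply(model$states, function(s) model$variables[[s]]$init, 0),
    model$states
  )
}
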