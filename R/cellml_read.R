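# CellML 1.0 reader: components, variables, units, connections, content
# MathML and RDF metadata annotations, flattened into a cellml_model.
# CellML 1.0 and 1.1 namespaces are accepted; 2.0 is rejected explicitly.
# Imports, reaction elements and group hierarchies are out of scope and
# rejected loudly.

.ns_cellml_10 <- "http://www.cellml.org/cellml/1.0#"
.ns_cellml_11 <- "http://www.cellml.org/cellml/1.1#"
.ns_cellml_20 <- "http://www.cellml.org/cellml/2.0#"
.ns_mathml <- "http://www.w3.org/1998/Math/MathML"
.ns_rdf <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
.ns_cmeta <- "http://www.cellml.org/metadata/1.0#"

local_name <- function(node) sub("^.*:", "", xml2::xml_name(node))

# Attribute lookup by local name, tolerant of namespace prefixes
# (initial_value, rdf:about, cmeta:id, ...).
attr_of <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (!is.na(v)) return(v)
  attrs <- xml2::xml_attrs(node)
  hit <- which(sub("^.*:", "", names(attrs)) == sub("^.*:", "", name))
  if (length(hit)) unname(attrs[[hit[[1L]]]]) else NULL
}

#' Parse a CellML 1.0 document into a model
#'
#' Reads components, variable declarations, unit definitions, content-MathML
#' equations, connections and RDF metadata annotations, merges connected
#' variables into canonical variables, and returns a validated
#' [new_model()] object.  Parsing is deterministic: document order drives
#' variable, equation and state ordering.
#'
#' @param path Path to a CellML 1.0 (or 1.1) XML file.
#' @return A `cellml_model`.
#' @export
parse_cellml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- xml2::read_xml(path)
  root_ns <- xml2::xml_ns(doc)
  uris <- as.character(root_ns)
  if (.ns_cellml_20 %in% uris) {
    stop("unsupported CellML version: 2.0 documents are not supported")
  }
  if (!any(c(.ns_cellml_10, .ns_cellml_11) %in% uris)) {
    stop("not a CellML 1.0/1.1 document (no CellML namespace found)")
  }
  cellml_uri <- if (.ns_cellml_10 %in% uris) .ns_cellml_10 else .ns_cellml_11
  ns <- c(c = cellml_uri, m = .ns_mathml, r = .ns_rdf)

  for (bad in c("import", "reaction", "group")) {
    if (length(xml2::xml_find_all(doc, sprintf("//c:%s", bad), ns)) > 0L) {
      stop("unsupported CellML element <", bad, ">")
    }
  }

  model_name <- attr_of(xml2::xml_root(doc), "name") %||% "model"

  # ---- units definitions ----------------------------------------------------
  reg <- units_registry()
  for (unode in xml2::xml_find_all(doc, "//c:units", ns)) {
    uname <- attr_of(unode, "name")
    if (is.null(uname)) stop("<units> element without a name")
    parts <- lapply(
      xml2::xml_find_all(unode, "./c:unit", ns),
      function(p) {
        list(
          units = attr_of(p, "units") %||%
            stop("<unit> element without a units attribute"),
          prefix = attr_of(p, "prefix"),
          exponent = as.numeric(attr_of(p, "exponent") %||% 1),
          multiplier = as.numeric(attr_of(p, "multiplier") %||% 1)
        )
      }
    )
    if (length(parts) == 0L) {
      if (isTRUE(attr_of(unode, "base_units") == "yes")) next
      stop("<units name='", uname, "'> has no <unit> parts")
    }
    define_unit(reg, uname, parts)
  }

  # ---- components -----------------------------------------------------------
  components <- lapply(
    xml2::xml_find_all(doc, "/c:model/c:component", ns),
    function(cnode) parse_component(cnode, ns)
  )
  names(components) <- vapply(components, `[[`, "", "name")
  if (anyDuplicated(names(components))) {
    stop("duplicate component names in document")
  }

  # ---- connections ----------------------------------------------------------
  raw_conn <- list()
  for (conn in xml2::xml_find_all(doc, "/c:model/c:connection", ns)) {
    mc <- xml2::xml_find_first(conn, "./c:map_components", ns)
    c1 <- attr_of(mc, "component_1"); c2 <- attr_of(mc, "component_2")
    for (mv in xml2::xml_find_all(conn, "./c:map_variables", ns)) {
      raw_conn[[length(raw_conn) + 1L]] <- list(
        component_1 = c1, variable_1 = attr_of(mv, "variable_1"),
        component_2 = c2, variable_2 = attr_of(mv, "variable_2")
      )
    }
  }
  cmap <- resolve_connections(components, raw_conn)

  # ---- metadata -------------------------------------------------------------
  tags <- extract_metadata_tags(doc)

  build_model_from_components(model_name, components, cmap, tags, reg)
}

parse_component <- function(cnode, ns) {
  vars <- lapply(
    xml2::xml_find_all(cnode, "./c:variable", ns),
    function(vn) {
      list(
        name = attr_of(vn, "name") %||% stop("variable without name"),
        units = attr_of(vn, "units") %||% "dimensionless",
        initial_value = as.numeric(attr_of(vn, "initial_value") %||% NA),
        public_interface = attr_of(vn, "public_interface") %||% "none",
        cmeta_id = attr_of(vn, "cmeta:id")
      )
    }
  )
  vnames <- vapply(vars, `[[`, "", "name")
  if (anyDuplicated(vnames)) {
    stop("duplicate variable names in component '", attr_of(cnode, "name"),
         "'")
  }
  names(vars) <- vnames
  list(
    name = attr_of(cnode, "name") %||% stop("component without name"),
    variables = vars,
    math = xml2::xml_find_all(cnode, "./m:math/m:apply", ns)
  )
}

#' Resolve CellML connections into canonical variable classes
#'
#' Performs a union-find over `component.variable` pairs linked by
#' `<connection>` elements and collapses each equivalence class onto one
#' canonical member — the member carrying a definition (initial value or, as
#' determined later, an equation) or declaring `public_interface="out"`.
#'
#' @param components Named list of parsed component documents (as produced
#'   internally by [parse_cellml()]), each with `name` and `variables`.
#' @param connections List of raw connection records with fields
#'   `component_1`, `variable_1`, `component_2`, `variable_2`.
#' @return A `connection_map`: list with `class_of` (named character: each
#'   `comp.var` key to its class id) and `canonical` (class id to `comp.var`
#'   key of the canonical member).
#' @export
resolve_connections <- function(components, connections) {
  key <- function(comp, var) paste0(comp, ".", var)
  parent <- new.env(parent = emptyenv())
  find <- function(x) {
    p <- get0(x, envir = parent, ifnotfound = x)
    if (identical(p, x)) return(x)
    r <- find(p)
    assign(x, r, envir = parent)
    r
  }
  union <- function(a, b) assign(find(a), find(b), envir = parent)

  for (comp in components) {
    for (v in comp$variables) invisible(find(key(comp$name, v$name)))
  }
  for (cn in connections) {
    k1 <- key(cn$component_1, cn$variable_1)
    k2 <- key(cn$component_2, cn$variable_2)
    for (k in c(k1, k2)) {
      parts <- strsplit(k, ".", fixed = TRUE)[[1L]]
      comp <- components[[parts[1L]]]
      if (is.null(comp) || is.null(comp$variables[[parts[2L]]])) {
        stop("connection references unknown variable '", k, "'")
      }
    }
    union(k1, k2)
  }

  all_keys <- unlist(lapply(components, function(comp) {
    vapply(comp$variables, function(v) key(comp$name, v$name), "")
  }), use.names = FALSE)
  class_of <- stats::setNames(vapply(all_keys, find, ""), all_keys)

  var_rec <- function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1L]]
    components[[parts[1L]]]$variables[[parts[2L]]]
  }
  canonical <- list()
  for (cls in unique(class_of)) {
    members <- names(class_of)[class_of == cls]
    has_init <- members[!vapply(members,
                                function(k) is.na(var_rec(k)$initial_value),
                                TRUE)]
    if (length(has_init) > 1L) {
      stop("conflicting definitions: variables ",
           paste(has_init, collapse = " and "),
           " are connected but both carry initial values")
    }
    is_out <- members[vapply(members,
                             function(k) {
                               identical(var_rec(k)$public_interface, "out")
                             }, TRUE)]
    canonical[[cls]] <-
      if (length(has_init) == 1L) has_init else
        if (length(is_out) >= 1L) is_out[[1L]] else members[[1L]]
  }
  structure(list(class_of = class_of, canonical = canonical),
            class = "connection_map")
}

#' Extract RDF metadata annotations
#'
#' Collects `bqbiol:is` statements from all `rdf:RDF` blocks, mapping each
#' annotated `cmeta:id` to the fragment part(s) of the annotation resource
#' URI (e.g. `membrane_voltage`).  Statements referencing a `cmeta:id` that
#' does not exist in the document are dropped with a warning.
#'
#' @param doc An `xml_document` (a parsed CellML file).
#' @return Named list: `cmeta:id` to character vector of tags.
#' @export
extract_metadata_tags <- function(doc) {
  ns <- c(r = .ns_rdf, b = "http://biomodels.net/biology-qualifiers/")
  ids_in_doc <- xml2::xml_attr(
    xml2::xml_find_all(doc, "//*[@cmeta:id]",
                       c(cmeta = .ns_cmeta)), "id"
  )
  out <- list()
  for (desc in xml2::xml_find_all(doc, "//r:RDF/r:Description", ns)) {
    about <- attr_of(desc, "about")
    if (is.null(about) || !startsWith(about, "#")) next
    id <- substring(about, 2L)
    for (isnode in xml2::xml_find_all(desc, "./b:is", ns)) {
      res <- attr_of(isnode, "resource")
      if (is.null(res)) next
      tag <- sub("^.*#", "", res)
      if (!id %in% ids_in_doc) {
        warning("RDF annotation references missing cmeta:id '", id,
                "'; dropped")
        next
      }
      out[[id]] <- unique(c(out[[id]], tag))
    }
  }
  out
}

#' Parse a content-MathML equation
#'
#' Translates a MathML `<apply><eq/>...</apply>` element into an equation
#' over the supported operator set (arithmetic, power and root, exp/ln/log,
#' abs/floor/ceiling, relational and logical operators, piecewise and
#' trigonometric functions).  Any other element is a hard error naming the
#' element.  A `<cn>` with a `cellml:units` attribute has its unit recorded
#' on the returned equation's `cn_units` attribute.
#'
#' @param element An `xml_node`: the `<apply>` holding the top-level `eq`.
#' @param scope Named character vector mapping in-scope `ci` names to global
#'   variable names; a `ci` not in scope is an undefined-variable error.
#' @return A `cellml_equation`.
#' @export
parse_mathml <- function(element, scope) {
  kids <- xml2::xml_children(element)
  if (local_name(element) != "apply" || length(kids) < 3L ||
      local_name(kids[[1L]]) != "eq") {
    stop("expected a content-MathML <apply><eq/>...</apply> equation")
  }
  cn_units <- character()
  note_cn <- function(u) cn_units <<- c(cn_units, u)
  lhs_node <- kids[[2L]]
  rhs <- mathml_to_expr(kids[[3L]], scope, note_cn)

  if (local_name(lhs_node) == "apply" &&
      local_name(xml2::xml_children(lhs_node)[[1L]]) == "diff") {
    dkids <- xml2::xml_children(lhs_node)
    bvar <- dkids[[which(vapply(dkids, local_name, "") == "bvar")]]
    bvar_name <- xml2::xml_text(xml2::xml_child(bvar), trim = TRUE)
    ci_nodes <- dkids[vapply(dkids, local_name, "") == "ci"]
    state_name <- xml2::xml_text(ci_nodes[[1L]], trim = TRUE)
    deg <- which(vapply(xml2::xml_children(bvar), local_name, "") == "degree")
    if (length(deg)) {
      stop("higher-order derivatives are not supported")
    }
    eq <- new_equation(resolve_ci(state_name, scope), rhs, ode = TRUE)
    attr(eq, "bvar") <- resolve_ci(bvar_name, scope)
  } else if (local_name(lhs_node) == "ci") {
    eq <- new_equation(
      resolve_ci(xml2::xml_text(lhs_node, trim = TRUE), scope), rhs
    )
  } else {
    stop("unsupported equation left-hand side <", local_name(lhs_node), ">")
  }
  attr(eq, "cn_units") <- cn_units
  eq
}

resolve_ci <- function(name, scope) {
  name <- trimws(name)
  if (!name %in% names(scope)) {
    stop("undefined variable '", name, "' referenced in mathematics")
  }
  unname(scope[[name]])
}

.mathml_ops <- c(
  plus = "+", minus = "-", times = "*", divide = "/", power = "^",
  exp = "exp", ln = "log", abs = "abs", floor = "floor",
  ceiling = "ceiling",
  sin = "sin", cos = "cos", tan = "tan", arcsin = "asin", arccos = "acos",
  arctan = "atan", sinh = "sinh", cosh = "cosh", tanh = "tanh",
  lt = "<", leq = "<=", gt = ">", geq = ">=", eq = "==", neq = "!=",
  and = "&", or = "|", not = "!"
)

mathml_to_expr <- function(node, scope, note_cn) {
  nm <- local_name(node)
  if (nm == "ci") {
    return(as.name(resolve_ci(xml2::xml_text(node, trim = TRUE), scope)))
  }
  if (nm == "cn") {
    u <- xml2::xml_attr(node, "units")
    if (!is.na(u)) note_cn(u)
    type <- xml2::xml_attr(node, "type")
    if (!is.na(type) && type == "e-notation") {
      parts <- xml2::xml_contents(node)
      nums <- trimws(xml2::xml_text(
        parts[vapply(parts, function(p) xml2::xml_name(p) != "sep", TRUE)]
      ))
      nums <- nums[nzchar(nums)]
      return(as.numeric(nums[[1L]]) * 10^as.numeric(nums[[2L]]))
    }
    v <- as.numeric(xml2::xml_text(node, trim = TRUE))
    if (!is.finite(v)) stop("non-finite numeric constant in <cn>")
    return(v)
  }
  if (nm == "pi") return(pi)
  if (nm == "exponentiale") return(exp(1))
  if (nm == "true") return(TRUE)
  if (nm == "false") return(FALSE)
  if (nm == "piecewise") {
    args <- list()
    otherwise <- NULL
    for (kid in xml2::xml_children(node)) {
      knm <- local_name(kid)
      pk <- xml2::xml_children(kid)
      if (knm == "piece") {
        val <- mathml_to_expr(pk[[1L]], scope, note_cn)
        cond <- mathml_to_expr(pk[[2L]], scope, note_cn)
        args <- c(args, list(cond, val))
      } else if (knm == "otherwise") {
        otherwise <- mathml_to_expr(pk[[1L]], scope, note_cn)
      } else {
        stop("unsupported MathML element <", knm, "> inside <piecewise>")
      }
    }
    if (is.null(otherwise)) {
      stop("<piecewise> without <otherwise> is not supported")
    }
    return(as.call(c(as.name("piecewise"), args, list(otherwise))))
  }
  if (nm != "apply") stop("unsupported MathML element <", nm, ">")

  kids <- xml2::xml_children(node)
  op <- local_name(kids[[1L]])
  argn <- kids[-1L]

  if (op == "root") {
    is_deg <- vapply(argn, local_name, "") == "degree"
    radicand <- mathml_to_expr(argn[[which(!is_deg)[1L]]], scope, note_cn)
    if (any(is_deg)) {
      deg <- mathml_to_expr(xml2::xml_child(argn[[which(is_deg)[1L]]]),
                            scope, note_cn)
      return(bin("^", radicand, bin("/", 1, deg)))
    }
    return(fun1("sqrt", radicand))
  }
  if (op == "log") {
    is_base <- vapply(argn, local_name, "") == "logbase"
    x <- mathml_to_expr(argn[[which(!is_base)[1L]]], scope, note_cn)
    if (any(is_base)) {
      b <- mathml_to_expr(xml2::xml_child(argn[[which(is_base)[1L]]]),
                          scope, note_cn)
      if (is_num(b) && b == 10) return(fun1("log10", x))
      return(as.call(list(as.name("log"), x, b)))
    }
    return(fun1("log10", x))
  }
  if (!op %in% names(.mathml_ops)) {
    stop("unsupported MathML element <", op, ">")
  }
  rop <- .mathml_ops[[op]]
  args <- lapply(argn, mathml_to_expr, scope = scope, note_cn = note_cn)
  if (length(args) == 1L) {
    if (rop == "-") return(neg(args[[1L]]))
    if (rop == "+") return(args[[1L]])
    return(fun1(rop, args[[1L]]))
  }
  out <- args[[1L]]
  for (a in args[-1L]) out <- bin(rop, out, a)
  out
}

# Assemble the flattened model from parsed pieces.
build_model_from_components <- function(model_name, components, cmap, tags,
                                        reg) {
  key_of <- function(comp, var) paste0(comp, ".", var)
  canon_key <- function(comp, var) {
    cmap$canonical[[cmap$class_of[[key_of(comp, var)]]]]
  }

  # choose globally unique names for canonical variables
  canon_keys <- unique(unlist(cmap$canonical, use.names = FALSE))
  short <- vapply(strsplit(canon_keys, ".", fixed = TRUE),
                  function(p) paste(p[-1L], collapse = "."), "")
  dup <- short %in% short[duplicated(short)]
  gname <- ifelse(dup, gsub("\\.", "__", canon_keys), short)
  names(gname) <- canon_keys

  # per-component scope: local ci name -> global name
  scopes <- lapply(components, function(comp) {
    s <- vapply(names(comp$variables), function(v) {
      unname(gname[[canon_key(comp$name, v)]])
    }, "")
    stats::setNames(s, names(comp$variables))
  })
  names(scopes) <- names(components)

  equations <- list()
  free_candidates <- character()
  for (comp in components) {
    for (apply_node in comp$math) {
      eq <- parse_mathml(apply_node, scopes[[comp$name]])
      if (eq$ode) free_candidates <- c(free_candidates, attr(eq, "bvar"))
      equations[[length(equations) + 1L]] <- eq
    }
  }
  free_candidates <- unique(free_candidates)
  if (length(free_candidates) > 1L) {
    stop("multiple differentiation variables found: ",
         paste(free_candidates, collapse = ", "),
         "; only a single free variable is supported")
  }

  ode_lhs <- vapply(Filter(function(e) e$ode, equations), `[[`, "", "lhs")
  alg_lhs <- vapply(Filter(function(e) !e$ode, equations), `[[`, "", "lhs")

  variables <- list()
  for (ck in canon_keys) {
    parts <- strsplit(ck, ".", fixed = TRUE)[[1L]]
    comp <- parts[[1L]]; vlocal <- paste(parts[-1L], collapse = ".")
    rec <- components[[comp]]$variables[[vlocal]]
    nm <- unname(gname[[ck]])
    # collect tags from every member of the class carrying a cmeta:id
    cls <- cmap$class_of[[ck]]
    member_keys <- names(cmap$class_of)[cmap$class_of == cls]
    vtags <- character()
    for (mk in member_keys) {
      mp <- strsplit(mk, ".", fixed = TRUE)[[1L]]
      mrec <- components[[mp[1L]]]$variables[[paste(mp[-1L],
                                                    collapse = ".")]]
      if (!is.null(mrec$cmeta_id) && !is.null(tags[[mrec$cmeta_id]])) {
        vtags <- c(vtags, tags[[mrec$cmeta_id]])
      }
    }
    kind <-
      if (nm %in% ode_lhs) "state"
      else if (length(free_candidates) == 1L && nm == free_candidates) "free"
      else if (nm %in% alg_lhs) "computed"
      else if (!is.na(rec$initial_value)) "parameter"
      else stop("variable '", nm,
                "' has neither a defining equation nor an initial value")
    if (kind == "state" && is.na(rec$initial_value)) {
      stop("state variable '", nm, "' has no initial value")
    }
    variables[[length(variables) + 1L]] <- new_variable(
      name = nm, component = comp, units = rec$units,
      init = rec$initial_value, kind = kind, tags = unique(vtags)
    )
  }

  new_model(model_name, variables, equations,
            free_variable = if (length(free_candidates)) free_candidates else
              "time",
            units = reg)
}
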