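# CellML 1.0 fixture writer.  This is test plumbing, not a general CellML
# exporter: it serialises models produced by the synthetic generator (and
# the Hodgkin-Huxley fixture) to CellML 1.0 XML — components, variables with
# interfaces, unit definitions, content MathML, connections and RDF tags —
# so the reader can be exercised end-to-end with no downloaded corpus.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

cn_xml <- function(x) {
  s <- formatC(x, digits = 17, format = "g")
  if (grepl("e", s, fixed = TRUE)) {
    parts <- strsplit(s, "e", fixed = TRUE)[[1L]]
    mant <- parts[[1L]]
    expn <- as.integer(parts[[2L]])
    return(sprintf(
      "<cn cellml:units=\"dimensionless\" type=\"e-notation\">%s<sep/>%d</cn>",
      mant, expn
    ))
  }
  sprintf("<cn cellml:units=\"dimensionless\">%s</cn>", s)
}

.mathml_names <- c(
  "+" = "plus", "-" = "minus", "*" = "times", "/" = "divide",
  "^" = "power", "<" = "lt", "<=" = "leq", ">" = "gt", ">=" = "geq",
  "==" = "eq", "!=" = "neq", "&" = "and", "|" = "or", "!" = "not",
  exp = "exp", log = "ln", abs = "abs", floor = "floor",
  ceiling = "ceiling", sin = "sin", cos = "cos", tan = "tan",
  asin = "arcsin", acos = "arccos", atan = "arctan", sinh = "sinh",
  cosh = "cosh", tanh = "tanh"
)

expr_to_mathml <- function(e) {
  if (is_num(e)) {
    if (e < 0) {
      return(sprintf("<apply><minus/>%s</apply>", cn_xml(-e)))
    }
    return(cn_xml(e))
  }
  if (is.logical(e)) return(if (e) "<true/>" else "<false/>")
  if (is.symbol(e)) return(sprintf("<ci>%s</ci>", as.character(e)))
  op <- call_name(e)
  args <- call_args(e)
  if (op == "piecewise") {
    n <- length(args)
    k <- (n - 1L) %/% 2L
    pieces <- vapply(seq_len(k), function(i) {
      sprintf("<piece>%s%s</piece>",
              expr_to_mathml(args[[2L * i]]),
              expr_to_mathml(args[[2L * i - 1L]]))
    }, "")
    return(sprintf("<piecewise>%s<otherwise>%s</otherwise></piecewise>",
                   paste(pieces, collapse = ""),
                   expr_to_mathml(args[[n]])))
  }
  if (op == "sqrt") {
    return(sprintf("<apply><root/>%s</apply>", expr_to_mathml(args[[1L]])))
  }
  if (op == "expm1") {
    # no MathML primitive: serialise the equivalent difference
    return(sprintf(
      "<apply><minus/><apply><exp/>%s</apply>%s</apply>",
      expr_to_mathml(args[[1L]]), cn_xml(1)
    ))
  }
  if (op == "log10") {
    return(sprintf("<apply><log/>%s</apply>", expr_to_mathml(args[[1L]])))
  }
  if (op == "log" && length(args) == 2L) {
    return(sprintf(
      "<apply><log/><logbase>%s</logbase>%s</apply>",
      expr_to_mathml(args[[2L]]), expr_to_mathml(args[[1L]])
    ))
  }
  if (!op %in% names(.mathml_names)) {
    stop("cannot serialise operator '", op, "' to MathML")
  }
  sprintf("<apply><%s/>%s</apply>", .mathml_names[[op]],
          paste(vapply(args, expr_to_mathml, ""), collapse = ""))
}

equation_to_mathml <- function(eq, free_variable, indent = "      ") {
  lhs <- if (eq$ode) {
    sprintf(
      "<apply><diff/><bvar><ci>%s</ci></bvar><ci>%s</ci></apply>",
      free_variable, eq$lhs
    )
  } else {
    sprintf("<ci>%s</ci>", eq$lhs)
  }
  rhs <- expr_to_mathml(if (is.numeric(eq$rhs)) as.numeric(eq$rhs) else
    eq$rhs)
  sprintf("%s<apply><eq/>%s%s</apply>", indent, lhs, rhs)
}

.builtin_unit_names <- c(
  "dimensionless", "metre", "meter", "kilogram", "gram", "second",
  "ampere", "kelvin", "celsius", "mole", "candela", "radian", "steradian",
  "hertz", "becquerel", "newton", "pascal", "joule", "watt", "coulomb",
  "volt", "farad", "ohm", "siemens", "weber", "tesla", "henry", "lumen",
  "lux", "gray", "sievert", "katal", "litre", "liter"
)

#' Write a model to a CellML 1.0 file
#'
#' Serialises the model's components, variables (with `in`/`out` public
#' interfaces and connections for cross-component use), custom unit
#' definitions, content-MathML equations and RDF metadata annotations.
#' Intended for fixture generation; round-trips through [parse_cellml()].
#'
#' @param model A `cellml_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cellml <- function(model, path) {
  comps <- unique(vapply(model$variables, `[[`, "", "component"))
  owner <- vapply(model$variables, `[[`, "", "component")
  eq_comp <- vapply(model$equations, function(eq) {
    owner[[eq$lhs]]
  }, "")
  # the free variable is used wherever ODEs or time-dependent maths live
  used_in <- function(comp) {
    used <- character()
    for (i in which(eq_comp == comp)) {
      eq <- model$equations[[i]]
      used <- c(used, expr_vars(eq$rhs),
                if (eq$ode) model$free_variable)
    }
    unique(used)
  }

  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0(
      "<model name=\"%s\" cmeta:id=\"%s\"\n",
      "    xmlns=\"http://www.cellml.org/cellml/1.0#\"\n",
      "    xmlns:cellml=\"http://www.cellml.org/cellml/1.0#\"\n",
      "    xmlns:cmeta=\"http://www.cellml.org/metadata/1.0#\">"
    ), model$name, model$name)
  )

  # custom units used by variables
  used_units <- unique(vapply(model$variables, `[[`, "", "units"))
  for (u in setdiff(used_units, .builtin_unit_names)) {
    def <- get_unit(model$units, u)
    parts <- attr(def, "parts")
    if (is.null(parts)) stop("no stored definition for unit '", u, "'")
    lines <- c(lines, sprintf("  <units name=\"%s\">", u))
    for (p in parts) {
      attrs <- sprintf(" units=\"%s\"", p$units)
      if (!is.null(p$prefix)) {
        attrs <- paste0(attrs, sprintf(" prefix=\"%s\"", p$prefix))
      }
      if (!is.null(p$exponent) && p$exponent != 1) {
        attrs <- paste0(attrs,
                        sprintf(" exponent=\"%g\"", p$exponent))
      }
      if (!is.null(p$multiplier) && p$multiplier != 1) {
        attrs <- paste0(attrs,
                        sprintf(" multiplier=\"%.17g\"", p$multiplier))
      }
      lines <- c(lines, sprintf("    <unit%s/>", attrs))
    }
    lines <- c(lines, "  </units>")
  }

  tagged <- Filter(function(v) length(v$tags) > 0L, model$variables)
  connections <- list()
  for (comp in comps) {
    lines <- c(lines, sprintf("  <component name=\"%s\">", comp))
    here <- names(owner)[owner == comp]
    foreign <- setdiff(used_in(comp), here)
    for (vn in here) {
      v <- model$variables[[vn]]
      attrs <- sprintf(" name=\"%s\" units=\"%s\"", v$name, v$units)
      if (!is.na(v$init)) {
        attrs <- paste0(attrs, sprintf(" initial_value=\"%.17g\"", v$init))
      }
      needed_elsewhere <- any(vapply(comps, function(other) {
        other != comp && v$name %in% used_in(other)
      }, TRUE))
      if (needed_elsewhere) {
        attrs <- paste0(attrs, " public_interface=\"out\"")
      }
      if (length(v$tags) > 0L) {
        attrs <- paste0(attrs, sprintf(" cmeta:id=\"%s\"", v$tags[[1L]]))
      }
      lines <- c(lines, sprintf("    <variable%s/>", attrs))
    }
    for (vn in foreign) {
      v <- model$variables[[vn]]
      lines <- c(lines, sprintf(
        "    <variable name=\"%s\" units=\"%s\" public_interface=\"in\"/>",
        v$name, v$units
      ))
      connections[[length(connections) + 1L]] <-
        c(owner[[vn]], comp, v$name)
    }
    eq_idx <- which(eq_comp == comp)
    if (length(eq_idx)) {
      lines <- c(lines,
                 "    <math xmlns=\"http://www.w3.org/1998/Math/MathML\">")
      for (i in eq_idx) {
        lines <- c(lines, equation_to_mathml(model$equations[[i]],
                                             model$free_variable))
      }
      lines <- c(lines, "    </math>")
    }
    lines <- c(lines, "  </component>")
  }

  # one connection element per component pair
  if (length(connections)) {
    pairs <- unique(lapply(connections, function(x) x[1:2]))
    for (pr in pairs) {
      lines <- c(lines, "  <connection>",
                 sprintf(
                   "    <map_components component_1=\"%s\" component_2=\"%s\"/>",
                   pr[[1L]], pr[[2L]]
                 ))
      for (cn in connections) {
        if (identical(cn[1:2], pr)) {
          lines <- c(lines, sprintf(
            "    <map_variables variable_1=\"%s\" variable_2=\"%s\"/>",
            cn[[3L]], cn[[3L]]
          ))
        }
      }
      lines <- c(lines, "  </connection>")
    }
  }

  if (length(tagged)) {
    lines <- c(lines, paste0(
      "  <rdf:RDF xmlns:rdf=\"http://www.w3.org/1999/02/22-rdf-syntax-ns#\"",
      " xmlns:bqbiol=\"http://biomodels.net/biology-qualifiers/\">"
    ))
    for (v in tagged) {
      lines <- c(lines, sprintf(
        "    <rdf:Description rdf:about=\"#%s\">", v$tags[[1L]]
      ))
      for (tg in v$tags) {
        lines <- c(lines, sprintf(paste0(
          "      <bqbiol:is rdf:resource=",
          "\"https://chaste.comlab.ox.ac.uk/cellml/ns/oxford-metadata#%s\"/>"
        ), tg))
      }
      lines <- c(lines, "    </rdf:Description>")
    }
    lines <- c(lines, "  </rdf:RDF>")
  }

  lines <- c(lines, "</model>")
  writeLines(lines, path)
  invisible(path)
}
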