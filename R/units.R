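# Dimensional analysis over CellML unit definitions.  A unit is an exponent
# vector over the seven SI base dimensions plus a multiplicative factor to
# coherent SI and an optional affine offset (celsius).  Compound definitions
# compose multiplicatively; offsets are rejected inside compounds, which is
# standard CellML practice.

.si_dims <- c("m", "kg", "s", "A", "K", "mol", "cd")

unit_def <- function(dims = stats::setNames(numeric(7), .si_dims),
                     factor = 1, offset = 0) {
  stopifnot(factor > 0)
  structure(list(dims = dims, factor = factor, offset = offset),
            class = "unit_definition")
}

dim_vec <- function(...) {
  d <- stats::setNames(numeric(7), .si_dims)
  args <- list(...)
  d[names(args)] <- unlist(args)
  d
}

.si_prefixes <- c(
  yotta = 24, zetta = 21, exa = 18, peta = 15, tera = 12, giga = 9,
  mega = 6, kilo = 3, hecto = 2, deka = 1, deca = 1, deci = -1,
  centi = -2, milli = -3, micro = -6, nano = -9, pico = -12,
  femto = -15, atto = -18, zepto = -21, yocto = -24
)

#' Create a units registry seeded with the CellML built-in units
#'
#' @return A `units_registry` environment mapping unit names to definitions.
#' @export
units_registry <- function() {
  reg <- new.env(parent = emptyenv())
  put <- function(name, def) assign(name, def, envir = reg)
  put("dimensionless", unit_def())
  put("metre", unit_def(dim_vec(m = 1)))
  put("meter", unit_def(dim_vec(m = 1)))
  put("kilogram", unit_def(dim_vec(kg = 1)))
  put("gram", unit_def(dim_vec(kg = 1), 1e-3))
  put("second", unit_def(dim_vec(s = 1)))
  put("ampere", unit_def(dim_vec(A = 1)))
  put("kelvin", unit_def(dim_vec(K = 1)))
  put("celsius", unit_def(dim_vec(K = 1), 1, offset = 273.15))
  put("mole", unit_def(dim_vec(mol = 1)))
  put("candela", unit_def(dim_vec(cd = 1)))
  put("radian", unit_def())
  put("steradian", unit_def())
  put("hertz", unit_def(dim_vec(s = -1)))
  put("becquerel", unit_def(dim_vec(s = -1)))
  put("newton", unit_def(dim_vec(kg = 1, m = 1, s = -2)))
  put("pascal", unit_def(dim_vec(kg = 1, m = -1, s = -2)))
  put("joule", unit_def(dim_vec(kg = 1, m = 2, s = -2)))
  put("watt", unit_def(dim_vec(kg = 1, m = 2, s = -3)))
  put("coulomb", unit_def(dim_vec(A = 1, s = 1)))
  put("volt", unit_def(dim_vec(kg = 1, m = 2, s = -3, A = -1)))
  put("farad", unit_def(dim_vec(kg = -1, m = -2, s = 4, A = 2)))
  put("ohm", unit_def(dim_vec(kg = 1, m = 2, s = -3, A = -2)))
  put("siemens", unit_def(dim_vec(kg = -1, m = -2, s = 3, A = 2)))
  put("weber", unit_def(dim_vec(kg = 1, m = 2, s = -2, A = -1)))
  put("tesla", unit_def(dim_vec(kg = 1, s = -2, A = -1)))
  put("henry", unit_def(dim_vec(kg = 1, m = 2, s = -2, A = -2)))
  put("lumen", unit_def(dim_vec(cd = 1)))
  put("lux", unit_def(dim_vec(cd = 1, m = -2)))
  put("gray", unit_def(dim_vec(m = 2, s = -2)))
  put("sievert", unit_def(dim_vec(m = 2, s = -2)))
  put("katal", unit_def(dim_vec(mol = 1, s = -1)))
  put("litre", unit_def(dim_vec(m = 3), 1e-3))
  put("liter", unit_def(dim_vec(m = 3), 1e-3))
  class(reg) <- c("units_registry", "environment")
  reg
}

#' Look up a unit definition
#'
#' @param registry A [units_registry()].
#' @param name Unit name.
#' @return The `unit_definition`.
#' @export
get_unit <- function(registry, name) {
  if (!exists(name, envir = registry, inherits = FALSE)) {
    stop("unknown unit '", name, "'")
  }
  get(name, envir = registry, inherits = FALSE)
}

#' Define a unit from component parts
#'
#' Registers a compound unit built from existing units, as in a CellML
#' `<units>` element: each part references a base unit with optional SI
#' prefix, exponent and multiplier.  Redefining a name with a different
#' signature is an error; units with affine offsets may not appear in
#' compounds.
#'
#' @param registry A [units_registry()] (modified in place).
#' @param name New unit name.
#' @param parts List of parts, each a list with `units` and optional
#'   `prefix` (SI prefix name or integer power of ten), `exponent`,
#'   `multiplier`.
#' @return The new `unit_definition`, invisibly.
#' @export
define_unit <- function(registry, name, parts) {
  dims <- dim_vec()
  factor <- 1
  for (p in parts) {
    base <- get_unit(registry, p$units)
    if (base$offset != 0) {
      stop("unit '", p$units, "' has an offset and cannot appear in the ",
           "compound definition of '", name, "'")
    }
    pref <- p$prefix %||% 0
    if (is.character(pref)) {
      if (!pref %in% names(.si_prefixes)) stop("unknown prefix '", pref, "'")
      pref <- .si_prefixes[[pref]]
    }
    expn <- p$exponent %||% 1
    mult <- p$multiplier %||% 1
    factor <- factor * mult * (base$factor * 10^pref)^expn
    dims <- dims + base$dims * expn
  }
  def <- unit_def(dims, factor)
  attr(def, "parts") <- parts
  if (exists(name, envir = registry, inherits = FALSE)) {
    old <- get_unit(registry, name)
    if (!isTRUE(all.equal(old$dims, def$dims)) ||
        abs(old$factor - def$factor) > 1e-12 * def$factor) {
      stop("unit '", name, "' redefined with a different signature")
    }
    return(invisible(old))
  }
  assign(name, def, envir = registry)
  invisible(def)
}

unit_signature <- function(def) {
  nz <- def$dims[def$dims != 0]
  if (length(nz) == 0L) return("dimensionless")
  paste(sprintf("%s^%g", names(nz), nz), collapse = " ")
}

#' Conversion factor between two units
#'
#' Returns `k` such that a quantity expressed in `from` times `k` gives the
#' quantity expressed in `to`.
#'
#' @param registry A [units_registry()].
#' @param from,to Unit names or `unit_definition` objects.
#' @return A single number.
#' @examples
#' reg <- units_registry()
#' define_unit(reg, "millivolt", list(list(units = "volt", prefix = "milli")))
#' conversion_factor(reg, "volt", "millivolt") # 1000
#' @export
conversion_factor <- function(registry, from, to) {
  f <- if (is.character(from)) get_unit(registry, from) else from
  t <- if (is.character(to)) get_unit(registry, to) else to
  if (!isTRUE(all.equal(f$dims, t$dims))) {
    stop("dimensional mismatch: cannot convert [", unit_signature(f),
         "] to [", unit_signature(t), "]")
  }
  if (f$offset != 0 || t$offset != 0) {
    stop("affine units do not admit a pure multiplicative conversion factor")
  }
  f$factor / t$factor
}

# Target interface units used by the conversion pass.
register_target_units <- function(reg) {
  if (!exists("millivolt", reg, inherits = FALSE)) {
    define_unit(reg, "millivolt",
                list(list(units = "volt", prefix = "milli")))
  }
  if (!exists("millisecond", reg, inherits = FALSE)) {
    define_unit(reg, "millisecond",
                list(list(units = "second", prefix = "milli")))
  }
  if (!exists("uA_per_cm2", reg, inherits = FALSE)) {
    define_unit(reg, "uA_per_cm2", list(
      list(units = "ampere", prefix = "micro"),
      list(units = "metre", prefix = "centi", exponent = -2)
    ))
  }
  reg
}

#' Convert tagged interface quantities to the fixed target units
#'
#' Re-expresses the variables tagged `membrane_voltage`, `time` and
#' `membrane_stimulus_current` in millivolts, milliseconds and microamperes
#' per square centimetre respectively, inserting compensating factors into
#' defining equations, uses and initial values so model semantics are
#' unchanged.  Idempotent; untagged variables are untouched.
#'
#' A stimulus current whose units are not dimensionally an area-normalised
#' current is a conversion error: converting raw currents via cell
#' capacitance is out of scope and fails loudly rather than guessing.
#'
#' @param model A `cellml_model`.
#' @return The converted `cellml_model`.
#' @export
convert_interface_quantities <- function(model) {
  reg <- register_target_units(model$units)
  plan <- list(
    list(tag = "membrane_voltage", target = "millivolt"),
    list(tag = "time", target = "millisecond"),
    list(tag = "membrane_stimulus_current", target = "uA_per_cm2")
  )
  for (p in plan) {
    v <- get_tagged_variable(model, p$tag, required = FALSE)
    if (is.null(v)) next
    k <- tryCatch(
      conversion_factor(reg, v$units, p$target),
      error = function(err) {
        stop("cannot convert '", v$name, "' (tagged ", p$tag, ") from '",
             v$units, "' to '", p$target, "': ", conditionMessage(err),
             call. = FALSE)
      }
    )
    if (k != 1) model <- rescale_variable(model, v$name, k)
    model$variables[[v$name]]$units <- p$target
  }
  model
}

# Rescale one variable x -> k*x (the stored variable now holds the value in
# the new units): initial value and defining equation are scaled by k, every
# use in other equations is divided by k.  Rescaling the free variable t
# additionally divides every ODE right-hand side by k (d/dt_new = (1/k) d/dt).
rescale_variable <- function(model, name, k) {
  is_free <- identical(name, model$free_variable)
  for (i in seq_along(model$equations)) {
    eq <- model$equations[[i]]
    rhs <- eq$rhs
    if (contains_var(rhs, name)) {
      rhs <- sub_vars(rhs, stats::setNames(
        list(bin("/", as.name(name), k)), name
      ))
    }
    if (eq$lhs == name) rhs <- bin("*", k, rhs)
    if (eq$ode && is_free) rhs <- bin("/", rhs, k)
    if (eq$ode && eq$lhs == name && !is_free) {
      # state in new units but still differentiated w.r.t. the free variable
      # (already handled by the k * rhs above)
    }
    model$equations[[i]]$rhs <- fold_constants(rhs)
  }
  v <- model$variables[[name]]
  if (!is.na(v$init)) model$variables[[name]]$init <- v$init * k
  model
}
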