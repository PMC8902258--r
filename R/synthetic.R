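# Deterministic synthetic-model generator.  Produces Hodgkin-Huxley-style
# gating models (dx/dt = alpha(V)(1-x) - beta(V)x, capacitive voltage ODE
# summing membrane currents) with a requested number of planted GHK-form
# singular terms whose (variant, B, v0) ground truth is returned alongside,
# so detection recall/precision and every downstream stage are testable with
# no external model corpus.

#' Generator specification
#'
#' Defaults describe a small, non-stiff cardiac-style cell: a handful of
#' gates with exponential/sigmoid rate laws, rate constants of order
#' 0.01-0.5 per ms, GHK slope factors B of 0.02-0.5 per mV and singular
#' voltages across the physiological range -90..+60 mV.
#'
#' @param seed Integer seed; identical seeds give identical models.
#' @param n_gates Number of gating state variables (>= 1).
#' @param n_ghk_currents Number of planted GHK-form current terms.
#' @param b_range Range for the slope constant B (per mV).
#' @param v0_range Range for the singular voltage v0 (mV).
#' @param variant_mix Probabilities over the four GHK form variants
#'   `U/(exp(U)-1)`, `U/(-1+exp(U))`, `(exp(U)-1)/U`, `(-1+exp(U))/U`.
#' @param prefixed_fraction Fraction of planted terms wrapped in a manual
#'   piecewise fix (which the detector must skip).
#' @param stimulus Include a tagged square-pulse stimulus current.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(seed = 1L, n_gates = 3L, n_ghk_currents = 2L,
                           b_range = c(0.02, 0.5), v0_range = c(-90, 60),
                           variant_mix = c(0.4, 0.2, 0.2, 0.2),
                           prefixed_fraction = 0, stimulus = TRUE) {
  stopifnot(n_gates >= 1L, n_ghk_currents >= 0L,
            diff(b_range) > 0, diff(v0_range) > 0,
            length(variant_mix) == 4L, all(variant_mix >= 0),
            prefixed_fraction >= 0, prefixed_fraction <= 1)
  structure(
    list(seed = as.integer(seed), n_gates = as.integer(n_gates),
         n_ghk_currents = as.integer(n_ghk_currents), b_range = b_range,
         v0_range = v0_range, variant_mix = variant_mix / sum(variant_mix),
         prefixed_fraction = prefixed_fraction, stimulus = isTRUE(stimulus)),
    class = "generator_spec"
  )
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

register_synthetic_units <- function(reg) {
  register_target_units(reg)
  if (!exists("per_millisecond", reg, inherits = FALSE)) {
    define_unit(reg, "per_millisecond",
                list(list(units = "second", prefix = "milli",
                          exponent = -1)))
    define_unit(reg, "microF_per_cm2", list(
      list(units = "farad", prefix = "micro"),
      list(units = "metre", prefix = "centi", exponent = -2)
    ))
    define_unit(reg, "milliS_per_cm2", list(
      list(units = "siemens", prefix = "milli"),
      list(units = "metre", prefix = "centi", exponent = -2)
    ))
  }
  reg
}

rand_in <- function(range) stats::runif(1, range[1L], range[2L])

# One GHK-form current expression plus its ground-truth record.
plant_ghk_term <- function(name, variant, B, v0, gbar, gate = NULL,
                           k_style = 1) {
  V <- as.name("V")
  U <- bin("*", B, bin("-", V, v0))
  affine <- bin("-", V, v0)
  den_exp <- function(first) {
    if (k_style != 1) {
      bin("-", bin("*", k_style, fun1("exp", U)), k_style)
    } else if (first) {
      bin("-", fun1("exp", U), 1)
    } else {
      bin("+", -1, fun1("exp", U))
    }
  }
  core <- switch(variant,
    bin("/", affine, den_exp(TRUE)),
    bin("/", affine, den_exp(FALSE)),
    bin("/", den_exp(TRUE), affine),
    bin("/", den_exp(FALSE), affine)
  )
  e <- bin("*", gbar, core)
  if (!is.null(gate)) e <- bin("*", e, as.name(gate))
  e
}

#' Generate a synthetic gating model with planted singularities
#'
#' @param spec A [generator_spec()].
#' @return List with `model` (a valid `cellml_model`) and `truth`, a
#'   data.frame of planted terms (equation, variant, B, v0, prefixed).
#' @export
generate_model <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  with_local_seed(spec$seed, {
    vars <- list()
    eqs <- list()
    add_var <- function(...) vars[[length(vars) + 1L]] <<- new_variable(...)
    add_eq <- function(...) eqs[[length(eqs) + 1L]] <<- new_equation(...)

    add_var("time", "environment", "millisecond", kind = "free",
            tags = "time")
    add_var("V", "membrane", "millivolt", init = -80, kind = "state",
            tags = "membrane_voltage")
    add_var("Cm", "membrane", "microF_per_cm2", init = 1,
            kind = "parameter")

    gates <- paste0("x", seq_len(spec$n_gates))
    current_names <- character()
    for (i in seq_len(spec$n_gates)) {
      g <- gates[[i]]
      comp <- paste0("gate_", g)
      add_var(g, comp, "dimensionless", init = round(stats::runif(1, 0.2,
                                                                  0.8), 3),
              kind = "state")
      for (rate in c("alpha", "beta")) {
        rn <- paste0(rate, "_", g)
        add_var(rn, comp, "per_millisecond", kind = "computed")
        A <- round(rand_in(c(0.02, 0.4)), 4)
        Vh <- round(rand_in(c(-60, 0)), 1)
        s <- round(rand_in(c(8, 30)), 1)
        shape <- sample(c("exponential", "sigmoid"), 1)
        rhs <- if (shape == "exponential") {
          bin("*", A, fun1("exp", bin("/", bin("-", as.name("V"), Vh), s)))
        } else {
          bin("/", A, bin("+", 1, fun1("exp", bin(
            "/", bin("-", Vh, as.name("V")), s
          ))))
        }
        add_eq(rn, rhs)
      }
      add_eq(g, bin(
        "-",
        bin("*", as.name(paste0("alpha_", g)),
            bin("-", 1, as.name(g))),
        bin("*", as.name(paste0("beta_", g)), as.name(g))
      ), ode = TRUE)

      # ohmic current through this gate, via a driving-potential
      # intermediate to give the dependency graph some depth
      E <- round(rand_in(c(-90, 60)), 1)
      gmax <- round(rand_in(c(0.05, 2)), 3)
      vd <- paste0("vd_", g)
      cur <- paste0("i_", g)
      add_var(vd, comp, "millivolt", kind = "computed")
      add_eq(vd, bin("-", as.name("V"), E))
      add_var(cur, comp, "uA_per_cm2", kind = "computed",
              tags = paste0("membrane_", g, "_current"))
      add_eq(cur, bin("*", bin("*", gmax, as.name(g)), as.name(vd)))
      current_names <- c(current_names, cur)
    }

    truth <- list()
    n_pref <- round(spec$prefixed_fraction * spec$n_ghk_currents)
    prefixed <- rep(c(TRUE, FALSE),
                    c(n_pref, spec$n_ghk_currents - n_pref))
    for (j in seq_len(spec$n_ghk_currents)) {
      variant <- sample(4L, 1, prob = spec$variant_mix)
      v0 <- round(rand_in(spec$v0_range), 2)
      bmax <- spec$b_range[2L]
      if (variant %in% 3:4) {
        # the reciprocal forms grow like exp(|U|) away from v0; bound the
        # exponent over the voltage range so planted currents stay within
        # physiological magnitudes
        excursion <- max(abs(spec$v0_range[1L] - v0),
                         abs(spec$v0_range[2L] - v0))
        bmax <- max(spec$b_range[1L], min(bmax, 8 / excursion))
      }
      B <- round(rand_in(c(spec$b_range[1L], bmax)), 4)
      if (stats::runif(1) < 0.5) B <- -B
      gbar <- round(rand_in(c(0.01, 0.5)), 4)
      gate <- if (stats::runif(1) < 0.5) sample(gates, 1) else NULL
      k_style <- sample(c(1, 1, 1, 0.5, 2, -1), 1)
      cur <- paste0("i_ghk", j)
      e <- plant_ghk_term(cur, variant, B, v0, gbar, gate, k_style)
      if (prefixed[[j]]) {
        # manual constant fix as found in published model files
        limit <- bin("/", gbar, B * k_style)
        if (!is.null(gate)) limit <- bin("*", limit, as.name(gate))
        if (variant %in% 3:4) {
          limit <- if (is.null(gate)) bin("*", gbar, B * k_style) else
            bin("*", bin("*", gbar, B * k_style), as.name(gate))
        }
        delta <- 1e-6 / abs(B)
        e <- as.call(list(
          as.name("piecewise"),
          bin("<", fun1("abs", bin("-", as.name("V"), v0)), delta),
          limit, e
        ))
      }
      add_var(cur, "ghk_currents", "uA_per_cm2", kind = "computed",
              tags = paste0("membrane_ghk", j, "_current"))
      add_eq(cur, e)
      current_names <- c(current_names, cur)
      truth[[j]] <- data.frame(
        equation = cur, variant = variant, B = B, v0 = v0,
        prefixed = prefixed[[j]]
      )
    }

    if (spec$stimulus) {
      for (p in list(
        list("stim_amplitude", "uA_per_cm2", -25,
             "membrane_stimulus_current_amplitude"),
        list("stim_duration", "millisecond", 2,
             "membrane_stimulus_current_duration"),
        list("stim_offset", "millisecond", 10,
             "membrane_stimulus_current_offset"),
        list("stim_period", "millisecond", 1000,
             "membrane_stimulus_current_period")
      )) {
        add_var(p[[1L]], "stimulus", p[[2L]], init = p[[3L]],
                kind = "parameter", tags = p[[4L]])
      }
      add_var("i_stim", "stimulus", "uA_per_cm2", kind = "computed",
              tags = "membrane_stimulus_current")
      tl <- bin("-", bin("-", as.name("time"), as.name("stim_offset")),
                bin("*", as.name("stim_period"),
                    fun1("floor", bin(
                      "/",
                      bin("-", as.name("time"), as.name("stim_offset")),
                      as.name("stim_period")
                    ))))
      add_eq("i_stim", as.call(list(
        as.name("piecewise"),
        bin("&", bin(">=", tl, 0), bin("<", tl, as.name("stim_duration"))),
        as.name("stim_amplitude"), 0
      )))
      current_names <- c(current_names, "i_stim")
    }

    total <- Reduce(function(a, b) bin("+", a, b),
                    lapply(current_names, as.name))
    add_eq("V", bin("/", neg(total), as.name("Cm")), ode = TRUE)

    model <- new_model(
      sprintf("synthetic_model_seed_%d", spec$seed), vars, eqs,
      free_variable = "time",
      units = register_synthetic_units(units_registry())
    )
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(equation = character(), variant = integer(),
                 B = numeric(), v0 = numeric(), prefixed = logical())
    list(model = model, truth = truth)
  })
}

#' Hodgkin-Huxley 1952 squid-axon fixture (original voltage convention)
#'
#' The classic four-state model in its original convention, in which the
#' rate equations for the m and n gates carry GHK-form terms in `(V + 25)`
#' and `(V + 10)`: voltage clamps to -25 or -10 mV hit removable 0/0
#' singularities, so the fixer must report exactly two fixes.
#'
#' @return A `cellml_model` with states V, m, h, n across seven components.
#' @export
make_hh_1952_fixture <- function() {
  vars <- list()
  eqs <- list()
  add_var <- function(...) vars[[length(vars) + 1L]] <<- new_variable(...)
  add_eq <- function(...) eqs[[length(eqs) + 1L]] <<- new_equation(...)

  add_var("time", "membrane", "millisecond", kind = "free", tags = "time")
  add_var("V", "membrane", "millivolt", init = 0, kind = "state",
          tags = "membrane_voltage")
  add_var("Cm", "membrane", "microF_per_cm2", init = 1, kind = "parameter")

  add_var("g_Na", "sodium_channel", "milliS_per_cm2", init = 120,
          kind = "parameter")
  add_var("E_Na", "sodium_channel", "millivolt", init = -115,
          kind = "parameter")
  add_var("i_Na", "sodium_channel", "uA_per_cm2", kind = "computed",
          tags = "membrane_fast_sodium_current")
  add_eq("i_Na", "g_Na * m^3 * h * (V - E_Na)")

  add_var("m", "sodium_channel_m_gate", "dimensionless", init = 0.0529,
          kind = "state")
  add_var("alpha_m", "sodium_channel_m_gate", "per_millisecond",
          kind = "computed")
  add_var("beta_m", "sodium_channel_m_gate", "per_millisecond",
          kind = "computed")
  add_eq("alpha_m", "0.1 * (V + 25) / (exp((V + 25) / 10) - 1)")
  add_eq("beta_m", "4 * exp(V / 18)")
  add_eq("m", "alpha_m * (1 - m) - beta_m * m", ode = TRUE)

  add_var("h", "sodium_channel_h_gate", "dimensionless", init = 0.5961,
          kind = "state")
  add_var("alpha_h", "sodium_channel_h_gate", "per_millisecond",
          kind = "computed")
  add_var("beta_h", "sodium_channel_h_gate", "per_millisecond",
          kind = "computed")
  add_eq("alpha_h", "0.07 * exp(V / 20)")
  add_eq("beta_h", "1 / (exp((V + 30) / 10) + 1)")
  add_eq("h", "alpha_h * (1 - h) - beta_h * h", ode = TRUE)

  add_var("g_K", "potassium_channel", "milliS_per_cm2", init = 36,
          kind = "parameter")
  add_var("E_K", "potassium_channel", "millivolt", init = 12,
          kind = "parameter")
  add_var("i_K", "potassium_channel", "uA_per_cm2", kind = "computed",
          tags = "membrane_potassium_current")
  add_eq("i_K", "g_K * n^4 * (V - E_K)")

  add_var("n", "potassium_channel_n_gate", "dimensionless", init = 0.3177,
          kind = "state")
  add_var("alpha_n", "potassium_channel_n_gate", "per_millisecond",
          kind = "computed")
  add_var("beta_n", "potassium_channel_n_gate", "per_millisecond",
          kind = "computed")
  add_eq("alpha_n", "0.01 * (V + 10) / (exp((V + 10) / 10) - 1)")
  add_eq("beta_n", "0.125 * exp(V / 80)")
  add_eq("n", "alpha_n * (1 - n) - beta_n * n", ode = TRUE)

  add_var("g_L", "leakage_current", "milliS_per_cm2", init = 0.3,
          kind = "parameter")
  add_var("E_L", "leakage_current", "millivolt", init = -10.613,
          kind = "parameter")
  add_var("i_L", "leakage_current", "uA_per_cm2", kind = "computed",
          tags = "membrane_leakage_current")
  add_eq("i_L", "g_L * (V - E_L)")

  for (p in list(
    list("stim_amplitude", "uA_per_cm2", 20,
         "membrane_stimulus_current_amplitude"),
    list("stim_duration", "millisecond", 0.5,
         "membrane_stimulus_current_duration"),
    list("stim_offset", "millisecond", 5,
         "membrane_stimulus_current_offset")
  )) {
    add_var(p[[1L]], "membrane", p[[2L]], init = p[[3L]],
            kind = "parameter", tags = p[[4L]])
  }
  add_var("i_stim", "membrane", "uA_per_cm2", kind = "computed",
          tags = "membrane_stimulus_current")
  add_eq("i_stim", paste0(
    "piecewise(time >= stim_offset & time < stim_offset + stim_duration, ",
    "stim_amplitude, 0)"
  ))

  add_eq("V", "-(i_Na + i_K + i_L + i_stim) / Cm", ode = TRUE)

  new_model("hodgkin_huxley_squid_axon_model_1952", vars, eqs,
            free_variable = "time",
            units = register_synthetic_units(units_registry()))
}
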