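# Canonical cell population dynamics models.
#
# Six models are supported, all with time measured in hours and rates in 1/h:
#   live / total            dN/dt = r N                    (net exponential)
#   live_logistic / total_  dN/dt = r (1 - N/cap) N        (logistic)
#   live_dead               dL/dt = (b - d) L
#                           dD/dt = d L - c D              (birth-death-clearance)
#   live_dead_logistic      dL/dt = b (1 - L/L_cap) L - d L
#                           dD/dt = d L - c D
#
# Closed forms are used wherever they exist; only live_dead_logistic is
# integrated numerically. Models are parameterised relative to the first
# observed time, so trajectories start at the supplied initial condition.

new_trajectory <- function(times, values) {
  stopifnot(is.list(values), all(vapply(values, length, 1L) == length(times)))
  structure(list(times = as.numeric(times), values = values),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d time points, observables: %s>\n",
              length(x$times), paste(names(x$values), collapse = ", ")))
  invisible(x)
}

# Unvalidated closed-form cores. The exported simulators validate their
# arguments and delegate here; the fitting loop calls the cores directly
# (finite-difference steps may probe infinitesimally outside the bounds).

core_exponential <- function(initial, growth_rate, times, observable) {
  tau <- times - times[1L]
  new_trajectory(times,
                 stats::setNames(list(initial * exp(growth_rate * tau)),
                                 observable))
}

core_logistic <- function(initial, growth_rate, cap, times, observable) {
  tau <- times - times[1L]
  vals <- if (initial == 0) rep(0, length(times)) else
    cap / (1 + (cap / initial - 1) * exp(-growth_rate * tau))
  new_trajectory(times, stats::setNames(list(vals), observable))
}

core_live_dead <- function(initial_live, initial_dead, birth_rate,
                           death_rate, clearance_rate, times) {
  tau <- times - times[1L]
  net <- birth_rate - death_rate
  live <- initial_live * exp(net * tau)
  denom <- net + clearance_rate
  dead <- if (abs(denom) < 1e-12) {
    (initial_dead + death_rate * initial_live * tau) *
      exp(-clearance_rate * tau)
  } else {
    initial_dead * exp(-clearance_rate * tau) +
      death_rate * initial_live *
        (exp(net * tau) - exp(-clearance_rate * tau)) / denom
  }
  new_trajectory(times, list(Live = live, Dead = dead))
}

core_live_dead_logistic <- function(initial_live, initial_dead, birth_rate,
                                    death_rate, clearance_rate, L_cap,
                                    times) {
  if (length(times) == 1L) {
    return(new_trajectory(times, list(Live = initial_live,
                                      Dead = initial_dead)))
  }
  rhs <- function(t, y, p) {
    list(c(
      p["b"] * (1 - y[1L] / p["K"]) * y[1L] - p["d"] * y[1L],
      p["d"] * y[1L] - p["cl"] * y[2L]
    ))
  }
  sol <- tryCatch(
    deSolve::ode(
      y = c(L = initial_live, D = initial_dead),
      times = times - times[1L],
      func = rhs,
      parms = c(b = birth_rate, d = death_rate, cl = clearance_rate,
                K = L_cap),
      method = "lsoda", rtol = 1e-8, atol = 1e-6
    ),
    error = function(e) stop_numerical(
      sprintf("ODE integration failed for live_dead_logistic: %s",
              conditionMessage(e)))
  )
  if (nrow(sol) != length(times)) {
    stop_numerical("ODE integrator returned an incomplete solution (step underflow?)")
  }
  new_trajectory(times, list(Live = pmax(sol[, "L"], 0),
                             Dead = pmax(sol[, "D"], 0)))
}

#' Exponential growth trajectory
#'
#' Closed-form solution of dN/dt = r N relative to the first time point:
#' N(t) = N0 * exp(r * (t - t0)). Serves both the live-cell and total-cell
#' exponential models; `growth_rate` is a net rate (birth minus death) and
#' may be negative for shrinking cultures.
#'
#' @param initial Cell count at the first time point (>= 0).
#' @param growth_rate Net growth rate in 1/h (may be negative).
#' @param times Strictly increasing time vector in hours.
#' @param observable Name of the observable the values represent
#'   ("Live" or "Total").
#' @return A `trajectory` object.
#' @export
#' @examples
#' simulate_exponential(100, 0.05, c(0, 24, 48))
simulate_exponential <- function(initial, growth_rate, times,
                                 observable = "Live") {
  check_times(times)
  check_nonneg_scalar(initial, "initial")
  if (!is.numeric(growth_rate) || length(growth_rate) != 1L || is.na(growth_rate)) {
    stop_invalid_input("`growth_rate` must be a single number")
  }
  core_exponential(initial, growth_rate, times, observable)
}

#' Logistic growth trajectory
#'
#' Closed-form solution of dN/dt = r (1 - N/cap) N:
#' N(t) = cap / (1 + (cap/N0 - 1) exp(-r (t - t0))). When N0 equals the
#' carrying capacity the population stays constant at the capacity.
#'
#' @inheritParams simulate_exponential
#' @param cap Carrying capacity in cells (> 0).
#' @return A `trajectory` object.
#' @export
simulate_logistic <- function(initial, growth_rate, cap, times,
                              observable = "Live") {
  check_times(times)
  check_nonneg_scalar(initial, "initial")
  if (!is.numeric(cap) || length(cap) != 1L || is.na(cap) || cap <= 0) {
    stop_invalid_input("carrying capacity `cap` must be > 0")
  }
  core_logistic(initial, growth_rate, cap, times, observable)
}

#' Birth-death-clearance trajectory
#'
#' Closed-form solution of the two-compartment model
#' dL/dt = (b - d) L, dD/dt = d L - c D. The dead compartment solves a
#' linear ODE driven by the live population:
#' D(t) = D0 exp(-c t) + d L0 (exp((b-d) t) - exp(-c t)) / (b - d + c),
#' with the resonant case b - d + c = 0 handled by its analytic limit
#' D(t) = (D0 + d L0 t) exp(-c t).
#'
#' @param initial_live,initial_dead Cell counts at the first time (>= 0).
#' @param birth_rate,death_rate,clearance_rate Mechanistic rates in 1/h (>= 0).
#' @param times Strictly increasing time vector in hours.
#' @return A `trajectory` with observables `Live` and `Dead`.
#' @export
simulate_live_dead <- function(initial_live, initial_dead, birth_rate,
                               death_rate, clearance_rate, times) {
  check_times(times)
  check_nonneg_scalar(initial_live, "initial_live")
  check_nonneg_scalar(initial_dead, "initial_dead")
  check_nonneg_scalar(birth_rate, "birth_rate")
  check_nonneg_scalar(death_rate, "death_rate")
  check_nonneg_scalar(clearance_rate, "clearance_rate")
  core_live_dead(initial_live, initial_dead, birth_rate, death_rate,
                 clearance_rate, times)
}

#' Logistic birth-death-clearance trajectory
#'
#' Numerically integrates
#' dL/dt = b (1 - L/L_cap) L - d L, dD/dt = d L - c D
#' with an adaptive-step solver (relative tolerance 1e-8, absolute
#' tolerance 1e-6 cells).
#'
#' @inheritParams simulate_live_dead
#' @param L_cap Live-cell carrying capacity in cells (> 0).
#' @return A `trajectory` with observables `Live` and `Dead`.
#' @export
simulate_live_dead_logistic <- function(initial_live, initial_dead,
                                        birth_rate, death_rate,
                                        clearance_rate, L_cap, times) {
  check_times(times)
  check_nonneg_scalar(initial_live, "initial_live")
  check_nonneg_scalar(initial_dead, "initial_dead")
  check_nonneg_scalar(birth_rate, "birth_rate")
  check_nonneg_scalar(death_rate, "death_rate")
  check_nonneg_scalar(clearance_rate, "clearance_rate")
  if (!is.numeric(L_cap) || length(L_cap) != 1L || is.na(L_cap) || L_cap <= 0) {
    stop_invalid_input("`L_cap` must be > 0")
  }
  core_live_dead_logistic(initial_live, initial_dead, birth_rate,
                          death_rate, clearance_rate, L_cap, times)
}

#' Population doubling time
#'
#' ln(2) divided by the net growth rate; the time for an exponentially
#' growing population to double.
#'
#' @param growth_rate Net growth rate in 1/h (> 0).
#' @return Doubling time in hours.
#' @export
#' @examples
#' doubling_time(0.0354) # about 19.6 h
doubling_time <- function(growth_rate) {
  if (!is.numeric(growth_rate) || length(growth_rate) != 1L ||
      is.na(growth_rate) || growth_rate <= 0) {
    stop_cellpopfit("undefined_doubling",
                    "doubling time is undefined for growth_rate <= 0")
  }
  log(2) / growth_rate
}

parameter_units <- c(
  growth_rate = "1/h", birth_rate = "1/h", death_rate = "1/h",
  clearance_rate = "1/h", L_cap = "cells", T_cap = "cells",
  initial_live = "cells", initial_dead = "cells", initial_total = "cells"
)

model_simulator <- function(name) {
  switch(name,
    live = function(p, times)
      core_exponential(p[["initial_live"]], p[["growth_rate"]], times,
                       "Live"),
    live_logistic = function(p, times)
      core_logistic(p[["initial_live"]], p[["growth_rate"]],
                    p[["L_cap"]], times, "Live"),
    live_dead = function(p, times)
      core_live_dead(p[["initial_live"]], p[["initial_dead"]],
                     p[["birth_rate"]], p[["death_rate"]],
                     p[["clearance_rate"]], times),
    live_dead_logistic = function(p, times)
      core_live_dead_logistic(p[["initial_live"]], p[["initial_dead"]],
                              p[["birth_rate"]], p[["death_rate"]],
                              p[["clearance_rate"]], p[["L_cap"]], times),
    total = function(p, times)
      core_exponential(p[["initial_total"]], p[["growth_rate"]], times,
                       "Total"),
    total_logistic = function(p, times)
      core_logistic(p[["initial_total"]], p[["growth_rate"]],
                    p[["T_cap"]], times, "Total"),
    stop_invalid_input(sprintf("unknown model '%s'", name))
  )
}

new_model_spec <- function(name, observables, parameter_names, description,
                           has_closed_form) {
  structure(list(
    name = name,
    observables = observables,
    parameter_names = parameter_names,
    n_parameters = length(parameter_names),
    description = description,
    has_closed_form = has_closed_form,
    simulate = model_simulator(name)
  ), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec '%s': %d parameters (%s); observables: %s>\n",
              x$name, x$n_parameters,
              paste(x$parameter_names, collapse = ", "),
              paste(x$observables, collapse = ", ")))
  invisible(x)
}

#' Registry of the supported growth models
#'
#' Returns the six canonical models with their fitted parameters
#' (initial conditions are fitted parameters, initialised at the first
#' observation) and the observables their equations produce.
#'
#' @return A named list of `model_spec` objects: `live`, `live_logistic`,
#'   `live_dead`, `live_dead_logistic`, `total`, `total_logistic`.
#' @export
model_registry <- function() {
  specs <- list(
    new_model_spec(
      "live", "Live", c("growth_rate", "initial_live"),
      paste("Exponential growth of the live cell population: the culture",
            "grows (or shrinks) at a constant per-cell net rate, the",
            "difference between cell birth and death. Appropriate while",
            "nutrients are plentiful and the culture is far from confluence."),
      TRUE),
    new_model_spec(
      "live_logistic", "Live", c("growth_rate", "L_cap", "initial_live"),
      paste("Logistic growth of the live cell population: growth slows as",
            "the culture approaches a carrying capacity, e.g. from substrate",
            "depletion or confluence."),
      TRUE),
    new_model_spec(
      "live_dead", c("Live", "Dead"),
      c("birth_rate", "death_rate", "clearance_rate",
        "initial_live", "initial_dead"),
      paste("Birth-death-clearance model: live cells divide at the birth",
            "rate and die at the death rate; dead cells accumulate and are",
            "cleared (degrade or stop being recognised by cell detection)",
            "at the clearance rate. Decouples cytostatic from cytotoxic",
            "effects."),
      TRUE),
    new_model_spec(
      "live_dead_logistic", c("Live", "Dead"),
      c("birth_rate", "death_rate", "clearance_rate", "L_cap",
        "initial_live", "initial_dead"),
      paste("Birth-death-clearance model with logistic suppression of cell",
            "birth as the live population approaches its carrying capacity."),
      FALSE),
    new_model_spec(
      "total", "Total", c("growth_rate", "initial_total"),
      paste("Exponential growth of the combined live plus dead cell count",
            "at a constant net rate."),
      TRUE),
    new_model_spec(
      "total_logistic", "Total", c("growth_rate", "T_cap", "initial_total"),
      paste("Logistic growth of the combined live plus dead cell count",
            "towards a total-population carrying capacity."),
      TRUE)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

model_equation_latex <- function(name) {
  switch(name,
    live = "\\frac{d[\\mathrm{Live}]}{dt} = r\\,[\\mathrm{Live}]",
    live_logistic = "\\frac{d[\\mathrm{Live}]}{dt} = r\\left(1 - \\frac{[\\mathrm{Live}]}{L_{cap}}\\right)[\\mathrm{Live}]",
    live_dead = "\\frac{d[\\mathrm{Live}]}{dt} = (b - d)[\\mathrm{Live}],\\quad \\frac{d[\\mathrm{Dead}]}{dt} = d\\,[\\mathrm{Live}] - c\\,[\\mathrm{Dead}]",
    live_dead_logistic = "\\frac{d[\\mathrm{Live}]}{dt} = b\\left(1 - \\frac{[\\mathrm{Live}]}{L_{cap}}\\right)[\\mathrm{Live}] - d\\,[\\mathrm{Live}],\\quad \\frac{d[\\mathrm{Dead}]}{dt} = d\\,[\\mathrm{Live}] - c\\,[\\mathrm{Dead}]",
    total = "\\frac{d[\\mathrm{Total}]}{dt} = r\\,[\\mathrm{Total}]",
    total_logistic = "\\frac{d[\\mathrm{Total}]}{dt} = r\\left(1 - \\frac{[\\mathrm{Total}]}{T_{cap}}\\right)[\\mathrm{Total}]",
    ""
  )
}
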