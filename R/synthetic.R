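# Synthetic high-content drug screen with known ground truth.
#
# Two archetypes of drug action on a birth-death-clearance culture:
#   cytostatic — suppresses the birth rate with dose (division arrest),
#   cytotoxic  — multiplies the death rate with dose (cell killing).
# Dose dependence follows a Hill curve Hill(d) = d^n / (ec50^n + d^n).
# Counts are simulated from the birth-death-clearance model and corrupted
# with multiplicative Gaussian noise (mean 1, sd = noise_cv), independently
# per well and time point, clipped at zero.

#' Describe a drug's dose-response archetype
#'
#' @param drug_name Label used in condition names.
#' @param archetype "cytostatic" (birth suppression) or "cytotoxic"
#'   (death amplification).
#' @param doses Sorted nonnegative dose grid (arbitrary concentration
#'   units); default a 5-point half-log ladder 0.1-10.
#' @param baseline_birth_rate,baseline_death_rate Untreated rates in 1/h.
#' @param max_effect For cytostatic: maximal fractional suppression of the
#'   birth rate (0-1). For cytotoxic: maximal fold-increase added to the
#'   death rate (death = baseline * (1 + max_effect * Hill)).
#' @param ec50 Dose of half-maximal effect.
#' @param hill_coefficient Hill steepness (default 1).
#' @return A `drug_response_spec`.
#' @export
drug_response_spec <- function(drug_name,
                               archetype = c("cytostatic", "cytotoxic"),
                               doses = c(0.1, 0.3, 1, 3, 10),
                               baseline_birth_rate = 0.04,
                               baseline_death_rate = 0.005,
                               max_effect = NULL,
                               ec50 = 1,
                               hill_coefficient = 1) {
  archetype <- match.arg(archetype)
  if (any(doses < 0) || is.unsorted(doses)) {
    stop_invalid_input("`doses` must be nonnegative and sorted")
  }
  check_nonneg_scalar(baseline_birth_rate, "baseline_birth_rate")
  check_nonneg_scalar(baseline_death_rate, "baseline_death_rate")
  max_effect <- max_effect %||% if (archetype == "cytostatic") 1 else 5
  if (archetype == "cytostatic" && (max_effect < 0 || max_effect > 1)) {
    stop_invalid_input("cytostatic `max_effect` must be in [0, 1]")
  }
  if (ec50 <= 0) stop_invalid_input("`ec50` must be > 0")
  structure(list(drug_name = drug_name, archetype = archetype,
                 doses = doses,
                 baseline_birth_rate = baseline_birth_rate,
                 baseline_death_rate = baseline_death_rate,
                 max_effect = max_effect, ec50 = ec50,
                 hill_coefficient = hill_coefficient),
            class = "drug_response_spec")
}

#' Screen design settings
#'
#' Defaults mirror a typical high-content screen: 5 doses x 5 biological
#' replicates of live and dead counts, wells seeded at 1000 cells and
#' imaged every 12 h over a 72 h run, with 10 % relative measurement
#' noise. The 12-hourly grid reflects how HCS platforms image wells
#' repeatedly over a run; it also keeps the five-parameter
#' birth-death-clearance model identifiable (a three-timepoint design
#' leaves one residual degree of freedom and a nearly flat
#' death/clearance ridge; see the methods vignette).
#'
#' @param n_doses,n_replicates Grid sizes (>= 1).
#' @param timepoints Measurement times in hours.
#' @param initial_live,initial_dead Seeded live cells and initial dead-cell
#'   (debris) count per well.
#' @param clearance_rate Dead-cell clearance rate in 1/h shared by all
#'   conditions.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   measurement noise (>= 0).
#' @param seed Integer seed; mandatory (the generator is fully seeded).
#' @return A `screen_design`.
#' @export
screen_design <- function(n_doses = 5, n_replicates = 5,
                          timepoints = seq(0, 72, by = 12),
                          initial_live = 1000, initial_dead = 10,
                          clearance_rate = 0.005,
                          noise_cv = 0.10, seed) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed)))) {
    stop_invalid_input("`seed` is mandatory for the screen generator")
  }
  if (n_doses < 1 || n_replicates < 1) {
    stop_invalid_input("`n_doses` and `n_replicates` must be >= 1")
  }
  check_times(timepoints, "timepoints")
  check_nonneg_scalar(noise_cv, "noise_cv")
  structure(list(n_doses = n_doses, n_replicates = n_replicates,
                 timepoints = as.numeric(timepoints),
                 initial_live = initial_live, initial_dead = initial_dead,
                 clearance_rate = clearance_rate,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "screen_design")
}

#' Birth and death rates at a given dose
#'
#' Cytostatic: birth = baseline_birth * (1 - max_effect * Hill(dose)),
#' death unchanged. Cytotoxic: death = baseline_death *
#' (1 + max_effect * Hill(dose)), birth unchanged.
#'
#' @param spec A `drug_response_spec`.
#' @param dose Nonnegative dose.
#' @return Named numeric vector `c(birth_rate, death_rate)`.
#' @export
dose_response_rates <- function(spec, dose) {
  check_nonneg_scalar(dose, "dose")
  n <- spec$hill_coefficient
  hill <- if (dose == 0) 0 else dose^n / (spec$ec50^n + dose^n)
  if (spec$archetype == "cytostatic") {
    c(birth_rate = spec$baseline_birth_rate * (1 - spec$max_effect * hill),
      death_rate = spec$baseline_death_rate)
  } else {
    c(birth_rate = spec$baseline_birth_rate,
      death_rate = spec$baseline_death_rate * (1 + spec$max_effect * hill))
  }
}

condition_label <- function(drug, dose) sprintf("%s_dose_%g", drug, dose)

#' Generate a synthetic drug screen with known truth
#'
#' For every (drug, dose) condition the birth-death-clearance model is
#' simulated at the condition's true rates, and each count is multiplied
#' by an independent N(1, noise_cv^2) factor, clipped at zero. Output is a
#' first-class `experiment_dataset` (live + dead counts) plus the
#' generating truth per condition. Fully deterministic for a fixed seed.
#'
#' @param specs List of `drug_response_spec` objects.
#' @param design A `screen_design`.
#' @return List with `dataset` (an `experiment_dataset`) and `truth`
#'   (named list of per-condition vectors: birth_rate, death_rate,
#'   clearance_rate, net_rate).
#' @export
generate_screen <- function(specs, design) {
  if (inherits(specs, "drug_response_spec")) specs <- list(specs)
  stopifnot(inherits(design, "screen_design"))
  withr::with_seed(design$seed, {
    conditions <- list()
    truth <- list()
    for (spec in specs) {
      doses <- spec$doses[seq_len(min(design$n_doses, length(spec$doses)))]
      for (dose in doses) {
        rates <- dose_response_rates(spec, dose)
        lab <- condition_label(spec$drug_name, dose)
        truth[[lab]] <- c(rates,
                          clearance_rate = design$clearance_rate,
                          net_rate = unname(rates["birth_rate"] -
                                              rates["death_rate"]))
        clean <- simulate_live_dead(
          design$initial_live, design$initial_dead,
          rates[["birth_rate"]], rates[["death_rate"]],
          design$clearance_rate, design$timepoints)
        reps <- list(Live = list(), Dead = list())
        for (k in seq_len(design$n_replicates)) {
          for (obs in c("Live", "Dead")) {
            noisy <- clean$values[[obs]] *
              stats::rnorm(length(design$timepoints), 1, design$noise_cv)
            reps[[obs]][[k]] <- new_replicate_series(
              design$timepoints, pmax(noisy, 0), paste0("rep_", k))
          }
        }
        conditions[[length(conditions) + 1L]] <- new_condition(
          lab,
          environment = list(drug = spec$drug_name, dose = dose),
          replicates = reps)
      }
    }
    dataset <- new_experiment_dataset(
      conditions,
      metadata = list(cell_line_name = "synthetic",
                      media = "simulated",
                      notes = sprintf("synthetic screen, seed %d",
                                      design$seed),
                      time_unit = "h"),
      user_info = list(name = "screen generator", contact = ""))
    list(dataset = dataset, truth = truth)
  })
}

#' Write the generating truth next to a dataset
#'
#' @param truth Truth list from [generate_screen()].
#' @param path Output CSV path (parent directories created).
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tab <- do.call(rbind, lapply(names(truth), function(lab) {
    data.frame(condition = lab,
               birth_rate = truth[[lab]][["birth_rate"]],
               death_rate = truth[[lab]][["death_rate"]],
               clearance_rate = truth[[lab]][["clearance_rate"]],
               net_rate = truth[[lab]][["net_rate"]])
  }))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a truth table written by [write_truth_table()]
#' @param path CSV path.
#' @return Named list of per-condition truth vectors.
#' @export
read_truth_table <- function(path) {
  tab <- utils::read.csv(path, fileEncoding = "UTF-8")
  out <- lapply(seq_len(nrow(tab)), function(i)
    c(birth_rate = tab$birth_rate[i], death_rate = tab$death_rate[i],
      clearance_rate = tab$clearance_rate[i], net_rate = tab$net_rate[i]))
  stats::setNames(out, tab$condition)
}

#' Score parameter recovery against the generating truth
#'
#' Mean over conditions of 100 * |fitted - true| / |true| for the birth,
#' death and net (birth - death) rates. Conditions where the true value of
#' a class is zero are excluded from that class with a warning.
#'
#' @param truth Truth list from [generate_screen()].
#' @param fits Named list (same condition keys) of converged `fit_result`
#'   objects from the birth-death-clearance model.
#' @return List with `birth`, `death`, `net` (mean absolute percent
#'   errors) and `per_condition` (data frame of the individual errors).
#' @export
recovery_report <- function(truth, fits) {
  keys <- names(truth)
  if (!setequal(keys, names(fits))) {
    stop_invalid_input("`truth` and `fits` must share the same condition keys")
  }
  if (!all(vapply(fits, `[[`, TRUE, "converged"))) {
    stop_invalid_input("all fits must have converged")
  }
  per <- do.call(rbind, lapply(keys, function(lab) {
    tr <- truth[[lab]]
    est <- fits[[lab]]$estimates
    fit_net <- est[["birth_rate"]] - est[["death_rate"]]
    data.frame(
      condition = lab,
      birth = pct_err(est[["birth_rate"]], tr[["birth_rate"]]),
      death = pct_err(est[["death_rate"]], tr[["death_rate"]]),
      net = pct_err(fit_net, tr[["net_rate"]]))
  }))
  class_mean <- function(cls) {
    v <- per[[cls]]
    if (anyNA(v)) {
      warning(sprintf(
        "%d condition(s) with true %s rate 0 excluded from the %s error",
        sum(is.na(v)), cls, cls))
    }
    mean(v, na.rm = TRUE)
  }
  list(birth = class_mean("birth"), death = class_mean("death"),
       net = class_mean("net"), per_condition = per)
}

pct_err <- function(fit, true) {
  if (true == 0) NA_real_ else 100 * abs(fit - true) / abs(true)
}

#' Fit the birth-death-clearance model to every condition of a screen
#'
#' Convenience wrapper: aggregates each condition's replicates and fits
#' the live_dead model.
#'
#' @param dataset An `experiment_dataset` with Live and Dead counts.
#' @return Named list of `fit_result` objects keyed by condition label.
#' @export
fit_screen <- function(dataset) {
  spec <- model_registry()$live_dead
  fits <- lapply(dataset$conditions, function(cond) {
    series <- suppressWarnings(aggregate_condition(cond, derive_total = FALSE))
    fit_model(spec, series)
  })
  stats::setNames(fits, vapply(dataset$conditions, `[[`, "", "label"))
}
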