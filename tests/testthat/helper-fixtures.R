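# Shared fixture builders. All synthetic: fixtures are generated in code
# at test time, never stored.

# Replicate list (as aggregate_replicates consumes) around a clean
# trajectory, with multiplicative Gaussian noise of coefficient cv.
make_noisy_replicates <- function(clean, times, n_reps = 3, cv = 0.05,
                                  seed = 1) {
  withr::with_seed(seed, {
    lapply(seq_len(n_reps), function(k) {
      list(times = times,
           counts = pmax(clean * rnorm(length(times), 1, cv), 0),
           replicate_id = paste0("rep_", k))
    })
  })
}

# Noiseless replicates (n identical copies; sd = 0 so unit weights apply).
make_clean_replicates <- function(clean, times, n_reps = 3) {
  lapply(seq_len(n_reps), function(k) {
    list(times = times, counts = clean, replicate_id = paste0("rep_", k))
  })
}

# A small live-only experiment dataset written as a CSV bundle.
write_template_bundle <- function(dir, times = c(0, 24, 48),
                                  n0 = 1000, rate = 0.03, n_reps = 3,
                                  cv = 0.03, seed = 42,
                                  label = "control") {
  clean <- n0 * exp(rate * times)
  reps <- make_noisy_replicates(clean, times, n_reps, cv, seed)
  ds <- cellpopfit:::new_experiment_dataset(
    list(cellpopfit:::new_condition(
      label, environment = list(media = "demo"),
      replicates = list(Live = lapply(reps, function(r)
        cellpopfit:::new_replicate_series(r$times, r$counts,
                                          r$replicate_id))))),
    metadata = list(cell_line_name = "demo line", media = "demo medium",
                    notes = "generated fixture", time_unit = "h"),
    user_info = list(name = "tester", contact = "tester@example.org"))
  write_dataset(ds, dir)
  ds
}

# Independent numerical oracle: integrate the model ODEs with deSolve at
# tight tolerance. Deliberately re-states the equations rather than
# calling any package simulator.
oracle_ode <- function(model, pars, times) {
  rhs <- switch(model,
    exponential = function(t, y, p) list(p$r * y),
    logistic = function(t, y, p) list(p$r * (1 - y / p$cap) * y),
    live_dead = function(t, y, p) list(c(
      (p$b - p$d) * y[1],
      p$d * y[1] - p$cl * y[2])),
    live_dead_logistic = function(t, y, p) list(c(
      p$b * (1 - y[1] / p$cap) * y[1] - p$d * y[1],
      p$d * y[1] - p$cl * y[2])))
  y0 <- if (model %in% c("exponential", "logistic")) c(N = pars$n0) else
    c(L = pars$l0, D = pars$d0)
  out <- deSolve::ode(y0, times - times[1], rhs, pars, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  out[, -1, drop = FALSE]
}

rel_diff <- function(a, b, floor = 1e-3) {
  max(abs(a - b) / pmax(abs(b), floor))
}
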