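test_that("replicate aggregation computes per-point mean and sample sd", {
  reps <- make_clean_replicates(c(100, 200), c(0, 24))
  agg <- aggregate_replicates(reps)
  expect_equal(agg$mean, c(100, 200))
  expect_equal(agg$sd, c(0, 0))
  expect_equal(agg$n_replicates, c(3L, 3L))

  reps <- list(list(times = 0, counts = 90),
               list(times = 0, counts = 100),
               list(times = 0, counts = 110))
  agg <- aggregate_replicates(reps)
  expect_equal(agg$mean, 100)
  expect_equal(agg$sd, 10)

  # single replicate: sd flagged unavailable
  agg <- aggregate_replicates(list(list(times = c(0, 5), counts = c(1, 2))))
  expect_true(all(is.na(agg$sd)))

  expect_error(aggregate_replicates(list()),
               class = "cellpopfit_invalid_input")
  expect_error(aggregate_replicates(list(
    list(times = c(0, 5), counts = c(1, 2)),
    list(times = c(0, 6), counts = c(1, 2)))),
    class = "cellpopfit_invalid_input")
})

test_that("fit-quality metrics reproduce the hand-computed examples", {
  expect_equal(compute_wsse(c(100), c(100), c(2)), 0)
  expect_equal(compute_wsse(c(100), c(90), c(2)), 0.5)
  expect_equal(compute_wsse(c(100, 200), c(110, 180), c(1, 2)), 2.0)
  expect_error(compute_wsse(1:3, 1:2, 1:3),
               class = "cellpopfit_invalid_input")

  expect_equal(compute_mape(c(50, 70), c(50, 70)), 0)
  expect_equal(compute_mape(c(100, 200), c(90, 220)), 10)
  # MAPE is scale-free
  expect_equal(compute_mape(3 * c(100, 200), 3 * c(90, 220)), 10)
  expect_warning(out <- compute_mape(c(0, 100), c(5, 110)),
                 "excluded")
  expect_equal(out, 10)

  expect_equal(compute_reduced_chi2(10, 7, 2), 2.0)
  expect_equal(compute_reduced_chi2(0, 5, 2), 0)
  expect_error(compute_reduced_chi2(1, 3, 3),
               class = "cellpopfit_dof_error")

  expect_equal(unname(compute_sem(4, matrix(0.25))), 1)
  expect_equal(unname(compute_sem(2, matrix(0))), 0)
  expect_equal(unname(compute_sem(1, diag(2))), c(1, 1))
  expect_error(compute_sem(1, matrix(-1)),
               class = "cellpopfit_numerical_error")
})

test_that("confidence intervals are symmetric with the stated multiplier", {
  ci <- confidence_interval(5, 0, 95)
  expect_equal(unname(ci), c(5, 5))
  ci <- confidence_interval(0.0354, 0.0017, 95)
  expect_equal(mean(ci), 0.0354)
  # z = 1.96 convention: 0.0354 +/- 1.96 * 0.0017 ~ [0.0321, 0.0387]
  expect_equal(unname(ci), c(0.0321, 0.0387), tolerance = 1e-3)
  expect_error(confidence_interval(1, 0.1, 100),
               class = "cellpopfit_invalid_input")
  expect_error(confidence_interval(1, 0.1, 95, method = "t"),
               class = "cellpopfit_invalid_input")
})

test_that("noiseless self-generated data is recovered exactly (each model)", {
  reg <- model_registry()
  times <- seq(0, 72, 12)
  true <- list(
    live = c(growth_rate = 0.05, initial_live = 1000),
    live_logistic = c(growth_rate = 0.08, L_cap = 2e4, initial_live = 1000),
    live_dead = c(birth_rate = 0.05, death_rate = 0.012,
                  clearance_rate = 0.02, initial_live = 1000,
                  initial_dead = 40),
    live_dead_logistic = c(birth_rate = 0.06, death_rate = 0.012,
                           clearance_rate = 0.02, L_cap = 2e4,
                           initial_live = 1000, initial_dead = 40),
    total = c(growth_rate = 0.04, initial_total = 1500),
    total_logistic = c(growth_rate = 0.07, T_cap = 3e4,
                       initial_total = 1500))
  for (name in names(true)) {
    spec <- reg[[name]]
    traj <- spec$simulate(true[[name]], times)
    series <- lapply(stats::setNames(nm = spec$observables), function(obs)
      aggregate_replicates(make_clean_replicates(traj$values[[obs]], times),
                           obs))
    fit <- suppressWarnings(fit_model(spec, series))
    expect_true(fit$converged)
    tol <- if (name == "live_dead_logistic") 1e-4 else 1e-6
    for (p in spec$parameter_names) {
      expect_lt(abs(fit$estimates[[p]] - true[[name]][[p]]) /
                  abs(true[[name]][[p]]), tol)
    }
    expect_lt(fit$wsse, 1e-10)
  }
})

test_that("two points determine the exponential model exactly", {
  series <- list(Live = aggregate_replicates(list(
    list(times = c(0, 10), counts = c(100, 200)))))
  fit <- suppressWarnings(fit_model(model_registry()$live, series))
  expect_equal(fit$estimates[["growth_rate"]], log(2) / 10,
               tolerance = 1e-12)
  expect_equal(fit$estimates[["initial_live"]], 100, tolerance = 1e-10)
  # zero degrees of freedom: no chi2 and no SEM
  expect_true(is.na(fit$reduced_chi2))
  expect_true(all(is.na(fit$sem)))
})

test_that("a model refuses fewer data points than parameters", {
  series <- list(Live = aggregate_replicates(list(
    list(times = c(0, 10), counts = c(100, 200)))))
  expect_error(suppressWarnings(
    fit_model(model_registry()$live_logistic, series)),
    class = "cellpopfit_insufficient_data")
  expect_error(fit_model(model_registry()$live_dead, series),
               class = "cellpopfit_invalid_input") # Dead series missing
})

test_that("the returned estimate is a local WSSE minimum", {
  times <- seq(0, 48, 8)
  clean <- 1000 * exp(0.04 * times)
  reps <- make_noisy_replicates(clean, times, n_reps = 4, cv = 0.08,
                                seed = 3)
  series <- list(Live = aggregate_replicates(reps))
  fit <- suppressWarnings(fit_model(model_registry()$live, series))
  sigma <- ifelse(series$Live$sd == 0, 1, series$Live$sd)
  wsse_at <- function(par) {
    sim <- simulate_exponential(par[["initial_live"]],
                                par[["growth_rate"]], times)$values$Live
    compute_wsse(series$Live$mean, sim, sigma)
  }
  w0 <- wsse_at(fit$estimates)
  expect_equal(w0, fit$wsse, tolerance = 1e-8)
  for (p in names(fit$estimates)) {
    for (fac in c(0.99, 1.01)) {
      pp <- fit$estimates
      pp[[p]] <- pp[[p]] * fac
      expect_gte(wsse_at(pp), w0)
    }
  }
})

test_that("fit metrics are invariant to reordering the time points", {
  times <- seq(0, 48, 8)
  clean <- 1000 * exp(0.04 * times)
  reps <- make_noisy_replicates(clean, times, n_reps = 4, cv = 0.08,
                                seed = 5)
  fit1 <- suppressWarnings(
    fit_model(model_registry()$live,
              list(Live = aggregate_replicates(reps))))
  ord <- withr::with_seed(6, sample(length(times)))
  reps_shuffled <- lapply(reps, function(r) {
    o <- order(r$times[ord])
    list(times = r$times[ord][o], counts = r$counts[ord][o],
         replicate_id = r$replicate_id)
  })
  fit2 <- suppressWarnings(
    fit_model(model_registry()$live,
              list(Live = aggregate_replicates(reps_shuffled))))
  expect_equal(fit1$wsse, fit2$wsse)
  expect_equal(fit1$mape, fit2$mape)
  expect_equal(fit1$reduced_chi2, fit2$reduced_chi2)
  expect_equal(fit1$sem, fit2$sem, tolerance = 1e-10)
})

test_that("doubling the sampling density shrinks the growth-rate SEM", {
  r <- 0.05
  dense_times <- seq(0, 48, 2)
  sparse_times <- seq(0, 48, 4)
  mk <- function(times) {
    clean <- 1000 * exp(r * times)
    suppressWarnings(fit_model(
      model_registry()$live,
      list(Live = aggregate_replicates(
        make_noisy_replicates(clean, times, n_reps = 4, cv = 0.08,
                              seed = 9)))))
  }
  expect_lt(mk(dense_times)$sem[["growth_rate"]],
            mk(sparse_times)$sem[["growth_rate"]])
})

test_that("model selection follows observables and point counts", {
  expect_setequal(names(select_models(c(Live = 7))),
                  c("live", "live_logistic"))
  expect_equal(names(select_models(c(Live = 2))), "live")
  # live+dead with 3 points each: 6 points admit the 5-parameter model
  # (with spare) and the 6-parameter one fit-only (no SEM at zero df)
  sel <- names(select_models(c(Live = 3, Dead = 3)))
  expect_true(all(c("live_dead", "live_dead_logistic") %in% sel))
  expect_true(all(c("total", "total_logistic") %in% sel))
  sel <- names(select_models(c(Live = 2, Dead = 2)))
  expect_false("live_dead" %in% sel)       # 4 points < 5 parameters
  expect_false("live_dead_logistic" %in% sel)
  expect_setequal(names(select_models(c(Total = 5))),
                  c("total", "total_logistic"))
  expect_error(select_models(c(Live = 1)),
               class = "cellpopfit_insufficient_data")
  expect_error(select_models(c(Frogs = 5)),
               class = "cellpopfit_invalid_input")
})

test_that("ranking is ascending with parsimony tie-breaks", {
  mk <- function(name, chi2, mape, npar) {
    structure(list(model_name = name, n_parameters = npar,
                   rank_scores = list(reduced_chi2 = chi2, mape = mape)),
              class = "fit_result")
  }
  fits <- list(mk("a", 2.0, 5, 2), mk("b", 1.5, 9, 3))
  expect_equal(vapply(rank_models(fits), `[[`, "", "model_name"),
               c("b", "a"))
  expect_equal(vapply(rank_models(fits, "mape"), `[[`, "", "model_name"),
               c("a", "b"))
  # tie on the metric: fewer parameters first, then name
  fits <- list(mk("z", 1, 1, 3), mk("m", 1, 1, 2), mk("k", 1, 1, 2))
  expect_equal(vapply(rank_models(fits), `[[`, "", "model_name"),
               c("k", "m", "z"))
  expect_length(rank_models(fits[1]), 1)
  # undefined metric sorts last
  fits <- list(mk("a", NA_real_, 1, 2), mk("b", 3, 2, 2))
  expect_equal(vapply(rank_models(fits), `[[`, "", "model_name"),
               c("b", "a"))
  expect_error(rank_models(list()), class = "cellpopfit_invalid_input")
})
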