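test_that("exponential closed form matches hand-computed anchors", {
  # zero rate is the identity
  tr <- simulate_exponential(1, 0, c(0, 5, 10))
  expect_equal(tr$values$Live, c(1, 1, 1))
  # a rate of 0.397/h doubles the population at its 1.75 h doubling time
  tr <- simulate_exponential(1, 0.397, c(0, 1.75))
  expect_equal(tr$values$Live[2], 2.0, tolerance = 5e-3)
  # hand evaluation: 50 * e^(0.0354*24)
  tr <- simulate_exponential(50, 0.0354, c(0, 24))
  expect_equal(tr$values$Live[2], 50 * exp(0.8496), tolerance = 1e-12)
})

test_that("exponential trajectories are monotone as the sign of the rate", {
  times <- seq(0, 50, by = 5)
  up <- simulate_exponential(10, 0.1, times)$values$Live
  down <- simulate_exponential(10, -0.1, times)$values$Live
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(down) < 0))
})

test_that("exponential rejects bad input", {
  expect_error(simulate_exponential(1, 0.1, numeric(0)),
               class = "cellpopfit_invalid_input")
  expect_error(simulate_exponential(1, 0.1, c(2, 1)),
               class = "cellpopfit_invalid_input")
  expect_error(simulate_exponential(-1, 0.1, c(0, 1)),
               class = "cellpopfit_invalid_input")
})

test_that("logistic closed form fixes its cap and reduces to exponential", {
  times <- c(0, 4, 9, 20)
  # starting at capacity is a fixed point
  tr <- simulate_logistic(500, 0.3, 500, times)
  expect_equal(tr$values$Live, rep(500, 4))
  # hand arithmetic: 1000 / (1 + 9 * exp(-ln3)) = 250
  tr <- simulate_logistic(100, log(3), 1000, c(0, 1))
  expect_equal(tr$values$Live[2], 250, tolerance = 1e-12)
  # infinite-cap limit recovers the exponential
  tr_log <- simulate_logistic(1, 0.1, 1e12, c(0, 5, 10))
  tr_exp <- simulate_exponential(1, 0.1, c(0, 5, 10))
  expect_equal(tr_log$values$Live, tr_exp$values$Live, tolerance = 1e-9)
  expect_error(simulate_logistic(10, 0.1, 0, c(0, 1)),
               class = "cellpopfit_invalid_input")
})

test_that("logistic trajectories stay within their admissible band", {
  withr::with_seed(11, {
    for (i in 1:25) {
      n0 <- runif(1, 1, 5e4)
      cap <- runif(1, 1, 5e4)
      r <- runif(1, -0.1, 0.15)
      v <- simulate_logistic(n0, r, cap, seq(0, 100, 5))$values$Live
      if (r >= 0) {
        # growing cultures are pinched between start and capacity
        expect_true(all(v >= min(n0, cap) - 1e-9 &
                          v <= max(n0, cap) + 1e-9))
      } else if (n0 <= cap) {
        # shrinking cultures decay below the start, but never below 0
        # (r < 0 above capacity is excluded: that ODE blows up in
        # finite time and is not an admissible culture)
        expect_true(all(v >= 0 & v <= max(n0, cap) + 1e-9))
      }
    }
  })
})

test_that("birth-death-clearance closed form handles its special cases", {
  times <- seq(0, 24, 4)
  # no death, no clearance: dead compartment stays put
  tr <- simulate_live_dead(100, 7, 0.05, 0, 0, times)
  expect_equal(tr$values$Dead, rep(7, length(times)))
  expect_equal(tr$values$Live, 100 * exp(0.05 * times))
  # birth = death: live constant, dead accumulates linearly
  tr <- simulate_live_dead(100, 0, 0.1, 0.1, 0, times)
  expect_equal(tr$values$Live, rep(100, length(times)))
  expect_equal(tr$values$Dead, 10 * times)
  # resonant branch b - d + c = 0: analytic limit (D0 + d L0 t) e^(-ct)
  tr <- simulate_live_dead(1000, 50, 0.01, 0.03, 0.02, times)
  expect_equal(tr$values$Dead,
               (50 + 0.03 * 1000 * times) * exp(-0.02 * times),
               tolerance = 1e-12)
  # birth-death model with d = c = 0 equals the live model
  tr <- simulate_live_dead(200, 0, 0.07, 0, 0, times)
  expect_equal(tr$values$Live,
               simulate_exponential(200, 0.07, times)$values$Live)
  expect_error(simulate_live_dead(100, 0, -0.1, 0, 0, times),
               class = "cellpopfit_invalid_input")
})

test_that("closed forms agree with an independent adaptive ODE oracle", {
  times <- seq(0, 100, length.out = 21)
  withr::with_seed(7, {
    for (i in 1:100) {
      r <- runif(1, -0.05, 0.1)
      n0 <- runif(1, 10, 1e4)
      # admissible logistic cultures only: a shrinking culture above its
      # capacity blows up in finite time
      cap <- if (r >= 0) runif(1, n0 / 2, 1e6) else runif(1, n0, 1e6)
      b <- runif(1, 0, 0.08); d <- runif(1, 0, 0.04)
      cl <- runif(1, 0, 0.05)
      l0 <- runif(1, 10, 5e3); d0 <- runif(1, 0, 500)

      expect_lt(rel_diff(
        simulate_exponential(n0, r, times)$values$Live,
        oracle_ode("exponential", list(r = r, n0 = n0), times)[, "N"]), 1e-6)
      expect_lt(rel_diff(
        simulate_logistic(n0, r, cap, times)$values$Live,
        oracle_ode("logistic", list(r = r, n0 = n0, cap = cap),
                   times)[, "N"]), 1e-6)
      tr <- simulate_live_dead(l0, d0, b, d, cl, times)
      ora <- oracle_ode("live_dead",
                        list(b = b, d = d, cl = cl, l0 = l0, d0 = d0), times)
      expect_lt(rel_diff(tr$values$Live, ora[, "L"]), 1e-6)
      expect_lt(rel_diff(tr$values$Dead, ora[, "D"], floor = 1), 1e-6)
    }
  })
})

test_that("logistic live/dead integration converges and hits its limits", {
  times <- seq(0, 72, 6)
  # death = clearance = 0 reduces to the logistic live model
  tr <- simulate_live_dead_logistic(1000, 0, 0.05, 0, 0, 2e4, times)
  expect_lt(rel_diff(tr$values$Live,
                     simulate_logistic(1000, 0.05, 2e4, times)$values$Live),
            1e-6)
  # infinite-cap limit reduces to the birth-death-clearance closed form
  tr <- simulate_live_dead_logistic(1000, 50, 0.04, 0.01, 0.005, 1e12, times)
  ref <- simulate_live_dead(1000, 50, 0.04, 0.01, 0.005, times)
  expect_lt(rel_diff(tr$values$Live, ref$values$Live), 1e-6)
  expect_lt(rel_diff(tr$values$Dead, ref$values$Dead, floor = 1), 1e-6)
  # generic parameters vs the independent tight-tolerance oracle
  tr <- simulate_live_dead_logistic(1000, 50, 0.06, 0.015, 0.01, 3e4, times)
  ora <- oracle_ode("live_dead_logistic",
                    list(b = 0.06, d = 0.015, cl = 0.01, cap = 3e4,
                         l0 = 1000, d0 = 50), times)
  expect_lt(rel_diff(tr$values$Live, ora[, "L"]), 1e-6)
  expect_lt(rel_diff(tr$values$Dead, ora[, "D"], floor = 1), 1e-6)
})

test_that("model registry lists the six models with their parameter counts", {
  reg <- model_registry()
  expect_length(reg, 6)
  expect_setequal(names(reg),
                  c("live", "live_logistic", "live_dead",
                    "live_dead_logistic", "total", "total_logistic"))
  counts <- vapply(reg, `[[`, 1L, "n_parameters")
  expect_equal(counts[["live"]], 2L)
  expect_equal(counts[["live_logistic"]], 3L)
  expect_equal(counts[["live_dead"]], 5L)
  expect_equal(counts[["live_dead_logistic"]], 6L)
  expect_equal(counts[["total"]], 2L)
  expect_equal(counts[["total_logistic"]], 3L)
  expect_equal(reg$total$observables, "Total")
  for (spec in reg) {
    expect_equal(spec$n_parameters, length(spec$parameter_names))
  }
})

test_that("doubling time follows ln(2)/rate and rejects nonpositive rates", {
  expect_equal(doubling_time(log(2)), 1.0)
  expect_equal(signif(doubling_time(0.397), 3), 1.75)
  expect_equal(doubling_time(0.0354), log(2) / 0.0354)
  expect_error(doubling_time(0), class = "cellpopfit_undefined_doubling")
  expect_error(doubling_time(-0.1), class = "cellpopfit_undefined_doubling")
})
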