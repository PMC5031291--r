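# Weighted least-squares calibration of growth models.
#
# The fitting objective is the weighted sum of squared errors
#   WSSE = sum_i (1/sigma_i) * (Data_i - Sim_i)^2 / Data_i
# minimised with the Levenberg-Marquardt algorithm. sigma_i is the
# replicate standard deviation of the i-th data point; points with
# sigma unavailable (single replicate, or zero spread) get unit weight,
# and points with Data_i = 0 are excluded (the weight is undefined there).
# Fit quality is summarised by MAPE and reduced chi-squared, and parameter
# uncertainty by SEM_i = sqrt(chi2_nu * Cov(i,i)).

#' Aggregate replicate time series into per-point means and spreads
#'
#' @param replicate_series List of replicate series for one observable;
#'   each element a list with numeric `times` and `counts` of equal length
#'   (a `replicate_series` as produced by the data reader qualifies).
#' @param observable Observable name ("Live", "Dead" or "Total").
#' @param tolerance Maximum allowed time misalignment between replicates,
#'   in hours. Replicates must share one grid; no interpolation is done.
#' @return An `aggregated_series`: data frame with columns `times`, `mean`,
#'   `sd` (NA when only one replicate) and `n_replicates`, plus an
#'   `observable` attribute.
#' @export
aggregate_replicates <- function(replicate_series, observable = "Live",
                                 tolerance = 1e-6) {
  if (!is.list(replicate_series) || length(replicate_series) == 0L) {
    stop_invalid_input("`replicate_series` must be a nonempty list")
  }
  times <- check_times(replicate_series[[1L]]$times)
  for (k in seq_along(replicate_series)) {
    rs <- replicate_series[[k]]
    check_times(rs$times, sprintf("times (replicate %d)", k))
    if (length(rs$times) != length(times) ||
        any(abs(rs$times - times) > tolerance)) {
      bad <- if (length(rs$times) == length(times)) {
        rs$times[abs(rs$times - times) > tolerance]
      } else rs$times
      stop_invalid_input(sprintf(
        "replicate %d is not on the common time grid (offending times: %s)",
        k, paste(signif(bad, 6), collapse = ", ")))
    }
    if (length(rs$counts) != length(rs$times)) {
      stop_invalid_input(sprintf(
        "replicate %d has %d counts for %d times", k,
        length(rs$counts), length(rs$times)))
    }
  }
  counts <- do.call(rbind, lapply(replicate_series, function(rs)
    as.numeric(rs$counts)))
  n <- nrow(counts)
  out <- data.frame(
    times = times,
    mean = colMeans(counts),
    sd = if (n > 1L) apply(counts, 2L, stats::sd) else NA_real_,
    n_replicates = n
  )
  structure(out, observable = observable,
            class = c("aggregated_series", "data.frame"))
}

#' Weighted sum of squared errors
#'
#' WSSE = sum (1/sigma) * (data - sim)^2 / data. This is the calibration
#' objective: points with larger replicate spread carry less weight.
#'
#' @param data,sim,sigma Equal-length numeric vectors: observed means,
#'   model predictions, and per-point standard deviations.
#' @return Nonnegative scalar; 0 iff `sim` equals `data`.
#' @export
compute_wsse <- function(data, sim, sigma) {
  if (length(data) != length(sim) || length(data) != length(sigma)) {
    stop_invalid_input("`data`, `sim` and `sigma` must have equal lengths")
  }
  if (any(data <= 0)) {
    stop_invalid_input("WSSE requires data > 0 (zero points must be excluded upstream)")
  }
  sum((1 / sigma) * (data - sim)^2 / data)
}

#' Mean absolute percentage error
#'
#' MAPE = (1/N) * sum 100 * |data - sim| / data, in percent. Points with
#' data = 0 are excluded with a warning (the ratio is undefined there).
#'
#' @param data,sim Equal-length numeric vectors.
#' @return Percentage >= 0; 0 iff the fit is perfect.
#' @export
compute_mape <- function(data, sim) {
  if (length(data) != length(sim)) {
    stop_invalid_input("`data` and `sim` must have equal lengths")
  }
  keep <- data != 0
  if (!all(keep)) {
    warning(sprintf("%d data point(s) with value 0 excluded from MAPE",
                    sum(!keep)))
  }
  if (!any(keep)) return(NA_real_)
  mean(100 * abs(data[keep] - sim[keep]) / data[keep])
}

#' Reduced chi-squared
#'
#' chi2_nu = WSSE / (n_data - n_parameters); penalises model complexity to
#' guard against overfitting.
#'
#' @param wsse Weighted sum of squared errors (>= 0).
#' @param n_data,n_parameters Number of data points and fitted parameters.
#' @return Nonnegative scalar.
#' @export
compute_reduced_chi2 <- function(wsse, n_data, n_parameters) {
  if (n_data <= n_parameters) {
    stop_cellpopfit("dof_error", sprintf(
      "reduced chi-squared undefined: %d data points for %d parameters",
      n_data, n_parameters))
  }
  wsse / (n_data - n_parameters)
}

#' Standard error of fitted parameters
#'
#' SEM_i = sqrt(chi2_nu * Cov(i,i)), where Cov is the unscaled covariance
#' of the fit (inverse of J'J for the weighted residual Jacobian J).
#'
#' @param reduced_chi2 Reduced chi-squared of the fit.
#' @param covariance Square covariance matrix over the fitted parameters
#'   (dimnames give parameter names).
#' @return Named vector of per-parameter SEMs.
#' @export
compute_sem <- function(reduced_chi2, covariance) {
  covariance <- as.matrix(covariance)
  if (nrow(covariance) != ncol(covariance)) {
    stop_invalid_input("`covariance` must be square")
  }
  d <- diag(covariance)
  if (any(d < 0)) {
    stop_numerical("negative covariance diagonal: fit is ill-conditioned")
  }
  stats::setNames(sqrt(reduced_chi2 * d),
                  rownames(covariance) %||% names(d))
}

#' Symmetric confidence interval for a fitted parameter
#'
#' estimate +/- multiplier * sem, with a normal-quantile multiplier by
#' default (1.96 for 95 %), or Student-t with `df` degrees of freedom.
#'
#' @param estimate,sem Point estimate and its standard error.
#' @param level Confidence level in percent (0 < level < 100), default 95.
#' @param method "z" (normal, default) or "t" (Student-t; requires `df`).
#' @param df Degrees of freedom for the t multiplier.
#' @return Numeric vector `c(lower, upper)`.
#' @export
confidence_interval <- function(estimate, sem, level = 95,
                                method = c("z", "t"), df = NULL) {
  method <- match.arg(method)
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 100) {
    stop_invalid_input("`level` must be a percentage strictly between 0 and 100")
  }
  if (!is.numeric(sem) || length(sem) != 1L || is.na(sem) || sem < 0) {
    stop_invalid_input("`sem` must be a single nonnegative number")
  }
  p <- 1 - (1 - level / 100) / 2
  mult <- if (method == "z") stats::qnorm(p) else {
    if (is.null(df) || df < 1) {
      stop_invalid_input("`df` required (>= 1) for the t multiplier")
    }
    stats::qt(p, df)
  }
  c(lower = estimate - mult * sem, upper = estimate + mult * sem)
}

# Deterministic, scale-aware starting values for a model given the data.
initial_guesses <- function(spec, series) {
  primary <- series[[spec$observables[[1L]]]]
  pos <- primary$mean > 0
  net0 <- if (sum(pos) >= 2L) {
    stats::coef(stats::lm(log(primary$mean[pos]) ~ primary$times[pos]))[[2L]]
  } else 0.01
  max_obs <- max(vapply(series, function(s) max(s$mean), 1))
  first_obs <- vapply(series, function(s) s$mean[1L], 1)
  g <- numeric(0)
  for (p in spec$parameter_names) {
    g[[p]] <- switch(p,
      growth_rate = net0,
      birth_rate = if (net0 >= 0) 1.1 * net0 + 1e-3 else 0.1 * abs(net0) + 1e-3,
      death_rate = if (net0 >= 0) 0.1 * net0 + 1e-3 else 1.1 * abs(net0) + 1e-3,
      clearance_rate = 0.01,
      L_cap = 2 * max_obs,
      T_cap = 2 * max_obs,
      initial_live = unname(first_obs["Live"] %|na|% first_obs[[1L]]),
      initial_dead = unname(first_obs["Dead"] %|na|% 0),
      initial_total = unname(first_obs["Total"] %|na|% first_obs[[1L]])
    )
  }
  g
}

`%|na|%` <- function(a, b) if (length(a) != 1L || is.na(a)) b else a

parameter_bounds <- function(spec, series) {
  max_obs <- max(vapply(series, function(s) max(s$mean), 1), 1)
  lower <- numeric(0); upper <- numeric(0)
  for (p in spec$parameter_names) {
    b <- switch(p,
      growth_rate = c(-10, 10),
      birth_rate = , death_rate = , clearance_rate = c(0, 10),
      L_cap = , T_cap = c(1e-6 * max_obs, 1e6 * max_obs),
      c(0, 1e6 * max_obs)  # initial populations
    )
    lower[[p]] <- b[1L]; upper[[p]] <- b[2L]
  }
  list(lower = lower, upper = upper)
}

# Forward-mode finite-difference Jacobian of the residual function.
numeric_jacobian <- function(fn, par) {
  r0 <- fn(par)
  J <- matrix(0, nrow = length(r0), ncol = length(par),
              dimnames = list(NULL, names(par)))
  for (j in seq_along(par)) {
    h <- max(abs(par[j]) * 1e-6, 1e-9)
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    J[, j] <- (fn(pp) - fn(pm)) / (2 * h)
  }
  J
}

covariance_from_jacobian <- function(J) {
  JtJ <- crossprod(J)
  cov <- tryCatch(solve(JtJ), error = function(e) NULL)
  if (is.null(cov)) {
    sv <- svd(JtJ)
    keep <- sv$d > max(sv$d) * 1e-12
    cov <- sv$v[, keep, drop = FALSE] %*%
      diag(1 / sv$d[keep], sum(keep)) %*% t(sv$u[, keep, drop = FALSE])
    dimnames(cov) <- dimnames(JtJ)
  }
  dimnames(cov) <- dimnames(JtJ)
  cov
}

#' Fit one growth model to aggregated data
#'
#' Minimises the weighted sum of squared errors over all observables the
#' model produces, using the Levenberg-Marquardt algorithm with
#' deterministic, scale-aware starting values (no random multistart:
#' identical input gives identical output). Initial conditions are fitted
#' parameters, started at the first observation.
#'
#' A model with n parameters needs at least n data points; standard errors
#' (and reduced chi-squared) are reported only with at least n + 1 points.
#'
#' @param spec A `model_spec` from [model_registry()].
#' @param series Named list of `aggregated_series`, one per observable of
#'   the model (names must cover `spec$observables`).
#' @return A `fit_result` with estimates, `sem`, `covariance`, `wsse`,
#'   `mape`, `reduced_chi2`, `n_data`, `n_parameters`, `fitted_trajectory`,
#'   `converged` and `rank_scores`.
#' @export
fit_model <- function(spec, series) {
  if (!inherits(spec, "model_spec")) {
    stop_invalid_input("`spec` must be a model_spec (see model_registry())")
  }
  missing_obs <- setdiff(spec$observables, names(series))
  if (length(missing_obs) > 0L) {
    stop_invalid_input(sprintf("model '%s' needs observable(s): %s",
                               spec$name, paste(missing_obs, collapse = ", ")))
  }
  series <- series[spec$observables]

  # Assemble the weighted data, excluding zero-valued points (weight
  # undefined) and flooring sigma to 1 where spread is unavailable.
  datasets <- lapply(spec$observables, function(obs) {
    s <- series[[obs]]
    sigma <- s$sd
    floored <- is.na(sigma) | sigma == 0
    if (any(floored)) {
      warning(sprintf(
        "%s: %d point(s) without replicate spread given unit weight",
        obs, sum(floored)))
      sigma[floored] <- 1
    }
    keep <- s$mean > 0
    if (!all(keep)) {
      warning(sprintf("%s: %d zero-count point(s) excluded from the fit",
                      obs, sum(!keep)))
    }
    list(obs = obs, times = s$times, data = s$mean[keep],
         sigma = sigma[keep], keep = keep)
  })
  names(datasets) <- spec$observables

  n_data <- sum(vapply(datasets, function(d) length(d$data), 1L))
  if (n_data < spec$n_parameters) {
    stop_insufficient_data(sprintf(
      "model '%s' needs at least %d data points, got %d",
      spec$name, spec$n_parameters, n_data))
  }

  # All observables of one model share the measurement grid by
  # construction, but support distinct grids via a union grid.
  grid <- sort(unique(unlist(lapply(datasets, `[[`, "times"))))
  idx <- lapply(datasets, function(d) match(d$times, grid))

  residual_fn <- function(par) {
    names(par) <- spec$parameter_names
    traj <- spec$simulate(par, grid)
    unlist(lapply(datasets, function(d) {
      sim <- traj$values[[d$obs]][idx[[d$obs]]][d$keep]
      (d$data - sim) / sqrt(d$sigma * d$data)
    }), use.names = FALSE)
  }

  start <- initial_guesses(spec, series)
  bounds <- parameter_bounds(spec, series)
  start <- pmin(pmax(start, bounds$lower), bounds$upper)

  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, lower = bounds$lower, upper = bounds$upper,
      fn = residual_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = 1000, ftol = 1e-15, ptol = 1e-15, gtol = 0)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(new_fit_result(spec, estimates = start, converged = FALSE,
                          message = conditionMessage(fit),
                          n_data = n_data, grid = grid))
  }

  est <- stats::setNames(as.numeric(fit$par), spec$parameter_names)
  converged <- fit$info %in% c(1L, 2L, 3L, 4L)
  resid <- residual_fn(est)
  wsse <- sum(resid^2)

  # Fit-quality metrics over all observables combined.
  traj <- spec$simulate(est, grid)
  all_data <- unlist(lapply(datasets, `[[`, "data"), use.names = FALSE)
  all_sim <- unlist(lapply(datasets, function(d)
    traj$values[[d$obs]][idx[[d$obs]]][d$keep]), use.names = FALSE)
  mape <- compute_mape(all_data, all_sim)

  J <- numeric_jacobian(residual_fn, est)
  covariance <- covariance_from_jacobian(J)

  if (n_data > spec$n_parameters) {
    chi2 <- compute_reduced_chi2(wsse, n_data, spec$n_parameters)
    sem <- tryCatch(compute_sem(chi2, covariance),
                    error = function(e) stats::setNames(
                      rep(NA_real_, spec$n_parameters), spec$parameter_names))
  } else {
    chi2 <- NA_real_
    sem <- stats::setNames(rep(NA_real_, spec$n_parameters),
                           spec$parameter_names)
  }

  new_fit_result(spec, estimates = est, sem = sem, covariance = covariance,
                 wsse = wsse, mape = mape, reduced_chi2 = chi2,
                 n_data = n_data, fitted_trajectory = traj,
                 converged = converged, message = fit$message, grid = grid)
}

new_fit_result <- function(spec, estimates, sem = NULL, covariance = NULL,
                           wsse = NA_real_, mape = NA_real_,
                           reduced_chi2 = NA_real_, n_data = NA_integer_,
                           fitted_trajectory = NULL, converged = FALSE,
                           message = "", grid = NULL) {
  structure(list(
    model_name = spec$name,
    estimates = estimates,
    units = parameter_units[spec$parameter_names],
    sem = sem %||% stats::setNames(rep(NA_real_, spec$n_parameters),
                                   spec$parameter_names),
    covariance = covariance,
    wsse = wsse,
    mape = mape,
    reduced_chi2 = reduced_chi2,
    n_data = n_data,
    n_parameters = spec$n_parameters,
    fitted_trajectory = fitted_trajectory,
    converged = converged,
    message = message,
    rank_scores = list(mape = mape, reduced_chi2 = reduced_chi2)
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result '%s'%s: n_data=%d, WSSE=%.4g, MAPE=%.3g%%, chi2_nu=%s>\n",
              x$model_name, if (x$converged) "" else " (NOT converged)",
              x$n_data, x$wsse, x$mape,
              if (is.na(x$reduced_chi2)) "NA" else
                sprintf("%.4g", x$reduced_chi2)))
  tab <- data.frame(estimate = x$estimates, sem = x$sem, unit = x$units)
  print(tab)
  invisible(x)
}

#' Select the models applicable to a condition's data
#'
#' Model choice is driven by which observables are present and how many
#' time points each carries: a model with n parameters needs at least n
#' points. Without dead-cell (viability) data the birth-death models are
#' omitted; with both live and dead counts, total-count models are fitted
#' on the summed series.
#'
#' @param observable_points Named integer vector of data-point counts per
#'   observable present, e.g. `c(Live = 7)` or `c(Live = 3, Dead = 3)`.
#' @return Named list of applicable `model_spec` objects.
#' @export
select_models <- function(observable_points) {
  if (is.null(names(observable_points)) ||
      !all(names(observable_points) %in% c("Live", "Dead", "Total"))) {
    stop_invalid_input(
      "`observable_points` must be named with Live/Dead/Total")
  }
  pts <- observable_points[observable_points >= 2L]
  if (length(pts) == 0L) {
    stop_insufficient_data(
      "no observable has the 2 data points needed to fit any model")
  }
  registry <- model_registry()
  chosen <- character(0)
  if ("Live" %in% names(pts)) {
    if (pts[["Live"]] >= 2L) chosen <- c(chosen, "live")
    if (pts[["Live"]] >= 3L) chosen <- c(chosen, "live_logistic")
  }
  has_live_dead <- all(c("Live", "Dead") %in% names(pts))
  if (has_live_dead) {
    both <- pts[["Live"]] + pts[["Dead"]]
    if (both >= registry$live_dead$n_parameters) {
      chosen <- c(chosen, "live_dead")
    }
    if (both >= registry$live_dead_logistic$n_parameters) {
      chosen <- c(chosen, "live_dead_logistic")
    }
  }
  total_pts <- if ("Total" %in% names(pts)) pts[["Total"]] else if
    (has_live_dead) min(pts[["Live"]], pts[["Dead"]]) else 0L
  if (total_pts >= 2L) chosen <- c(chosen, "total")
  if (total_pts >= 3L) chosen <- c(chosen, "total_logistic")
  registry[chosen]
}

#' Rank fitted models by quality of fit
#'
#' Ascending by the chosen metric (lower is better); ties break towards
#' fewer parameters, then lexicographic model name. Fits with an undefined
#' metric (e.g. reduced chi-squared at zero degrees of freedom) sort last.
#'
#' @param fits List of `fit_result` objects.
#' @param metric "reduced_chi2" (default) or "mape".
#' @return The input list, reordered.
#' @export
rank_models <- function(fits, metric = c("reduced_chi2", "mape")) {
  metric <- match.arg(metric)
  if (length(fits) == 0L) stop_invalid_input("`fits` must be nonempty")
  score <- vapply(fits, function(f) as.numeric(f$rank_scores[[metric]]), 1)
  npar <- vapply(fits, function(f) as.numeric(f$n_parameters), 1)
  nm <- vapply(fits, `[[`, "", "model_name")
  fits[order(is.na(score), score, npar, nm)]
}
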