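#' Mean and variance of the birth-death process (moment ODEs)
#'
#' Integrates the moment (diffusion-approximation) ODE system of the
#' stochastic logistic birth-death process,
#' \deqn{dm/dt = B(m) - D(m), \qquad
#'   dV/dt = 2 V \{B'(m) - D'(m)\} + B(m) + D(m),}
#' with `B(n) = theta1 n (1 - theta2 n / N)` and `D(n) = theta3 n`, from the
#' known initial condition `m(0) = n0`, `V(0) = 0`. The mean equation
#' carries no variance feedback, so `m(t)` coincides with the deterministic
#' logistic solution. Integration is fixed-step classical RK4 (non-stiff
#' system: the state relaxes on the 1/r timescale).
#'
#' @param params a [bdp_params()] object.
#' @param n0 initial abundance.
#' @param times output times, days, increasing, >= 0.
#' @param dt RK4 step, days.
#' @return A data frame with columns `time`, `mean`, `var`.
#' @export
moment_odes <- function(params, n0, times, dt = 0.01) {
  stopifnot(inherits(params, "bdp_params"), n0 >= 0,
            is.numeric(times), all(times >= 0), !is.unsorted(times),
            dt > 0)
  mp <- moment_path_cpp(params$theta1, params$theta2, params$theta3,
                        params$N, n0, times, dt)
  data.frame(time = times, mean = mp[, 1], var = mp[, 2])
}

#' Likelihood-family specification
#'
#' Identifies one of the package's likelihood families and the scope it is
#' applied at. Families: `"PHEN"` (phenomenological: deterministic logistic
#' mean, iid Gaussian error with free standard deviation), `"DEMOG"`
#' (demographic: Gaussian with moment-ODE mean and variance, no sampling
#' error) and `"DEMOG_SAMP"` (demographic plus the Poisson sampling-variance
#' correction). Scopes: `"single_temperature"` (per-temperature fits used by
#' the indirect estimators) and `"direct"` (joint multi-temperature fits
#' with activation energy as an explicit parameter; `two_ea` switches to
#' separate activation energies for growth rate and carrying capacity).
#'
#' @param family one of `"PHEN"`, `"DEMOG"`, `"DEMOG_SAMP"`.
#' @param scope one of `"single_temperature"`, `"direct"`.
#' @param two_ea logical; two activation energies (direct scope only).
#' @return An object of class `likelihood_spec`.
#' @export
likelihood_spec <- function(family = c("PHEN", "DEMOG", "DEMOG_SAMP"),
                            scope = c("single_temperature", "direct"),
                            two_ea = FALSE) {
  family <- match.arg(family)
  scope <- match.arg(scope)
  if (two_ea && scope != "direct") {
    stop("two_ea applies only to the direct scope")
  }
  if (scope == "direct" && family == "PHEN") {
    stop("the direct scope uses the demographic families only")
  }
  structure(list(family = family, scope = scope, two_ea = two_ea),
            class = "likelihood_spec")
}

# Drop the t = 0 observation (V(0) = 0 with n0 known; by default it is not
# part of the likelihood) and validate a series data frame.
prep_series <- function(series, include_t0 = FALSE) {
  stopifnot(is.data.frame(series),
            all(c("time", "count", "frac_samp") %in% names(series)))
  s <- series[order(series$time), , drop = FALSE]
  if (!include_t0) s <- s[s$time > 0, , drop = FALSE]
  s
}

#' Phenomenological log-likelihood
#'
#' Gaussian iid log-density of observed counts around the deterministic
#' expectation `frac_samp * logistic_mean(t)`, with a free error standard
#' deviation `sigma` on the count scale. This is the classic
#' least-squares-style fit that ignores both demographic stochasticity and
#' the structure of the sampling error.
#'
#' @param r,K logistic growth rate (1/day) and carrying capacity.
#' @param sigma error standard deviation on the count scale (> 0).
#' @param series data frame with columns `time`, `count`, `frac_samp`.
#' @param n0 known initial abundance.
#' @param include_t0 include the `t = 0` observation? Default drops it.
#' @return Scalar log-likelihood.
#' @export
loglik_phen <- function(r, K, sigma, series, n0, include_t0 = FALSE) {
  stopifnot(sigma > 0, K > 0, n0 >= 0)
  s <- prep_series(series, include_t0)
  mu <- s$frac_samp * logistic_mean(s$time, logistic_params(r, K, n0))
  sum(dnorm(s$count, mean = mu, sd = sigma, log = TRUE))
}

#' Demographic (moment-based) log-likelihoods
#'
#' `loglik_demog()` is the Gaussian log-density of observed counts with
#' mean `f * m(t)` and variance `f^2 * V(t)`, where `(m, V)` come from the
#' moment ODEs ([moment_odes()]) and `f` is the per-observation sampling
#' fraction — demographic stochasticity without sampling error.
#' `loglik_corrected()` adds the Poisson sampling variance of the
#' observation layer, giving observation variance `f^2 V(t) + f m(t)`.
#' Variances are floored at `var_floor` to avoid degeneracy where
#' `V(t) = 0`.
#'
#' @param params a [bdp_params()] object.
#' @param series data frame with columns `time`, `count`, `frac_samp`.
#' @param n0 known initial abundance.
#' @param correct add the Poisson sampling variance term?
#' @param var_floor lower bound for the observation variance.
#' @param dt moment-ODE integration step, days.
#' @param include_t0 include the `t = 0` observation? Default drops it.
#' @return Scalar log-likelihood.
#' @export
loglik_demog <- function(params, series, n0, correct = FALSE,
                         var_floor = 1e-6, dt = 0.01, include_t0 = FALSE) {
  s <- prep_series(series, include_t0)
  mp <- moment_odes(params, n0, s$time, dt = dt)
  mu <- s$frac_samp * mp$mean
  v <- s$frac_samp^2 * mp$var
  if (correct) v <- v + s$frac_samp * mp$mean
  v <- pmax(v, var_floor)
  sum(dnorm(s$count, mean = mu, sd = sqrt(v), log = TRUE))
}

#' @rdname loglik_demog
#' @export
loglik_corrected <- function(params, series, n0, var_floor = 1e-6,
                             dt = 0.01, include_t0 = FALSE) {
  loglik_demog(params, series, n0, correct = TRUE, var_floor = var_floor,
               dt = dt, include_t0 = include_t0)
}

# Precomputed observation layout for fast repeated likelihood evaluation
# (optimisers/samplers): union time grid plus flattened per-observation
# indices, counts and sampling fractions.
group_layout <- function(series_list, include_t0 = FALSE) {
  series_list <- lapply(series_list, prep_series, include_t0 = include_t0)
  utimes <- sort(unique(unlist(lapply(series_list, `[[`, "time"))))
  idx <- unlist(lapply(series_list, function(s) match(s$time, utimes)))
  list(utimes = utimes, idx = idx,
       count = unlist(lapply(series_list, `[[`, "count")),
       frac = unlist(lapply(series_list, `[[`, "frac_samp")))
}

demog_loglik_layout <- function(params, layout, n0, correct,
                                var_floor = 1e-6, dt = 0.01) {
  if (!length(layout$utimes)) return(0)
  mp <- moment_path_cpp(params$theta1, params$theta2, params$theta3,
                        params$N, n0, layout$utimes, dt)
  m <- mp[layout$idx, 1]
  mu <- layout$frac * m
  v <- layout$frac^2 * mp[layout$idx, 2]
  if (correct) v <- v + mu
  v[v < var_floor] <- var_floor
  -0.5 * sum(log(2 * pi * v) + (layout$count - mu)^2 / v)
}

# Pooled demographic log-likelihood for several series sharing one set of
# birth-death parameters (replicates at one temperature). Integrates the
# moment ODEs once on the union of observation times.
demog_loglik_group <- function(params, series_list, n0, correct,
                               var_floor = 1e-6, dt = 0.01,
                               include_t0 = FALSE) {
  layout <- group_layout(series_list, include_t0 = include_t0)
  demog_loglik_layout(params, layout, n0, correct, var_floor, dt)
}

# Pooled phenomenological log-likelihood over replicate series.
phen_loglik_group <- function(r, K, sigma, series_list, n0,
                              include_t0 = FALSE) {
  sum(vapply(series_list, function(s) {
    loglik_phen(r, K, sigma, s, n0, include_t0 = include_t0)
  }, numeric(1)))
}

#' Direct multi-temperature log-likelihood
#'
#' Sum over all observed temperatures of the demographic log-likelihood
#' (with or without sampling-error correction), with the birth-death
#' parameters at every temperature tied to one [arrhenius_model()] via
#' [scale_model()]. This is the likelihood underlying the direct
#' activation-energy estimators; with a two-component `e_a` in the model it
#' becomes the two-activation-energy variant used for real data in which
#' growth rate and carrying capacity scale independently.
#'
#' @param model an [arrhenius_model()].
#' @param dataset an `ea_dataset` (or list with conforming `data`).
#' @param corrected add the Poisson sampling variance term?
#' @param n0 initial abundance; defaults to the dataset design's `n0`.
#' @param var_floor,dt,include_t0 see [loglik_demog()].
#' @return Scalar log-likelihood.
#' @export
direct_loglik <- function(model, dataset, corrected = FALSE, n0 = NULL,
                          var_floor = 1e-6, dt = 0.01, include_t0 = FALSE) {
  stopifnot(inherits(model, "arrhenius_model"))
  if (is.null(n0)) {
    if (is.null(dataset$design)) {
      stop("n0 must be supplied when the dataset carries no design")
    }
    n0 <- dataset$design$n0
  }
  series <- dataset_series(dataset)
  temps <- vapply(series, function(s) s$temperature_C[1], numeric(1))
  ll <- 0
  for (tc in unique(temps)) {
    params <- scale_model(model, celsius_to_kelvin(tc))
    ll <- ll + demog_loglik_group(params, series[temps == tc], n0,
                                  correct = corrected,
                                  var_floor = var_floor, dt = dt,
                                  include_t0 = include_t0)
  }
  ll
}
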