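# Fast, non-validating bdp_params constructor for samplers/optimisers.
new_bdp_params <- function(theta1, theta2, theta3, N) {
  structure(list(theta1 = theta1, theta2 = theta2, theta3 = theta3, N = N),
            class = "bdp_params")
}

#' MCMC chain configuration
#'
#' Defaults follow the package's standard setup: 20,000 random-walk
#' Metropolis iterations, the first half discarded as burn-in, thinned to
#' 1,000 retained draws, with the proposal scale adapted during burn-in
#' toward a 20-40\% acceptance rate. All values are configurable; reduced
#' settings are appropriate for large factorial sweeps.
#'
#' @param n_iter total iterations.
#' @param burn_frac fraction discarded as burn-in.
#' @param n_keep retained (thinned) post-burn-in draws.
#' @param adapt_interval iterations between proposal-scale adaptations
#'   (burn-in only).
#' @param target_accept target acceptance rate.
#' @param init_step initial per-component proposal standard deviation.
#' @return A list of class `chain_control`.
#' @export
chain_control <- function(n_iter = 20000, burn_frac = 0.5, n_keep = 1000,
                          adapt_interval = 50, target_accept = 0.3,
                          init_step = 0.15) {
  stopifnot(n_iter >= 20, burn_frac > 0, burn_frac < 1, n_keep >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_frac = burn_frac,
                 n_keep = as.integer(n_keep),
                 adapt_interval = as.integer(adapt_interval),
                 target_accept = target_accept, init_step = init_step),
            class = "chain_control")
}

# Random-walk Metropolis. The chain starts at the posterior mode (short
# Nelder-Mead ascent from `init`) and the proposal is adapted during
# burn-in: a global scale tuned to the target acceptance rate plus, once
# enough burn-in history exists, a Haario-style empirical-covariance shape
# (scaled by 2.38/sqrt(d)) so that correlated, unevenly scaled posteriors
# mix well. Returns retained draws and the post-burn-in acceptance rate.
metropolis <- function(logpost, init, chain) {
  d <- length(init)
  opt <- tryCatch(
    optim(init, function(q) {
      v <- logpost(q)
      if (is.finite(v)) -v else 1e12
    }, method = "Nelder-Mead", control = list(maxit = 400)),
    error = function(e) NULL
  )
  p <- if (!is.null(opt) && is.finite(opt$value) && opt$value < 1e12) {
    opt$par
  } else init
  lp <- logpost(p)
  if (!is.finite(lp)) {
    p <- init
    lp <- logpost(p)
  }
  if (!is.finite(lp)) {
    return(list(status = "failed",
                reason = "log-posterior not finite at the initial value"))
  }
  n_iter <- chain$n_iter
  n_burn <- floor(chain$burn_frac * n_iter)
  base <- diag(chain$init_step, d)   # proposal shape (lower-triangular)
  lambda <- 1                        # global proposal scale
  adapted_shape <- FALSE
  burn_hist <- matrix(NA_real_, n_burn, d)
  keep_at <- unique(round(seq(n_burn + 1, n_iter,
                              length.out = min(chain$n_keep,
                                               n_iter - n_burn))))
  draws <- matrix(NA_real_, length(keep_at), d)
  ki <- 1L
  acc_win <- 0L
  acc_post <- 0L
  for (it in seq_len(n_iter)) {
    prop <- p + lambda * as.numeric(base %*% rnorm(d))
    lpp <- logpost(prop)
    if (is.finite(lpp) && log(runif(1)) < lpp - lp) {
      p <- prop
      lp <- lpp
      acc_win <- acc_win + 1L
      if (it > n_burn) acc_post <- acc_post + 1L
    }
    if (it <= n_burn) {
      burn_hist[it, ] <- p
      if (it %% chain$adapt_interval == 0L) {
        rate <- acc_win / chain$adapt_interval
        acc_win <- 0L
        lambda <- min(max(lambda * exp(rate - chain$target_accept),
                          1e-4), 100)
        if (it >= max(200L, 4L * chain$adapt_interval)) {
          S <- stats::cov(burn_hist[(it %/% 2L):it, , drop = FALSE])
          ch <- tryCatch(chol(S + 1e-10 * diag(d)),
                         error = function(e) NULL)
          if (!is.null(ch) && all(is.finite(ch))) {
            if (!adapted_shape) lambda <- 1  # first switch to cov shape
            adapted_shape <- TRUE
            base <- t(ch) * (2.38 / sqrt(d))
          }
        }
      }
    }
    if (ki <= length(keep_at) && it == keep_at[ki]) {
      draws[ki, ] <- p
      ki <- ki + 1L
    }
  }
  accept_rate <- acc_post / (n_iter - n_burn)
  if (accept_rate < 0.01) {
    return(list(status = "failed",
                reason = sprintf("acceptance rate %.3f%% after adaptation",
                                 100 * accept_rate)))
  }
  list(status = "ok", draws = draws, accept_rate = accept_rate)
}

# Crude data-driven initializer for (r, K) from one or more series at a
# single temperature: K from the rescaled mean of the last two observations
# per series, r from the log-slope of the early (below K/2) growth phase.
crude_init <- function(series_list, n0) {
  nhat_all <- lapply(series_list, function(s) {
    s <- s[order(s$time), , drop = FALSE]
    data.frame(time = s$time, nhat = s$count / s$frac_samp)
  })
  K_hat <- mean(vapply(nhat_all, function(d) {
    mean(utils::tail(d$nhat, 2))
  }, numeric(1)))
  K_hat <- max(K_hat, 2 * max(n0, 1), 10)
  tt <- unlist(lapply(nhat_all, `[[`, "time"))
  nn <- unlist(lapply(nhat_all, `[[`, "nhat"))
  grow <- nn > 0 & nn <= 0.5 * K_hat & tt > 0
  r_hat <- NA_real_
  if (sum(grow) >= 2 && length(unique(tt[grow])) >= 2) {
    r_hat <- unname(coef(lm(log(nn[grow]) ~ tt[grow]))[2])
  } else if (any(grow)) {
    i <- which(grow)[1]
    r_hat <- (log(nn[i]) - log(max(n0, 1))) / tt[i]
  }
  if (!is.finite(r_hat)) r_hat <- 1
  r_hat <- min(max(r_hat, 0.05), 5)
  list(r = r_hat, K = K_hat)
}

fit_result <- function(engine, family, par, se = NULL, vcov = NULL,
                       loglik = NA_real_, status = "ok", reason = NULL,
                       draws = NULL, diagnostics = list()) {
  structure(list(engine = engine, family = family, par = par, se = se,
                 vcov = vcov, loglik = loglik, status = status,
                 reason = reason, draws = draws, diagnostics = diagnostics),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$engine, x$family, "status:", x$status, "\n")
  if (!is.null(x$reason)) cat("  reason:", x$reason, "\n")
  if (!is.null(x$par)) {
    est <- signif(x$par, 5)
    if (!is.null(x$se)) {
      cat("  ", paste(names(est), "=", est, "(se",
                      signif(x$se, 3), ")"), "\n")
    } else {
      cat("  ", paste(names(est), "=", est), "\n")
    }
  }
  invisible(x)
}

# Parameter layouts for single-temperature fits. The demographic families
# use (log r, log K, log theta3) -- a bijection of the log-thetas given N
# that keeps log r and log K as direct coordinates:
#   theta1 = r + theta3, theta2 = N r / (theta1 K).
demog_par_to_params <- function(p, N) {
  r <- exp(p[1])
  K <- exp(p[2])
  th3 <- exp(p[3])
  th1 <- r + th3
  new_bdp_params(th1, N * r / (th1 * K), th3, N)
}

single_temp_negloglik <- function(spec, series_list, n0, N, dt, var_floor,
                                  include_t0) {
  layout <- group_layout(series_list, include_t0 = include_t0)
  if (spec$family == "PHEN") {
    function(p) {
      if (any(!is.finite(p)) || any(abs(p) > 50)) return(Inf)
      mu <- layout$frac *
        logistic_mean(layout$utimes,
                      logistic_params(exp(p[1]), exp(p[2]), n0))[layout$idx]
      s2 <- exp(2 * p[3])
      0.5 * sum(log(2 * pi * s2) + (layout$count - mu)^2 / s2)
    }
  } else {
    correct <- spec$family == "DEMOG_SAMP"
    function(p) {
      if (any(!is.finite(p)) || any(abs(p) > 50)) return(Inf)
      -demog_loglik_layout(demog_par_to_params(p, N), layout, n0,
                           correct = correct, var_floor = var_floor,
                           dt = dt)
    }
  }
}

single_temp_init <- function(spec, series_list, n0) {
  ini <- crude_init(series_list, n0)
  if (spec$family == "PHEN") {
    sig <- max(1, sd(unlist(lapply(series_list, `[[`, "count"))), na.rm = TRUE)
    c(log_r = log(ini$r), log_K = log(ini$K), log_sigma = log(sig))
  } else {
    c(log_r = log(ini$r), log_K = log(ini$K), log_theta3 = log(0.5 * ini$r))
  }
}

as_series_list <- function(series) {
  if (is.data.frame(series)) list(series) else series
}

degenerate_series <- function(series_list, include_t0 = FALSE) {
  s <- lapply(series_list, prep_series, include_t0 = include_t0)
  n_obs <- sum(vapply(s, nrow, integer(1)))
  total <- sum(unlist(lapply(s, `[[`, "count")))
  n_obs < 3 || total == 0
}

#' Maximum-likelihood fit at a single temperature
#'
#' Multi-start Nelder-Mead optimisation of the chosen likelihood family on
#' log-scale parameters, with Wald standard errors from the inverse
#' numerical Hessian. Replicate series at the temperature are pooled into
#' one likelihood. A non-positive-definite Hessian yields status
#' `"NA-variance"` (point estimates retained, no standard errors) — the
#' failure mode that makes MLE-based activation-energy estimates fragile.
#'
#' @param spec a [likelihood_spec()] with scope `"single_temperature"`.
#' @param series a series data frame (columns `time`, `count`,
#'   `frac_samp`) or a list of them (replicates).
#' @param n0 known initial abundance.
#' @param N birth-saturation population size (demographic families).
#' @param n_starts number of optimisation starts (initializer plus
#'   deterministic offsets).
#' @param dt,var_floor,include_t0 see [loglik_demog()].
#' @return A `fit_result` with log-scale estimates; for all families the
#'   first two components are `log_r` and `log_K`.
#' @export
fit_mle <- function(spec, series, n0, N = 15000, n_starts = 5, dt = 0.01,
                    var_floor = 1e-6, include_t0 = FALSE) {
  stopifnot(inherits(spec, "likelihood_spec"),
            spec$scope == "single_temperature")
  series_list <- as_series_list(series)
  if (degenerate_series(series_list, include_t0)) {
    return(fit_result("MLE", spec$family, par = NULL, status = "failed",
                      reason = "degenerate data"))
  }
  # The phenomenological family profiles sigma analytically (the MLE of
  # sigma^2 is the mean squared residual), making the fit equivalent to
  # least squares and well behaved down to noiseless data.
  if (spec$family == "PHEN") {
    layout <- group_layout(series_list, include_t0 = include_t0)
    n_obs <- length(layout$count)
    nll <- function(p) {
      if (any(!is.finite(p)) || any(abs(p) > 50)) return(Inf)
      mu <- layout$frac *
        logistic_mean(layout$utimes,
                      logistic_params(exp(p[1]), exp(p[2]), n0))[layout$idx]
      s2 <- max(mean((layout$count - mu)^2), 1e-12)
      0.5 * n_obs * (log(2 * pi * s2) + 1)
    }
    init <- single_temp_init(spec, series_list, n0)[1:2]
  } else {
    nll <- single_temp_negloglik(spec, series_list, n0, N, dt, var_floor,
                                 include_t0)
    init <- single_temp_init(spec, series_list, n0)
  }
  offsets <- rbind(c(0, 0, 0), c(0.4, -0.4, 0), c(-0.4, 0.4, 0),
                   c(0.6, 0.6, 0.6), c(-0.6, -0.6, -0.6),
                   c(1, 0, -1), c(-1, 0, 1))
  offsets <- offsets[, seq_along(init), drop = FALSE]
  offsets <- offsets[seq_len(min(n_starts, nrow(offsets))), , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(offsets))) {
    start <- init + offsets[i, ]
    if (!is.finite(nll(start))) next
    opt <- tryCatch(
      optim(start, nll, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(opt) || !is.finite(opt$value)) next
    better <- is.null(best) || opt$value < best$value - 1e-9 ||
      (abs(opt$value - best$value) <= 1e-9 &&
         sum(opt$par^2) < sum(best$par^2))
    if (better) best <- opt
  }
  if (is.null(best)) {
    return(fit_result("MLE", spec$family, par = NULL, status = "failed",
                      reason = "no optimisation start converged"))
  }
  par <- setNames(best$par, names(init))
  H <- tryCatch(optimHess(best$par, nll), error = function(e) NULL)
  vc <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
  status <- "ok"
  se <- NULL
  reason <- NULL
  if (is.null(vc) || any(!is.finite(diag(vc))) || any(diag(vc) <= 0)) {
    status <- "NA-variance"
    reason <- "Hessian not positive definite"
    vc <- NULL
  } else {
    se <- setNames(sqrt(diag(vc)), names(init))
  }
  fit_result("MLE", spec$family, par = par, se = se, vcov = vc,
             loglik = -best$value, status = status, reason = reason,
             diagnostics = list(convergence = best$convergence))
}

#' Bayesian fit at a single temperature (random-walk Metropolis)
#'
#' Samples the posterior of the chosen likelihood family on log-scale
#' parameters under independent Gaussian priors centred at a crude
#' data-driven initializer with standard deviation `prior_sd` (natural-log
#' units; weakly informative and scale-free). Replicates are pooled. The
#' proposal scale adapts during burn-in toward 20-40\% acceptance;
#' Gaussianity of each retained marginal is recorded via a Shapiro-Wilk
#' statistic in `diagnostics$shapiro_p`.
#'
#' @inheritParams fit_mle
#' @param chain a [chain_control()].
#' @param prior_sd prior standard deviation, natural-log units.
#' @param prior_only if `TRUE`, sample the prior (likelihood switched
#'   off) — a sampler diagnostic.
#' @return A `fit_result` carrying retained `draws` (one column per
#'   parameter; for all families the first two are `log_r` and `log_K`).
#' @export
fit_mcmc <- function(spec, series, n0, N = 15000, chain = chain_control(),
                     prior_sd = 2, prior_only = FALSE, dt = 0.01,
                     var_floor = 1e-6, include_t0 = FALSE) {
  stopifnot(inherits(spec, "likelihood_spec"),
            spec$scope == "single_temperature",
            inherits(chain, "chain_control"))
  series_list <- as_series_list(series)
  if (degenerate_series(series_list, include_t0)) {
    return(fit_result("MCMC", spec$family, par = NULL, status = "failed",
                      reason = "degenerate data"))
  }
  nll <- single_temp_negloglik(spec, series_list, n0, N, dt, var_floor,
                               include_t0)
  init <- single_temp_init(spec, series_list, n0)
  prior_mean <- init
  logpost <- function(p) {
    lp <- sum(dnorm(p, prior_mean, prior_sd, log = TRUE))
    if (prior_only) return(lp)
    lp - nll(p)
  }
  res <- metropolis(logpost, init, chain)
  if (res$status != "ok") {
    return(fit_result("MCMC", spec$family, par = NULL, status = "failed",
                      reason = res$reason))
  }
  draws <- res$draws
  colnames(draws) <- names(init)
  par <- setNames(colMeans(draws), names(init))
  se <- setNames(apply(draws, 2, sd), names(init))
  shap <- apply(draws, 2, function(x) {
    if (sd(x) < 1e-12) return(NA_real_)
    tryCatch(shapiro.test(x)$p.value, error = function(e) NA_real_)
  })
  fit_result("MCMC", spec$family, par = par, se = se, loglik = NA_real_,
             draws = draws,
             diagnostics = list(accept_rate = res$accept_rate,
                                shapiro_p = shap))
}

#' Activation-energy estimate
#'
#' Container for an activation-energy estimate: posterior/sampling mean
#' `mean` and standard error `se` (both eV), the method that produced it,
#' the source parameter (`"r"`, `"K"` or `"joint"`), and — for indirect
#' estimates — the Arrhenius regression intercept (the temperature-
#' independent constant).
#'
#' @param mean,se estimate and its standard error, eV.
#' @param method_id method label (`"M1"`..`"M10"` or custom).
#' @param source `"r"`, `"K"` or `"joint"`.
#' @param intercept Arrhenius regression intercept (indirect methods).
#' @param details free-form list (fits, draws summaries, regression).
#' @return An object of class `ea_estimate`.
#' @export
ea_estimate <- function(mean, se, method_id = NA_character_,
                        source = c("joint", "r", "K"), intercept = NA_real_,
                        details = list()) {
  source <- match.arg(source)
  stopifnot(is.finite(mean), is.numeric(se), se >= 0)
  structure(list(mean = mean, se = se, method_id = method_id,
                 source = source, intercept = intercept, details = details),
            class = "ea_estimate")
}

#' @export
print.ea_estimate <- function(x, ...) {
  cat("<ea_estimate>", x$method_id, "(source:", x$source, ")  E_A =",
      signif(x$mean, 4), "eV  (se", signif(x$se, 3), ")\n")
  invisible(x)
}

#' Indirect activation-energy estimate via Arrhenius regression
#'
#' Regresses per-temperature estimates of `log r` (or `log K`) on the
#' inverse thermal energy `x = 1/(kB T)` by weighted least squares with
#' weights `1/se^2`. The Arrhenius model makes `log r` linear in `x` with
#' slope `-E_A` and `log K` linear with slope `+E_A`, so the activation
#' energy is minus (plus) the fitted slope for the growth-rate
#' (carrying-capacity) route. Failed per-temperature fits are dropped with
#' a warning; at least three usable temperatures are required.
#'
#' @param fits list of per-temperature `fit_result`s (from [fit_mle()] or
#'   [fit_mcmc()]).
#' @param temperatures matching temperatures, Celsius.
#' @param source which per-temperature parameter carries the temperature
#'   signal: `"r"` or `"K"`.
#' @param method_id label stored in the result.
#' @param weighted use `1/se^2` weights (unweighted least squares
#'   otherwise).
#' @return An [ea_estimate()].
#' @export
indirect_ea <- function(fits, temperatures, source = c("r", "K"),
                        method_id = NA_character_, weighted = TRUE) {
  source <- match.arg(source)
  stopifnot(length(fits) == length(temperatures))
  field <- if (source == "r") "log_r" else "log_K"
  idx <- if (source == "r") 1L else 2L
  y <- se <- rep(NA_real_, length(fits))
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    if (!inherits(f, "fit_result") || f$status != "ok") next
    y[i] <- f$par[[idx]]
    se[i] <- f$se[[idx]]
  }
  usable <- is.finite(y) & is.finite(se) & se > 0
  if (any(!usable)) {
    warning(sum(!usable), " of ", length(fits),
            " per-temperature fits unusable; excluded from the regression")
  }
  if (sum(usable) < 3) {
    stop("insufficient temperatures: need >= 3 usable per-temperature fits")
  }
  x <- 1 / (k_boltzmann() * celsius_to_kelvin(temperatures[usable]))
  w <- if (weighted) 1 / se[usable]^2 else NULL
  reg <- lm(y[usable] ~ x, weights = w)
  sl <- summary(reg)$coefficients
  slope <- sl["x", "Estimate"]
  slope_se <- sl["x", "Std. Error"]
  ea_estimate(
    mean = if (source == "r") -slope else slope,
    se = slope_se,
    method_id = method_id, source = source,
    intercept = unname(coef(reg)[1]),
    details = list(regression = reg, n_temperatures = sum(usable),
                   excluded = which(!usable))
  )
}

# Crude multi-temperature initializer for the direct model: per-temperature
# (r, K) initializers, unweighted Arrhenius regressions for starting values
# of E_A,r and E_A,K, and extrapolation of the baselines to T0.
direct_init <- function(groups, temps_C, n0, N, t0) {
  lr <- lk <- rep(NA_real_, length(groups))
  for (i in seq_along(groups)) {
    ini <- crude_init(groups[[i]], n0)
    lr[i] <- log(ini$r)
    lk[i] <- log(ini$K)
  }
  x <- 1 / (k_boltzmann() * celsius_to_kelvin(temps_C))
  x0 <- 1 / (k_boltzmann() * t0)
  fit_r <- lm(lr ~ x)
  fit_k <- lm(lk ~ x)
  ea_r <- min(max(-coef(fit_r)[[2]], 0.05), 2)
  ea_k <- min(max(coef(fit_k)[[2]], -1), 2)
  log_r0 <- coef(fit_r)[[1]] + coef(fit_r)[[2]] * x0
  log_K0 <- coef(fit_k)[[1]] + coef(fit_k)[[2]] * x0
  r0 <- exp(log_r0)
  K0 <- min(exp(log_K0), 0.9 * N)
  th3 <- 0.5 * r0
  th1 <- r0 + th3
  th2 <- N * r0 / (th1 * K0)
  list(log_th01 = log(th1), log_th02 = log(th2), log_th03 = log(th3),
       ea_r = ea_r, ea_k = ea_k)
}

#' Direct activation-energy estimate (joint multi-temperature MCMC)
#'
#' Fits all temperature series simultaneously: the birth-death baselines
#' `(theta01, theta02, theta03)` at the reference temperature and the
#' activation energy are sampled jointly by random-walk Metropolis, with
#' the per-temperature parameters tied through the Arrhenius model and the
#' likelihood summed over temperatures ([direct_loglik()]). With
#' `two_ea = TRUE` the model carries separate activation energies for
#' growth rate (`E_A,r`, log scale) and carrying capacity (`E_A,K`, natural
#' scale, since values near or below zero are plausible for real data).
#'
#' Priors: independent Gaussians (sd `prior_sd` log-units) on the log
#' baselines and log `E_A` (natural scale for `E_A,K`), centred at a crude
#' data-driven initializer.
#'
#' @param dataset an `ea_dataset` spanning at least two temperatures.
#' @param corrected include the Poisson sampling-variance correction?
#' @param two_ea separate activation energies for r and K?
#' @param chain a [chain_control()].
#' @param n0 initial abundance; defaults to the dataset design.
#' @param N birth-saturation population size; defaults to the dataset's
#'   simulation truth, else 15000.
#' @param t0 reference temperature, Kelvin.
#' @param prior_sd prior standard deviation.
#' @param dt,var_floor,include_t0 see [loglik_demog()].
#' @return An [ea_estimate()] (source `"joint"`); for `two_ea = TRUE` a
#'   list with components `r` and `K`, each an [ea_estimate()]. The
#'   underlying `fit_result` is attached as `details$fit` (or `$fit`).
#' @export
direct_ea <- function(dataset, corrected = FALSE, two_ea = FALSE,
                      chain = chain_control(), n0 = NULL, N = NULL,
                      t0 = t_ref(), prior_sd = 2, dt = 0.01,
                      var_floor = 1e-6, include_t0 = FALSE) {
  if (is.null(n0)) {
    if (is.null(dataset$design)) stop("n0 required without a design")
    n0 <- dataset$design$n0
  }
  if (is.null(N)) N <- if (!is.null(dataset$model)) dataset$model$N else 15000
  series <- dataset_series(dataset)
  temps <- vapply(series, function(s) s$temperature_C[1], numeric(1))
  utemps <- sort(unique(temps))
  if (length(utemps) < 2) {
    stop("direct estimation requires a dataset spanning >= 2 temperatures")
  }
  groups <- lapply(utemps, function(tc) series[temps == tc])
  temps_K <- celsius_to_kelvin(utemps)
  ini <- direct_init(groups, utemps, n0, N, t0)

  if (two_ea) {
    init <- c(log_th01 = ini$log_th01, log_th02 = ini$log_th02,
              log_th03 = ini$log_th03, log_ea_r = log(ini$ea_r),
              ea_k = ini$ea_k)
  } else {
    init <- c(log_th01 = ini$log_th01, log_th02 = ini$log_th02,
              log_th03 = ini$log_th03, log_ea = log(ini$ea_r))
  }
  prior_mean <- init
  kB <- k_boltzmann()

  layouts <- lapply(groups, group_layout, include_t0 = include_t0)
  loglik_at <- function(th01, th02, th03, ea3) {
    # ea3: per-theta activation energies (theta1, theta2, theta3)
    ll <- 0
    for (i in seq_along(layouts)) {
      fac <- exp(-(ea3 / kB) * (1 / temps_K[i] - 1 / t0))
      params <- new_bdp_params(th01 * fac[1], th02 * fac[2],
                               th03 * fac[3], N)
      ll <- ll + demog_loglik_layout(params, layouts[[i]], n0,
                                     correct = corrected,
                                     var_floor = var_floor, dt = dt)
      if (!is.finite(ll)) return(-Inf)
    }
    ll
  }
  logpost <- function(p) {
    lp <- sum(dnorm(p, prior_mean, prior_sd, log = TRUE))
    ea3 <- if (two_ea) c(exp(p[4]), p[5], exp(p[4])) else rep(exp(p[4]), 3)
    lp + loglik_at(exp(p[1]), exp(p[2]), exp(p[3]), ea3)
  }
  res <- metropolis(logpost, init, chain)
  if (res$status != "ok") {
    stop("direct MCMC failed: ", res$reason)
  }
  draws <- res$draws
  colnames(draws) <- names(init)
  fit <- fit_result("MCMC", if (corrected) "DEMOG_SAMP" else "DEMOG",
                    par = colMeans(draws), se = apply(draws, 2, sd),
                    draws = draws,
                    diagnostics = list(accept_rate = res$accept_rate))
  if (two_ea) {
    ea_r_draws <- exp(draws[, "log_ea_r"])
    ea_k_draws <- draws[, "ea_k"]
    out <- list(
      r = ea_estimate(mean(ea_r_draws), sd(ea_r_draws), source = "r",
                      details = list(draws = ea_r_draws)),
      K = ea_estimate(mean(ea_k_draws), sd(ea_k_draws), source = "K",
                      details = list(draws = ea_k_draws)),
      fit = fit
    )
    class(out) <- "ea_estimate_pair"
    return(out)
  }
  ea_draws <- exp(draws[, "log_ea"])
  ea_estimate(mean(ea_draws), sd(ea_draws), source = "joint",
              details = list(fit = fit, draws = ea_draws))
}

#' @export
print.ea_estimate_pair <- function(x, ...) {
  cat("<ea_estimate_pair> two-activation-energy direct fit\n")
  cat("  E_A,r =", signif(x$r$mean, 4), "eV (se", signif(x$r$se, 3), ")\n")
  cat("  E_A,K =", signif(x$K$mean, 4), "eV (se", signif(x$K$se, 3), ")\n")
  invisible(x)
}

#' The ten activation-energy inference methods
#'
#' `method_table()` enumerates the package's inference methods: indirect
#' methods fit each temperature separately and regress the log parameter on
#' inverse thermal energy; direct methods fit all temperatures jointly with
#' activation energy as an explicit parameter.
#'
#' | id  | likelihood | parameter | approach | engine | sampling-error corr. |
#' |-----|-----------|-----------|----------|--------|----------------------|
#' | M1  | PHEN      | r         | indirect | MLE    | no  |
#' | M2  | PHEN      | K         | indirect | MLE    | no  |
#' | M3  | DEMOG     | r         | indirect | MLE    | no  |
#' | M4  | DEMOG     | K         | indirect | MLE    | no  |
#' | M5  | DEMOG     | r         | indirect | MCMC   | no  |
#' | M6  | DEMOG     | K         | indirect | MCMC   | no  |
#' | M7  | DEMOG_SAMP| r         | indirect | MCMC   | yes |
#' | M8  | DEMOG_SAMP| K         | indirect | MCMC   | yes |
#' | M9  | DEMOG     | E_A       | direct   | MCMC   | no  |
#' | M10 | DEMOG_SAMP| E_A       | direct   | MCMC   | yes |
#'
#' @return A data frame with one row per method.
#' @export
method_table <- function() {
  data.frame(
    method = paste0("M", 1:10),
    family = c("PHEN", "PHEN", "DEMOG", "DEMOG", "DEMOG", "DEMOG",
               "DEMOG_SAMP", "DEMOG_SAMP", "DEMOG", "DEMOG_SAMP"),
    parameter = c("r", "K", "r", "K", "r", "K", "r", "K", "E_A", "E_A"),
    approach = c(rep("indirect", 8), "direct", "direct"),
    engine = c("MLE", "MLE", "MLE", "MLE", "MCMC", "MCMC", "MCMC", "MCMC",
               "MCMC", "MCMC"),
    corrected = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                  FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Run one inference method on a dataset
#'
#' Dispatches the configuration in [method_table()]: per-temperature fits
#' (replicates pooled) followed by weighted Arrhenius regression for the
#' indirect methods M1-M8, or a joint multi-temperature MCMC fit for the
#' direct methods M9-M10. Per-temperature failures are excluded from the
#' regression with a warning provided at least three temperatures remain.
#'
#' @param method_id one of `"M1"`..`"M10"`.
#' @param dataset an `ea_dataset`.
#' @param chain a [chain_control()] (MCMC methods).
#' @param n0,N defaults taken from the dataset (design / simulation truth).
#' @param weighted weight the Arrhenius regression by `1/se^2`?
#' @param mle_starts multi-start count for MLE methods.
#' @param dt,var_floor,include_t0 see [loglik_demog()].
#' @return An [ea_estimate()] with `method_id` set; per-temperature fits
#'   (indirect methods) are in `details$fits`.
#' @export
run_method <- function(method_id, dataset, chain = chain_control(),
                       n0 = NULL, N = NULL, weighted = TRUE,
                       mle_starts = 5, dt = 0.01, var_floor = 1e-6,
                       include_t0 = FALSE) {
  tab <- method_table()
  row <- tab[tab$method == method_id, ]
  if (nrow(row) != 1) {
    stop("unknown method id '", method_id, "'; see method_table()")
  }
  if (is.null(n0)) {
    if (is.null(dataset$design)) stop("n0 required without a design")
    n0 <- dataset$design$n0
  }
  if (is.null(N)) N <- if (!is.null(dataset$model)) dataset$model$N else 15000

  if (row$approach == "direct") {
    est <- direct_ea(dataset, corrected = row$corrected, two_ea = FALSE,
                     chain = chain, n0 = n0, N = N, dt = dt,
                     var_floor = var_floor, include_t0 = include_t0)
    est$method_id <- method_id
    return(est)
  }

  spec <- likelihood_spec(row$family, "single_temperature")
  series <- dataset_series(dataset)
  temps <- vapply(series, function(s) s$temperature_C[1], numeric(1))
  utemps <- sort(unique(temps))
  fits <- lapply(utemps, function(tc) {
    group <- series[temps == tc]
    if (row$engine == "MLE") {
      fit_mle(spec, group, n0 = n0, N = N, n_starts = mle_starts, dt = dt,
              var_floor = var_floor, include_t0 = include_t0)
    } else {
      fit_mcmc(spec, group, n0 = n0, N = N, chain = chain, dt = dt,
               var_floor = var_floor, include_t0 = include_t0)
    }
  })
  est <- indirect_ea(fits, utemps, source = row$parameter,
                     method_id = method_id, weighted = weighted)
  est$details$fits <- fits
  est$details$temperatures <- utemps
  est
}
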