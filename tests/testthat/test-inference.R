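test_that("indirect regression recovers exact Arrhenius slopes to machine precision", {
  model <- paper_model(0.73)
  temps <- c(18, 23, 28)
  fits <- lapply(temps, function(tc) {
    lp <- derive_logistic(scale_model(model, celsius_to_kelvin(tc)))
    thermopop:::fit_result(
      "MLE", "PHEN",
      par = c(log_r = log(lp$r), log_K = log(lp$K)),
      se = c(log_r = 0.01, log_K = 0.01)
    )
  })
  est_r <- indirect_ea(fits, temps, source = "r")
  est_K <- indirect_ea(fits, temps, source = "K")
  expect_equal(est_r$mean, 0.73, tolerance = 1e-9)
  expect_equal(est_K$mean, 0.73, tolerance = 1e-9)
  # the r-route slope is negative, the K-route slope positive
  x <- 1 / (k_boltzmann() * celsius_to_kelvin(temps))
  lr <- vapply(fits, function(f) f$par[["log_r"]], numeric(1))
  lK <- vapply(fits, function(f) f$par[["log_K"]], numeric(1))
  expect_lt(coef(lm(lr ~ x))[2], 0)
  expect_gt(coef(lm(lK ~ x))[2], 0)
})

test_that("weighted regression matches a hand-coded WLS oracle", {
  set.seed(17)
  temps <- seq(18, 28, by = 2)
  x <- 1 / (k_boltzmann() * celsius_to_kelvin(temps))
  se <- c(0.05, 0.2, 0.08, 0.3, 0.1, 0.15)
  y <- -0.6 * x + 30 + rnorm(6, 0, se)
  fits <- lapply(seq_along(temps), function(i) {
    thermopop:::fit_result("MCMC", "DEMOG",
                           par = c(log_r = y[i], log_K = 0),
                           se = c(log_r = se[i], log_K = 1))
  })
  est <- indirect_ea(fits, temps, source = "r")
  # closed-form weighted least squares
  w <- 1 / se^2
  xb <- sum(w * x) / sum(w)
  yb <- sum(w * y) / sum(w)
  slope <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
  resid <- y - yb - slope * (x - xb)
  s2 <- sum(w * resid^2) / (length(x) - 2)
  slope_se <- sqrt(s2 / sum(w * (x - xb)^2))
  expect_equal(est$mean, -slope, tolerance = 1e-10)
  expect_equal(est$se, slope_se, tolerance = 1e-10)
  expect_equal(est$intercept, yb - slope * xb, tolerance = 1e-8)
})

test_that("indirect estimation requires three usable temperatures", {
  f_ok <- thermopop:::fit_result("MLE", "DEMOG",
                                 par = c(log_r = 0, log_K = 9),
                                 se = c(log_r = 0.1, log_K = 0.1))
  f_bad <- thermopop:::fit_result("MLE", "DEMOG", par = NULL,
                                  status = "failed", reason = "degenerate")
  expect_error(
    suppressWarnings(indirect_ea(list(f_ok, f_ok, f_bad), c(18, 23, 28))),
    "insufficient temperatures"
  )
  expect_warning(
    indirect_ea(list(f_ok, f_ok, f_ok, f_bad), c(18, 21, 24, 28)),
    "excluded"
  )
})

test_that("degenerate series are refused with a machine-readable reason", {
  zero <- data.frame(time = 1:10, count = 0, frac_samp = 0.01)
  f <- fit_mle(likelihood_spec("DEMOG"), zero, n0 = 100)
  expect_equal(f$status, "failed")
  expect_match(f$reason, "degenerate data")
  f2 <- fit_mcmc(likelihood_spec("DEMOG"), zero, n0 = 100,
                 chain = chain_control(n_iter = 100, n_keep = 10))
  expect_equal(f2$status, "failed")
})

test_that("mcmc chains are reproducible and concentrate around the MLE", {
  design <- experimental_design(28, reps = 10, sample_times = 1:15,
                                frac_samp = 1, n0 = 100)
  ds <- simulate_design(paper_model(0.6), design, seed = 55)
  ser <- dataset_series(ds)
  spec <- likelihood_spec("DEMOG")
  ch <- chain_control(n_iter = 3000, n_keep = 500)
  set.seed(5)
  f1 <- fit_mcmc(spec, ser, n0 = 100, chain = ch)
  set.seed(5)
  f2 <- fit_mcmc(spec, ser, n0 = 100, chain = ch)
  expect_identical(f1$draws, f2$draws)
  expect_gt(f1$diagnostics$accept_rate, 0.05)

  mle <- fit_mle(spec, ser, n0 = 100)
  expect_lt(abs(f1$par[["log_r"]] - mle$par[["log_r"]]),
            max(1.5 * f1$se[["log_r"]], 0.05))
  expect_lt(abs(f1$par[["log_K"]] - mle$par[["log_K"]]),
            max(1.5 * f1$se[["log_K"]], 0.05))
})

test_that("prior-only sampling reproduces the prior moments", {
  ser <- data.frame(time = 1:10, count = rep(c(3, 5), 5), frac_samp = 0.01)
  set.seed(9)
  f <- fit_mcmc(likelihood_spec("DEMOG"), ser, n0 = 100,
                chain = chain_control(n_iter = 20000, n_keep = 2000),
                prior_only = TRUE)
  # independent N(init, 2) priors: sd of each marginal ~ 2
  sds <- apply(f$draws, 2, sd)
  expect_true(all(abs(sds - 2) < 0.45))
})

test_that("method dispatch covers the full table and flags unknown ids", {
  expect_equal(nrow(method_table()), 10)
  expect_error(run_method("M11", noiseless_dataset()), "unknown method")

  # M1 on noiseless deterministic data recovers the exact activation energy
  ds <- noiseless_dataset(e_a = 0.6)
  est <- run_method("M1", ds)
  expect_equal(est$method_id, "M1")
  expect_equal(est$source, "r")
  expect_equal(est$mean, 0.6, tolerance = 1e-3)
  est2 <- run_method("M2", ds)
  expect_equal(est2$mean, 0.6, tolerance = 1e-3)
})

test_that("direct estimation needs a temperature gradient", {
  design <- experimental_design(28, reps = 2, sample_times = c(3, 6, 9),
                                frac_samp = 0.01, n0 = 100)
  ds <- simulate_design(paper_model(0.6), design, seed = 77)
  expect_error(direct_ea(ds), ">= 2 temperatures")
})

test_that("indirect estimates are invariant to the reference temperature", {
  # T0 enters only through the baselines; generating exact parameter values
  # from models with different T0 but the same E_A gives the same slope
  temps <- seq(18, 28, by = 5)
  make_fits <- function(t0) {
    model <- arrhenius_model(1.5, 1, 0.5, e_a = 0.45, t0 = t0)
    lapply(temps, function(tc) {
      lp <- derive_logistic(scale_model(model, celsius_to_kelvin(tc)))
      thermopop:::fit_result("MLE", "DEMOG",
                             par = c(log_r = log(lp$r), log_K = log(lp$K)),
                             se = c(log_r = 0.05, log_K = 0.05))
    })
  }
  e1 <- indirect_ea(make_fits(301.15), temps, source = "r")
  e2 <- indirect_ea(make_fits(291.15), temps, source = "r")
  expect_equal(e1$mean, e2$mean, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(e1$intercept, e2$intercept)))
})
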