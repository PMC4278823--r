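test_that("moment ODE mean is the logistic solution and variance limits hold", {
  p <- paper_params()
  tt <- c(0.5, 2, 5, 10, 15)
  mp <- moment_odes(p, 100, tt)
  expect_equal(mp$mean, logistic_mean(tt, logistic_params(1, 10000, 100)),
               tolerance = 1e-7)
  expect_true(all(mp$var >= 0))

  # critical branching limit: theta1 = theta3, density dependence off ->
  # variance grows linearly, dV/dt = 2 theta1 n0
  p0 <- bdp_params(1, 1e-12, 1, 15000)
  mp0 <- moment_odes(p0, 50, c(1, 2, 4))
  expect_equal(mp0$mean, rep(50, 3), tolerance = 1e-6)
  expect_equal(mp0$var, 2 * 1 * 50 * c(1, 2, 4), tolerance = 1e-5)
})

test_that("moment ODE variance matches an independent integrator", {
  skip_if_not_installed("deSolve")
  p <- bdp_params(1.2, 0.8, 0.4, 12000)
  tt <- c(1, 3, 6, 10, 15)
  ode <- deSolve::lsoda(
    c(m = 80, V = 0), c(0, tt),
    function(t, y, parms) {
      B <- 1.2 * y[1] * (1 - 0.8 * y[1] / 12000)
      D <- 0.4 * y[1]
      Bp <- 1.2 * (1 - 2 * 0.8 * y[1] / 12000)
      list(c(B - D, 2 * y[2] * (Bp - 0.4) + B + D))
    },
    rtol = 1e-10, atol = 1e-8
  )
  mp <- moment_odes(p, 80, tt)
  expect_equal(mp$mean, unname(ode[-1, "m"]), tolerance = 1e-7)
  expect_equal(mp$var, unname(ode[-1, "V"]), tolerance = 1e-7)
})

test_that("phenomenological likelihood behaves like a gaussian in residuals", {
  lp <- logistic_params(1, 10000, 100)
  tt <- 1:10
  mu <- 0.01 * logistic_mean(tt, lp)
  ser <- data.frame(time = tt, count = mu, frac_samp = 0.01)
  # zero residuals: log L = -n/2 log(2 pi sigma^2)
  expect_equal(loglik_phen(1, 10000, 2, ser, 100),
               -length(tt) / 2 * log(2 * pi * 4))
  # shifting counts strictly lowers the likelihood
  ser2 <- ser
  ser2$count <- ser2$count + 3
  expect_lt(loglik_phen(1, 10000, 2, ser2, 100),
            loglik_phen(1, 10000, 2, ser, 100))
})

test_that("demographic likelihood reduces to the marginal normal and scales", {
  p <- paper_params()
  # frac = 1, one late observation: density is Normal(m(t), V(t))
  mp <- moment_odes(p, 100, 10)
  ser <- data.frame(time = 10, count = 9800, frac_samp = 1)
  expect_equal(loglik_demog(p, ser, 100),
               dnorm(9800, mp$mean, sqrt(mp$var), log = TRUE))
  # corrected adds the Poisson sampling variance f * m
  expect_equal(loglik_corrected(p, ser, 100),
               dnorm(9800, mp$mean, sqrt(mp$var + mp$mean), log = TRUE))

  # doubling frac_samp and counts keeps standardized residuals: the
  # uncorrected log-likelihood changes by exactly -n log 2
  tt <- c(2, 5, 9)
  mp3 <- moment_odes(p, 100, tt)
  ser1 <- data.frame(time = tt, count = 0.5 * mp3$mean + 10, frac_samp = 0.5)
  ser2 <- ser1
  ser2$count <- 2 * ser1$count
  ser2$frac_samp <- 1
  expect_equal(loglik_demog(p, ser2, 100),
               loglik_demog(p, ser1, 100) - 3 * log(2), tolerance = 1e-8)

  # order of observations within a series is irrelevant
  perm <- ser1[c(3, 1, 2), ]
  expect_equal(loglik_demog(p, perm, 100), loglik_demog(p, ser1, 100))
})

test_that("direct likelihood is additive over series and temperatures", {
  model <- paper_model(0.6)
  design <- design_preset(tempsamp = 3, reps = 2, timesamp = 5,
                          fracsamp = 0.01)
  ds <- simulate_design(model, design, seed = 21)
  ll_all <- direct_loglik(model, ds, corrected = TRUE)
  # sum of single-temperature datasets equals the joint log-likelihood
  parts <- vapply(unique(ds$data$temperature_C), function(tc) {
    sub <- ds
    sub$data <- ds$data[ds$data$temperature_C == tc, ]
    direct_loglik(model, sub, corrected = TRUE)
  }, numeric(1))
  expect_equal(ll_all, sum(parts), tolerance = 1e-10)

  # a dataset with a single series equals the per-temperature likelihood
  one <- ds
  one$data <- ds$data[ds$data$temperature_C == 23 & ds$data$replicate == 1, ]
  params <- scale_model(model, celsius_to_kelvin(23))
  ser <- dataset_series(one)[[1]]
  expect_equal(direct_loglik(model, one, corrected = TRUE),
               loglik_corrected(params, ser, 100), tolerance = 1e-10)
})

test_that("likelihood at the truth beats a misspecified alternative", {
  model <- paper_model(0.6)
  design <- design_preset(tempsamp = 6, reps = 1, timesamp = 10,
                          fracsamp = 0.01)
  wins <- 0
  for (s in 1:20) {
    ds <- simulate_design(model, design, seed = 400 + s)
    ll_true <- direct_loglik(model, ds, corrected = TRUE)
    ll_zero <- direct_loglik(paper_model(0), ds, corrected = TRUE)
    if (ll_true > ll_zero) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("maximum likelihood on rich data recovers the birth-death rates", {
  # frac = 1, many replicates: L1 point estimates near truth
  p <- paper_params()
  design <- experimental_design(28, reps = 25, sample_times = 1:15,
                                frac_samp = 1, n0 = 100)
  ds <- simulate_design(paper_model(0.6), design, seed = 33)
  fit <- fit_mle(likelihood_spec("DEMOG"), dataset_series(ds), n0 = 100)
  expect_equal(fit$status, "ok")
  expect_lt(abs(fit$par[["log_r"]] - log(1)), 2.5 * fit$se[["log_r"]] + 0.02)
  expect_lt(abs(fit$par[["log_K"]] - log(10000)),
            2.5 * fit$se[["log_K"]] + 0.02)
})
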