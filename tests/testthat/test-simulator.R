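test_that("design presets reproduce the factorial levels", {
  expect_equal(tempsamp_grid(3), c(18, 23, 28))
  expect_equal(tempsamp_grid(6), seq(18, 28, by = 2))
  expect_equal(tempsamp_grid(11), 18:28)
  expect_equal(timesamp_grid(5), c(3, 6, 9, 12, 15))
  expect_equal(length(timesamp_grid(10)), 10)
  expect_equal(timesamp_grid(15), 1:15)
  expect_error(tempsamp_grid(4))
  expect_error(timesamp_grid(7))
  d <- design_preset(tempsamp = 6, reps = 5, timesamp = 10, fracsamp = 0.005)
  expect_s3_class(d, "experimental_design")
  expect_error(experimental_design(c(20, 18), 1, 1:5, 0.01))
  expect_error(experimental_design(18, 1, 1:5, 0))
})

test_that("gillespie paths respect absorbing and boundary states", {
  p <- paper_params()
  set.seed(1)
  traj0 <- gillespie(p, 0, 15)
  expect_length(traj0$times, 0)
  expect_equal(trajectory_state(traj0, c(0, 7, 15)), c(0L, 0L, 0L))
  expect_error(gillespie(p, 15001, 15), "floor")

  set.seed(2)
  traj <- gillespie(p, 100, 15)
  expect_true(all(diff(traj$times) > 0))
  expect_true(all(abs(diff(c(traj$n0, traj$sizes))) == 1L))
  # births shut off at N/theta2
  expect_true(max(traj$sizes) <= p$N / p$theta2)
})

test_that("state lookup is right-continuous (post-event at event times)", {
  traj <- structure(
    list(times = c(1, 2, 3), sizes = c(11L, 12L, 11L), n0 = 10L,
         horizon = 5),
    class = "bdp_trajectory"
  )
  expect_equal(trajectory_state(traj, c(0, 0.5, 1, 1.5, 2, 3, 4)),
               c(10L, 10L, 11L, 11L, 12L, 11L, 11L))
})

test_that("pure death process decays exponentially in the mean", {
  p <- bdp_params(0, 1, 0.5, 100)
  set.seed(42)
  ens <- gillespie_ensemble(p, 30, c(1, 2), 2000)
  for (i in 1:2) {
    expected <- 30 * exp(-0.5 * c(1, 2)[i])
    se <- sd(ens[i, ]) / sqrt(ncol(ens))
    expect_lt(abs(mean(ens[i, ]) - expected), 3 * se)
  }
})

test_that("ensemble moments agree with moment-closure theory", {
  # Mean: the logistic form is the first-order (mean-field) answer; the
  # second-order closure adds the -theta1 theta2 V / N correction, which is
  # the statistically exact comparison at Monte-Carlo precision.
  p <- paper_params()
  tt <- c(2, 5, 10, 15)
  set.seed(7)
  ens <- gillespie_ensemble(p, 100, tt, 400)
  m_hat <- rowMeans(ens)
  se <- apply(ens, 1, sd) / sqrt(ncol(ens))

  mp <- moment_odes(p, 100, tt)
  corr <- moment_closure_mean(p, 100, tt)
  lp <- logistic_mean(tt, logistic_params(1, 10000, 100))
  expect_equal(mp$mean, lp, tolerance = 1e-6) # structural identity
  expect_true(all(abs(m_hat - corr) < 4 * se))
  expect_true(all(abs(m_hat - lp) / lp < 0.01))

  # Variance from the moment ODEs during the growth phase (t <= time to
  # 0.9 K, about day 7): within Monte-Carlo error of the ensemble.
  v_hat <- apply(ens, 1, var)
  se_v <- apply(ens, 1, function(x) {
    n <- length(x)
    sqrt((mean((x - mean(x))^4) - var(x)^2 * (n - 3) / (n - 1)) / n)
  })
  grow <- tt <= 7
  expect_true(all(abs(v_hat[grow] - mp$var[grow]) < 4 * se_v[grow]))
})

test_that("poisson observation layer has matching mean and variance", {
  traj <- structure(list(times = numeric(0), sizes = integer(0),
                         n0 = 10000L, horizon = 1), class = "bdp_trajectory")
  set.seed(11)
  obs <- observe(traj, rep(0.5, 2000), 0.01)
  se_mean <- sd(obs$count) / sqrt(2000)
  expect_lt(abs(mean(obs$count) - 100), 3 * se_mean)
  x <- obs$count
  se_var <- sqrt((mean((x - mean(x))^4) - var(x)^2) / length(x))
  expect_lt(abs(var(x) - 100), 3 * se_var)
  # degenerate fraction limit: tiny fraction gives (almost) all zeros
  set.seed(12)
  obs0 <- observe(traj, rep(0.5, 100), 1e-9)
  expect_true(all(obs0$count == 0))
})

test_that("simulated designs are reproducible and correctly shaped", {
  model <- paper_model(0.6)
  design <- design_preset(tempsamp = 11, reps = 5, timesamp = 5,
                          fracsamp = 0.01)
  ds1 <- simulate_design(model, design, seed = 5)
  ds2 <- simulate_design(model, design, seed = 5)
  expect_identical(ds1$data, ds2$data)
  expect_equal(length(dataset_series(ds1)), 55)
  expect_equal(nrow(ds1$data), 55 * 5)
  ds3 <- simulate_design(model, design, seed = 6)
  expect_false(identical(ds1$data, ds3$data))
})

test_that("high activation energy slows growth at cold temperatures", {
  # at 18 C the rate-scaling factor is smaller for larger E_A, so final
  # counts should be ordered accordingly (compare against logistic means)
  final_mean <- function(ea) {
    lp <- derive_logistic(
      scale_model(paper_model(ea), celsius_to_kelvin(18)), 100)
    logistic_mean(15, lp)
  }
  expect_lt(final_mean(1.2), 0.2 * final_mean(0.2))
  design <- design_preset(tempsamp = 3, reps = 2, timesamp = 5,
                          fracsamp = 0.01)
  d_hi <- simulate_design(paper_model(1.2), design, seed = 9)
  d_lo <- simulate_design(paper_model(0.2), design, seed = 9)
  at18 <- function(d) d$data[d$data$temperature_C == 18 &
                               d$data$time_d == 15, "count"]
  expect_lt(mean(at18(d_hi)), mean(at18(d_lo)))
})
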