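# Shared fixtures: everything is generated in code at test time.

paper_params <- function() bdp_params(1.5, 1, 0.5, 15000)

paper_model <- function(e_a = 0.6) arrhenius_model(1.5, 1, 0.5, e_a = e_a)

# A noiseless dataset whose counts equal frac * logistic mean exactly
# (continuous values; only the fitting layer consumes it).
noiseless_dataset <- function(e_a = 0.6, temps = seq(18, 28, by = 2),
                              times = 1:15, frac = 0.01, n0 = 100) {
  model <- paper_model(e_a)
  rows <- lapply(temps, function(tc) {
    lp <- derive_logistic(scale_model(model, celsius_to_kelvin(tc)), n0)
    data.frame(temperature_C = tc, replicate = 1, time_d = times,
               count = frac * logistic_mean(times, lp), frac_samp = frac)
  })
  structure(list(data = do.call(rbind, rows),
                 design = experimental_design(temps, 1, times, frac,
                                              n0 = n0, horizon = max(times)),
                 model = model, seed = NA_integer_),
            class = "ea_dataset")
}

# Independent second-order moment-closure oracle for the ensemble mean:
# dm/dt = B(m) - D(m) - theta1 theta2 V / N (the E[B(n)] expansion term),
# dV/dt as in the package's moment ODEs. Plain-R RK4.
moment_closure_mean <- function(params, n0, times, dt = 0.005) {
  th1 <- params$theta1; th2 <- params$theta2; th3 <- params$theta3
  N <- params$N
  f <- function(m, V) {
    B <- th1 * m * (1 - th2 * m / N); D <- th3 * m
    Bp <- th1 * (1 - 2 * th2 * m / N)
    c(B - D - th1 * th2 * V / N, 2 * V * (Bp - th3) + B + D)
  }
  y <- c(n0, 0); t <- 0; out <- numeric(length(times)); k <- 1
  for (target in times) {
    while (t < target - 1e-12) {
      h <- min(dt, target - t)
      k1 <- f(y[1], y[2]); k2 <- f(y[1] + h/2 * k1[1], y[2] + h/2 * k1[2])
      k3 <- f(y[1] + h/2 * k2[1], y[2] + h/2 * k2[2])
      k4 <- f(y[1] + h * k3[1], y[2] + h * k3[2])
      y <- y + h/6 * (k1 + 2*k2 + 2*k3 + k4); t <- t + h
    }
    out[k] <- y[1]; k <- k + 1
  }
  out
}

# Ensemble of Gillespie states at fixed times (matrix: times x reps).
gillespie_ensemble <- function(params, n0, times, n_rep) {
  replicate(n_rep, {
    traj <- gillespie(params, n0, max(times))
    trajectory_state(traj, times)
  })
}
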