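#' Factorial design presets
#'
#' The simulation study varies four design factors, each over three levels:
#' the number of temperatures along the 18-28 C gradient (TEMPSAMP: 3, 6 or
#' 11), replicates per temperature (REPS: 1, 3 or 5), sampling occasions
#' over the 15-day horizon (TIMESAMP: 5, 10 or 15) and the fraction of the
#' habitat counted at each occasion (FRACSAMP: 0.001, 0.005 or 0.01).
#'
#' `tempsamp_grid()` returns the Celsius temperature grid for a TEMPSAMP
#' level: 11 -> 18:28 in 1-degree steps, 6 -> 18:28 in 2-degree steps,
#' 3 -> 18, 23, 28. `timesamp_grid()` returns sampling days for a TIMESAMP
#' level: 5 -> once every three days (3, 6, 9, 12, 15), 10 -> twice every
#' three days (1.5, 3, ..., 15), 15 -> daily (1, ..., 15).
#'
#' @param tempsamp one of 3, 6, 11.
#' @param timesamp one of 5, 10, 15.
#' @return Numeric vector of temperatures (Celsius) or times (days).
#' @export
tempsamp_grid <- function(tempsamp) {
  switch(as.character(tempsamp),
    "3"  = c(18, 23, 28),
    "6"  = seq(18, 28, by = 2),
    "11" = seq(18, 28, by = 1),
    stop("tempsamp must be one of 3, 6, 11")
  )
}

#' @rdname tempsamp_grid
#' @export
timesamp_grid <- function(timesamp) {
  switch(as.character(timesamp),
    "5"  = seq(3, 15, by = 3),
    "10" = seq(1.5, 15, by = 1.5),
    "15" = seq(1, 15, by = 1),
    stop("timesamp must be one of 5, 10, 15")
  )
}

#' Experimental design for a temperature-gradient microcosm study
#'
#' Describes one simulated experiment: which temperatures are run, how many
#' replicate populations per temperature, when each population is sampled,
#' and what fraction of the habitat is counted at each sampling occasion.
#'
#' @param temperatures temperatures in Celsius, strictly increasing.
#' @param reps replicates per temperature (>= 1).
#' @param sample_times sampling days, strictly increasing, all within
#'   `[0, horizon]`.
#' @param frac_samp fraction of habitat sampled per observation, in (0, 1].
#' @param n0 initial abundance, individuals.
#' @param horizon experiment duration, days.
#' @return An object of class `experimental_design`.
#' @seealso [design_preset()] to build a design from factor levels.
#' @export
experimental_design <- function(temperatures, reps, sample_times,
                                frac_samp, n0 = 100, horizon = 15) {
  stopifnot(
    is.numeric(temperatures), length(temperatures) >= 1,
    !is.unsorted(temperatures, strictly = TRUE),
    is.numeric(reps), length(reps) == 1L, reps >= 1, reps == floor(reps),
    is.numeric(sample_times), length(sample_times) >= 1,
    !is.unsorted(sample_times, strictly = TRUE),
    all(sample_times >= 0), all(sample_times <= horizon),
    is.numeric(frac_samp), length(frac_samp) == 1L,
    frac_samp > 0, frac_samp <= 1,
    n0 >= 0, horizon > 0
  )
  structure(
    list(temperatures = temperatures, reps = as.integer(reps),
         sample_times = sample_times, frac_samp = frac_samp,
         n0 = n0, horizon = horizon),
    class = "experimental_design"
  )
}

#' @param tempsamp,timesamp,fracsamp factor levels: `tempsamp` in
#'   \{3, 6, 11\}, `timesamp` in \{5, 10, 15\}, `fracsamp` in (0, 1].
#' @rdname experimental_design
#' @export
design_preset <- function(tempsamp = 11, reps = 3, timesamp = 15,
                          fracsamp = 0.01, n0 = 100, horizon = 15) {
  experimental_design(
    temperatures = tempsamp_grid(tempsamp),
    reps = reps,
    sample_times = timesamp_grid(timesamp),
    frac_samp = fracsamp,
    n0 = n0, horizon = horizon
  )
}

#' @export
print.experimental_design <- function(x, ...) {
  cat("<experimental_design>", length(x$temperatures), "temperatures (",
      min(x$temperatures), "-", max(x$temperatures), "C ) x", x$reps,
      "reps;", length(x$sample_times), "sampling times over", x$horizon,
      "days; frac_samp =", x$frac_samp, "; n0 =", x$n0, "\n")
  invisible(x)
}

#' Exact stochastic simulation of the birth-death process
#'
#' Simulates one sample path of the stochastic logistic birth-death process
#' with the Gillespie algorithm, recording the exact time and population
#' size after every individual birth or death event. Randomness comes from
#' R's RNG, so `set.seed()` gives reproducible paths.
#'
#' @param params a [bdp_params()] object.
#' @param n0 initial abundance (integer >= 0; must not exceed the abundance
#'   at which the birth propensity vanishes, `floor(N / theta2)`).
#' @param horizon simulation end time, days.
#' @return An object of class `bdp_trajectory`: list with `times` (event
#'   times, days), `sizes` (abundance after each event), `n0`, `horizon`.
#' @examples
#' set.seed(1)
#' p <- bdp_params(1.5, 1, 0.5, 15000)
#' traj <- gillespie(p, n0 = 100, horizon = 15)
#' @export
gillespie <- function(params, n0, horizon) {
  stopifnot(inherits(params, "bdp_params"),
            is.numeric(n0), length(n0) == 1L, n0 >= 0, n0 == floor(n0),
            is.numeric(horizon), length(horizon) == 1L, horizon > 0)
  if (n0 > floor(params$N / params$theta2)) {
    stop("n0 exceeds floor(N / theta2): birth propensity would be negative")
  }
  res <- gillespie_cpp(params$theta1, params$theta2, params$theta3,
                       params$N, as.integer(n0), horizon)
  structure(
    list(times = res$times, sizes = as.integer(res$sizes),
         n0 = as.integer(n0), horizon = horizon),
    class = "bdp_trajectory"
  )
}

#' @export
print.bdp_trajectory <- function(x, ...) {
  cat("<bdp_trajectory>", length(x$times), "events over", x$horizon,
      "days; n0 =", x$n0, "; final size =",
      if (length(x$sizes)) x$sizes[length(x$sizes)] else x$n0, "\n")
  invisible(x)
}

#' State of a trajectory at given times
#'
#' Right-continuous step lookup: the state at time `t` is the population
#' size after the last event at or before `t`.
#'
#' @param traj a [gillespie()] trajectory.
#' @param times times to query, days.
#' @return Integer abundances.
#' @export
trajectory_state <- function(traj, times) {
  stopifnot(inherits(traj, "bdp_trajectory"), is.numeric(times),
            all(times >= 0))
  idx <- findInterval(times, traj$times)
  c(traj$n0, traj$sizes)[idx + 1L]
}

#' Poisson sampling of a trajectory
#'
#' Emulates counting a fraction of the habitat: the observed count at time
#' `t` is drawn from `Poisson(frac_samp * n(t))`, with `n(t)` the trajectory
#' state at `t`, independently across sampling occasions given the path.
#'
#' @param traj a [gillespie()] trajectory.
#' @param times sampling times, days, within `[0, horizon]`.
#' @param frac_samp fraction(s) of habitat sampled, in (0, 1]; recycled to
#'   `length(times)`.
#' @return A data frame with columns `time`, `count`, `frac_samp`.
#' @export
observe <- function(traj, times, frac_samp) {
  stopifnot(inherits(traj, "bdp_trajectory"),
            all(times >= 0), all(times <= traj$horizon),
            is.numeric(frac_samp), all(frac_samp > 0), all(frac_samp <= 1))
  frac_samp <- rep_len(frac_samp, length(times))
  n_t <- trajectory_state(traj, times)
  data.frame(time = times, count = rpois(length(times), frac_samp * n_t),
             frac_samp = frac_samp)
}

#' Simulate a full temperature-gradient dataset
#'
#' Simulates one independent Gillespie path per (temperature, replicate)
#' cell of the design, with the birth-death parameters at each temperature
#' obtained by Arrhenius scaling of the model baselines, then applies the
#' Poisson sampling layer at the design's sampling times. Per-series seeds
#' are spawned deterministically from the master seed, so the same seed
#' always yields the same dataset.
#'
#' @param model an [arrhenius_model()].
#' @param design an [experimental_design()].
#' @param seed master integer seed.
#' @return An object of class `ea_dataset`: list with `data` (data frame
#'   with columns `temperature_C`, `replicate`, `time_d`, `count`,
#'   `frac_samp`), `design`, `model` (the simulation truth) and `seed`.
#' @export
simulate_design <- function(model, design, seed) {
  stopifnot(inherits(model, "arrhenius_model"),
            inherits(design, "experimental_design"),
            is.numeric(seed), length(seed) == 1L)
  temps <- design$temperatures
  n_series <- length(temps) * design$reps
  set.seed(as.integer(seed))
  series_seeds <- sample.int(.Machine$integer.max, n_series)

  pieces <- vector("list", n_series)
  k <- 0L
  for (i in seq_along(temps)) {
    params <- scale_model(model, celsius_to_kelvin(temps[i]))
    if (params$theta1 <= params$theta3) {
      stop("model implies a non-growing population at ", temps[i], " C")
    }
    for (j in seq_len(design$reps)) {
      k <- k + 1L
      set.seed(series_seeds[k])
      states <- gillespie_states_cpp(
        params$theta1, params$theta2, params$theta3, params$N,
        as.integer(design$n0), design$sample_times
      )
      pieces[[k]] <- data.frame(
        temperature_C = temps[i], replicate = j,
        time_d = design$sample_times,
        count = rpois(length(states), design$frac_samp * states),
        frac_samp = design$frac_samp
      )
    }
  }
  structure(
    list(data = do.call(rbind, pieces), design = design, model = model,
         seed = as.integer(seed)),
    class = "ea_dataset"
  )
}

#' @export
print.ea_dataset <- function(x, ...) {
  temps <- unique(x$data$temperature_C)
  cat("<ea_dataset>", nrow(x$data), "observations;", length(temps),
      "temperatures (", min(temps), "-", max(temps), "C );",
      length(unique(interaction(x$data$temperature_C, x$data$replicate))),
      "series\n")
  if (!is.null(x$model)) {
    cat("  simulated; true activation energy:",
        paste(signif(x$model$e_a, 6), collapse = ", "), "eV; seed",
        x$seed, "\n")
  }
  invisible(x)
}

#' Split a dataset into per-series data frames
#'
#' @param dataset an `ea_dataset` (or any list with a conforming `data`
#'   data frame).
#' @return Named list of data frames (one per temperature x replicate),
#'   each with columns `time`, `count`, `frac_samp` plus `temperature_C`
#'   and `replicate`.
#' @export
dataset_series <- function(dataset) {
  d <- dataset$data
  stopifnot(is.data.frame(d))
  key <- interaction(d$temperature_C, d$replicate, drop = TRUE, sep = "/")
  lapply(split(d, key), function(s) {
    s <- s[order(s$time_d), ]
    data.frame(time = s$time_d, count = s$count, frac_samp = s$frac_samp,
               temperature_C = s$temperature_C, replicate = s$replicate)
  })
}
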