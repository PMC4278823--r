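#' Birth-death process parameters at a single temperature
#'
#' The stochastic logistic model is a continuous-time birth-death process on
#' population size `n` with propensities
#' \deqn{B(n) = \theta_1 n (1 - \theta_2 n / N), \qquad D(n) = \theta_3 n,}
#' where `theta1` and `theta3` are the per-capita birth and death rates in
#' the absence of density dependence (1/day), `theta2` (dimensionless)
#' controls the strength of density dependence on births, and `N` is the
#' population size at which the probability of a birth reaches zero.
#'
#' @param theta1 per-capita birth rate at low density, 1/day (>= 0;
#'   zero gives a pure death process).
#' @param theta2 density-dependence strength, dimensionless (> 0).
#' @param theta3 per-capita death rate, 1/day (>= 0).
#' @param N birth-saturation population size, individuals (>= 1).
#' @param require_growth if `TRUE`, require `theta1 > theta3` (a growing
#'   population), as needed when the parameters drive a simulation.
#' @return An object of class `bdp_params`.
#' @seealso [derive_logistic()] for the implied growth rate and carrying
#'   capacity, [gillespie()] for simulation.
#' @examples
#' p <- bdp_params(1.5, 1, 0.5, 15000)
#' derive_logistic(p) # r = 1/day, K = 10000
#' @export
bdp_params <- function(theta1, theta2, theta3, N, require_growth = FALSE) {
  stopifnot(
    is.numeric(theta1), length(theta1) == 1L, is.finite(theta1), theta1 >= 0,
    is.numeric(theta2), length(theta2) == 1L, is.finite(theta2), theta2 > 0,
    is.numeric(theta3), length(theta3) == 1L, is.finite(theta3), theta3 >= 0,
    is.numeric(N), length(N) == 1L, is.finite(N), N >= 1
  )
  if (require_growth && theta1 <= theta3) {
    stop("non-growing population: theta1 must exceed theta3 for simulation")
  }
  structure(
    list(theta1 = theta1, theta2 = theta2, theta3 = theta3, N = N),
    class = "bdp_params"
  )
}

#' @export
print.bdp_params <- function(x, ...) {
  cat("<bdp_params> theta1 =", x$theta1, " theta2 =", x$theta2,
      " theta3 =", x$theta3, " N =", x$N, "\n")
  lp <- derive_logistic(x)
  cat("  implied r =", lp$r, "/day,  K =", lp$K, "individuals\n")
  invisible(x)
}

#' Arrhenius temperature-scaling model for demographic rates
#'
#' Ties the birth-death parameters at all temperatures together through the
#' Arrhenius equation: each rate `theta_i` at absolute temperature `T` is
#' \deqn{\theta_i(T) = \theta_{0i}\,
#'   e^{-\frac{E_{A,i}}{k_B}(1/T - 1/T_0)},}
#' where `E_A,i` is the activation energy (eV), `k_B` the Boltzmann constant
#' and `T0` the reference temperature at which the baselines are defined.
#'
#' `e_a` may be
#' * a single value: one shared activation energy for all three rates (the
#'   usual simulation setting), under which the growth rate scales with
#'   `-E_A` and the carrying capacity with `+E_A` on the 1/(kB T) scale;
#' * a named pair `c(r = ..., K = ...)`: separate activation energies for
#'   growth rate and carrying capacity (the case-study variant), mapped to
#'   per-rate energies `(E_A,r, E_A,K, E_A,r)` so that r scales exactly with
#'   `E_A,r` and K exactly with `E_A,K`;
#' * a length-3 vector: explicit per-rate energies for `(theta1, theta2,
#'   theta3)`.
#'
#' @param theta01,theta02,theta03 baseline rates at `t0` (see
#'   [bdp_params()] for units and meaning).
#' @param e_a activation energy specification in eV (see Details).
#' @param N birth-saturation population size (temperature independent).
#' @param t0 reference temperature, Kelvin.
#' @return An object of class `arrhenius_model`.
#' @examples
#' mod <- arrhenius_model(1.5, 1, 0.5, e_a = 0.6)
#' scale_model(mod, celsius_to_kelvin(18))
#' @export
arrhenius_model <- function(theta01, theta02, theta03, e_a,
                            N = 15000, t0 = t_ref()) {
  stopifnot(
    theta01 > 0, theta02 > 0, theta03 >= 0, N >= 1,
    is.numeric(t0), length(t0) == 1L, t0 > 0,
    is.numeric(e_a), all(is.finite(e_a))
  )
  triple <- ea_triple(e_a)
  structure(
    list(theta01 = theta01, theta02 = theta02, theta03 = theta03,
         e_a = e_a, e_a_triple = triple, N = N, t0 = t0),
    class = "arrhenius_model"
  )
}

# Expand an activation-energy spec to per-theta energies (theta1, theta2,
# theta3). A named (r, K) pair maps to (E_r, E_K, E_r): theta1 and theta3
# share E_r so r = theta1 - theta3 scales with E_r, while theta2 carries E_K
# so K = N r / (theta1 theta2) scales with +E_K.
ea_triple <- function(e_a) {
  if (length(e_a) == 1L) {
    rep(unname(e_a), 3L)
  } else if (length(e_a) == 2L) {
    nm <- names(e_a)
    if (is.null(nm) || !setequal(nm, c("r", "K"))) {
      stop("a length-2 `e_a` must be named c(r = ..., K = ...)")
    }
    c(unname(e_a["r"]), unname(e_a["K"]), unname(e_a["r"]))
  } else if (length(e_a) == 3L) {
    unname(e_a)
  } else {
    stop("`e_a` must have length 1, 2 (named r/K) or 3")
  }
}

#' @export
print.arrhenius_model <- function(x, ...) {
  cat("<arrhenius_model> baselines at T0 =", x$t0, "K:",
      x$theta01, x$theta02, x$theta03, " N =", x$N, "\n")
  cat("  activation energies (theta1, theta2, theta3):",
      paste(signif(x$e_a_triple, 6), collapse = ", "), "eV\n")
  invisible(x)
}

#' Arrhenius scaling of a single rate
#'
#' Scales a rate known at reference temperature `t0` to temperature `temp`:
#' `theta0 * exp(-(e_a / kB) * (1/temp - 1/t0))`. Strictly increasing in
#' `temp` when `e_a > 0`. Vectorised over `temp`.
#'
#' @param theta0 rate at the reference temperature (> 0).
#' @param e_a activation energy, eV.
#' @param temp target absolute temperature(s), Kelvin (> 0).
#' @param t0 reference absolute temperature, Kelvin (> 0).
#' @return The rate(s) at `temp`.
#' @export
arrhenius_scale <- function(theta0, e_a, temp, t0 = t_ref()) {
  stopifnot(is.numeric(theta0), all(theta0 > 0), is.numeric(e_a))
  if (!is.numeric(temp) || any(temp <= 0) || !is.numeric(t0) || any(t0 <= 0)) {
    stop("temperatures must be positive and in Kelvin")
  }
  theta0 * exp(-(e_a / k_boltzmann()) * (1 / temp - 1 / t0))
}

#' Scale an Arrhenius model to one temperature
#'
#' Applies [arrhenius_scale()] to each baseline rate with its own activation
#' energy, returning the birth-death parameters in force at absolute
#' temperature `temp`.
#'
#' @param model an [arrhenius_model()].
#' @param temp absolute temperature, Kelvin.
#' @return A [bdp_params()] object.
#' @export
scale_model <- function(model, temp) {
  stopifnot(inherits(model, "arrhenius_model"),
            is.numeric(temp), length(temp) == 1L, temp > 0)
  ea <- model$e_a_triple
  bdp_params(
    theta1 = arrhenius_scale(model$theta01, ea[1], temp, model$t0),
    theta2 = arrhenius_scale(model$theta02, ea[2], temp, model$t0),
    theta3 = if (model$theta03 > 0) {
      arrhenius_scale(model$theta03, ea[3], temp, model$t0)
    } else 0,
    N = model$N
  )
}

#' Logistic growth parameters
#'
#' Container for the deterministic logistic description of the mean
#' dynamics: maximum growth rate `r` (1/day), carrying capacity `K`
#' (individuals) and initial abundance `n0`.
#'
#' @param r maximum per-capita growth rate, 1/day.
#' @param K carrying capacity, individuals (> 0 where used).
#' @param n0 initial abundance, individuals (>= 0).
#' @return An object of class `logistic_params`.
#' @export
logistic_params <- function(r, K, n0) {
  stopifnot(is.numeric(r), length(r) == 1L, is.finite(r),
            is.numeric(K), length(K) == 1L,
            is.numeric(n0), length(n0) == 1L, n0 >= 0)
  structure(list(r = r, K = K, n0 = n0), class = "logistic_params")
}

#' Growth rate and carrying capacity implied by birth-death parameters
#'
#' The mean abundance of the birth-death process follows the logistic
#' equation with
#' \deqn{r = \theta_1 - \theta_3, \qquad
#'   K = N (\theta_1 - \theta_3) / (\theta_1 \theta_2).}
#' A non-growing parameter set (`theta1 <= theta3`) is flagged via the
#' `growing` attribute rather than raising an error: inference routines may
#' legitimately visit such points.
#'
#' @param params a [bdp_params()] object.
#' @param n0 initial abundance carried into the result (default 0, i.e.
#'   unspecified).
#' @return A [logistic_params()] object with attribute `growing`.
#' @export
derive_logistic <- function(params, n0 = 0) {
  stopifnot(inherits(params, "bdp_params"))
  r <- params$theta1 - params$theta3
  # theta1 = 0 is a pure death process: no birth saturation, K undefined
  K <- if (params$theta1 > 0) {
    params$N * r / (params$theta1 * params$theta2)
  } else NA_real_
  out <- logistic_params(r = r, K = K, n0 = n0)
  attr(out, "growing") <- r > 0
  out
}

#' Deterministic logistic mean abundance
#'
#' Closed-form solution of `dn/dt = r n (1 - n/K)` from `n(0) = n0`,
#' evaluated at times `t` (days):
#' \deqn{n(t) = \frac{K n_0 e^{rt}}{K + n_0 (e^{rt} - 1)}.}
#' Computed in the overflow-safe form `K / (1 + ((K - n0)/n0) e^{-rt})`.
#' The degenerate case `r = 0` returns `n0` (the logistic field vanishes).
#'
#' @param t time(s) since the start, days (>= 0).
#' @param lp a [logistic_params()] object (with `K > 0`).
#' @return Mean abundance at each `t`.
#' @export
logistic_mean <- function(t, lp) {
  stopifnot(inherits(lp, "logistic_params"), is.numeric(t), all(t >= 0),
            lp$K > 0)
  if (lp$n0 == 0) return(rep(0, length(t)))
  if (lp$r == 0) return(rep(lp$n0, length(t)))
  lp$K / (1 + ((lp$K - lp$n0) / lp$n0) * exp(-lp$r * t))
}
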