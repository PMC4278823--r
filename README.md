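# thermopop

Estimating the activation energy of population growth parameters from
temperature-stratified abundance time series.

## The problem

Single-species microcosm experiments run at several fixed temperatures
produce count time series from which ecologists estimate how the intrinsic
growth rate *r* and the carrying capacity *K* depend on temperature. Over
moderate thermal ranges both follow the Arrhenius law

    theta_i(T) = theta_0i * exp(-(E_Ai / kB) * (1/T - 1/T0)),

so that log *r* is linear in the inverse thermal energy 1/(kB·T) with
slope −E_A and log *K* is linear with slope +E_A, where E_A is the
activation energy in electronvolts. Between the parameters and the data
sit two layers of noise — demographic stochasticity (discrete birth and
death events in a finite population) and sampling error (only a fraction
*f* of the habitat is counted) — and how an inference method treats these
layers determines how well E_A can be recovered.

`thermopop` implements the whole stack:

* a **stochastic logistic birth–death model** with propensities
  `B(n) = theta1·n·(1 − theta2·n/N)` and `D(n) = theta3·n`, simulated
  exactly with the Gillespie algorithm, with Arrhenius-scaled rates and a
  Poisson observation layer (`counts ~ Poisson(f·n(t))`);
* **five likelihood families** built on the deterministic logistic mean
  (phenomenological), on the moment (diffusion) approximation of the
  process (demographic), and on the latter plus the Poisson sampling
  variance (corrected);
* **ten inference methods** (`M1`–`M10`) crossing likelihood × engine
  (multi-start MLE or adaptive random-walk Metropolis MCMC) × route:
  *indirect* (per-temperature fits, then weighted regression of the log
  parameter on 1/(kB·T)) or *direct* (joint fit of all temperatures with
  E_A an explicit parameter), including a two-activation-energy variant
  for real data in which *r* and *K* scale differently;
* an **evaluation layer**: factorial sweeps over experimental designs
  (sampling fraction, sampling times, temperatures, replicates) recording
  the relative error `R = 100·|m(E_A) − E_A|/E_A` and precision
  `P = 100·se(E_A)/E_A` of every method, plus regression-tree (CART)
  analysis of which design factors drive the error.

## Worked example

Simulate a 6-temperature experiment (18–28 °C, 3 replicates, sampled
twice every three days, counting 1 % of the habitat) with a true
activation energy of 0.6 eV, and estimate E_A with the best-performing
indirect method (M7: corrected likelihood, MCMC, growth-rate route) and
the corrected direct method (M10):

```r
library(thermopop)
model  <- arrhenius_model(1.5, 1, 0.5, e_a = 0.6)   # r(T0)=1/d, K(T0)=10000
design <- design_preset(tempsamp = 6, reps = 3, timesamp = 10,
                        fracsamp = 0.01)
ds <- simulate_design(model, design, seed = 1)
ds
#> <ea_dataset> 180 observations; 6 temperatures ( 18 - 28 C ); 18 series
#>   simulated; true activation energy: 0.6 eV; seed 1

set.seed(1)
run_method("M7", ds, chain = chain_control(n_iter = 8000))
#> <ea_estimate> M7 (source: r )  E_A = 0.5954 eV  (se 0.0192 )

set.seed(1)
est10 <- run_method("M10", ds, chain = chain_control(n_iter = 8000))
est10
#> <ea_estimate> M10 (source: joint )  E_A = 0.5983 eV  (se 0.021 )

em <- error_metrics(est10, 0.6)
sprintf("relative error R = %.1f%%, precision P = %.1f%%", em$R, em$P)
#> [1] "relative error R = 0.3%, precision P = 3.5%"
```

The direct method pools the information in all 18 series — growth rates
*and* carrying capacities — into a single posterior for E_A; here it lands
within a third of a percent of the truth. `run_factorial()` repeats this over a
grid of designs and methods, and `cart_error_tree()` shows which design
factor matters most (in this study space: the sampled fraction of the
habitat, by a wide margin).

A thin command-line front end over the same functions is installed with
the package (`system.file("scripts", "thermopop", package = "thermopop")`)
with subcommands `simulate`, `fit`, `evaluate` and `cart`.

See the vignette `vignettes/estimating-activation-energy.Rmd` for the
model, the likelihood derivations, priors and chain settings, and the
design decisions.

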