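# parextrap

Tools for analysing how observers extrapolate noisy parabolas when the
curvature is drawn from a bimodal prior — a minimal testbed for whether
behaviour reflects full Bayesian regression, point-estimate regression, or
the prior alone, and whether responses arise by probability matching or by
loss-based decision making.

## The problem

An observer sees four dots sampled from a hidden parabola `y = w x^2` with
Gaussian noise `sigma_g` on the y-coordinates, and must report where the
parabola crosses a probe line at `x* = 2`. The quadratic parameter is drawn
from a bimodal Gaussian-mixture prior

    pi(w) = c N(w; mu_pi, sigma_pi^2) + (1 - c) N(w; -mu_pi, sigma_pi^2)

with `mu_pi = 1`, `c = 1/2`: parabolas face up or down with equal
probability. Conjugacy makes everything closed-form. The package implements:

* **Five regression models** with analytic posterior and posterior-predictive
  distributions (`posterior_w()`, `predictive()`): prior regression (P-R),
  maximum-likelihood regression (ML-R), maximum-a-posteriori regression
  (MAP-R), full Bayesian regression (B-R), and Bayesian regression with a
  trial-by-trial noise estimate (B-R_sigma). Only B-R and its variant
  transition from unimodal to bimodal predictions as `sigma_g` grows.
* **Two decision rules** (`response_distribution()`): probability matching
  (one sample from the predictive, motor noise convolved in closed form) and
  squared-loss Bayesian decision theory (the predictive mean, motor noise the
  only variability — always unimodal).
* **Fitting-free model comparison**: summed log likelihood per participant
  and condition (`compare_all()`) and Bayesian random-effects aggregation via
  the variational Dirichlet scheme (`random_effects()`).
* **Variance analysis**: empirical vs analytic response variances, the
  decomposition `var = sigma_m^2 + sigma_y^2 + c(1-c)(mu_1 - mu_2)^2`
  (`decompose_empirical()`), and a dense noise sweep (`variance_sweep()`).
* **Dominant-mode conditioning**: the unimodal dataset, truncated and
  renormalised model predictions, retention fractions
  (`build_unimodal_dataset()`, `unimodal_compare()`).
* **Synthetic observers and I/O**: generators for both experimental designs,
  simulated observers under any model x rule x motor-noise configuration
  (`generate_experiment()`, `simulate_observer()`), and readers/writers for
  the 11-column per-participant trial-file dialect (`read_trials()`,
  `write_trials()`), plus a small CLI (`cli_main()`,
  `inst/cli/parextrap.R`).

## Worked example

Simulate a Bayesian-regression observer on the main experimental design,
estimate its motor noise from the noise-free practice block, and run the
model comparison:

```r
library(parextrap)
ex     <- generate_experiment("exp1", seed = 42)
config <- observer_config("BR", "sampling", sigma_m = 0.4,
                          participant_id = "sim1")
trials <- simulate_observer(ex, config, seed = 43)

practice <- trials[trials$sigma_g == 0, ]
mn <- estimate_motor_noise(practice$response, practice$w_true[1] * 4)
mn
#> Motor noise sigma_m = 0.3733 (from 20 responses)

cmp <- compare_all(trials, sigma_m = mn$sigma_m, rules = "sampling")
subset(cmp$group, sigma_g == 0.4)[, c("model", "mean_delta")]
#>    model   mean_delta
#>       BR      0.00000
#>  BRsigma    -11.78046
#>     MAPR -17051.33315
#>      MLR -80140.92576
#>       PR    -15.65767
```

The 16/84-percentile estimator recovers the configured motor noise (0.37 vs
0.4 at twenty practice responses). At the highest noise level the generating
model (B-R) wins; the point-estimate models collapse because they place all
mass on one mode while the responses span both; and P-R trails B-R only
narrowly, since with uninformative data the posterior approaches the prior.
Deltas are log-likelihood differences from the B-R + sampling baseline over
400 responses.

Conditioning on the dominant mode shows the retention fractions falling as
the stimuli become less informative:

```r
build_unimodal_dataset(trials)$retention
#>  sigma_pi sigma_g retention_fraction n_participants
#>       0.1    0.03             1.0000              1
#>       0.1    0.10             0.8975              1
#>       0.1    0.40             0.4800              1
```

And the null model's predictive variance at the probe, the benchmark for
fully bimodal responding:

```r
gmix_var(predictive("PR", hyper = hyper_params(sigma_g = 0.03)))
#> [1] 16.1609
```

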