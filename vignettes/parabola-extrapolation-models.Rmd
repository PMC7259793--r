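---
title: "Bayesian regression models of parabola extrapolation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian regression models of parabola extrapolation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parextrap)
```

## The task and the generative model

An observer sees four dots drawn from a hidden parabola `y = w x^2` and must
report where the parabola crosses a vertical probe line at `x* = 2`. The
quadratic parameter is drawn from a bimodal Gaussian-mixture prior

$$\pi(w) = c\,N(w;\, \mu_\pi, \sigma_\pi^2) + (1-c)\,N(w;\, -\mu_\pi, \sigma_\pi^2),$$

with modes at $\pm\mu_\pi = \pm 1$ and mixing coefficient $c = 1/2$, so
parabolas face up or down with equal probability. The dot y-coordinates carry
Gaussian generative noise of standard deviation $\sigma_g$:
$y_i = w x_i^2 + \epsilon_i$, $\epsilon_i \sim N(0, \sigma_g^2)$.

Because the likelihood in $w$ is Gaussian and the prior is a two-component
Gaussian mixture, everything downstream is available in closed form; the
package's universal carrier is the one-dimensional Gaussian mixture
(`gmix()`), used for the prior over $w$, the posterior over $w$, the
posterior predictive over $y^\star$, and the response distribution over $r$.

Two designs are emulated by `generate_experiment()`:

* **Experiment 1** — fixed x-positions $(-0.3, -0.1, 0.1, 0.3)$,
  $\sigma_\pi = 0.1$; 20 unique stimuli per noise level
  $\sigma_g \in \{0.03, 0.1, 0.4\}$, each repeated 20 times (400 trials per
  level), order shuffled within level. A practice block at
  $\sigma_g = 10^{-5}$ (condition label 0) holds the 20 repetitions of the
  near-noiseless stimulus used for motor-noise estimation.
* **Experiment 2** — x-positions jittered around $(-0.18, -0.09, 0, 0.09)$
  with SD 0.09 and a minimum pairwise spacing of 0.1 (resampled under a
  bounded budget, so an infeasible design errors rather than loops);
  $\sigma_\pi = 0.5$, $\sigma_g = 0.1$; 10 unique stimuli repeated 10 times
  plus 100 single presentations.

## The five regression models

Writing $S_4 = \sum_i x_i^4$, the likelihood maximiser is
$w_{ML} = \sum_i y_i x_i^2 / S_4$ with $w$-space variance
$s^2 = \sigma_g^2 / S_4$. Conjugate updating of each prior mode gives a
two-component posterior with common variance
$v = (1/\sigma_\pi^2 + S_4/\sigma_g^2)^{-1}$, means
$v(\pm\mu_\pi/\sigma_\pi^2 + \sum_i y_i x_i^2/\sigma_g^2)$, and weights
proportional to the prior weights times $N(w_{ML};\, \pm\mu_\pi,\,
\sigma_\pi^2 + s^2)$. `predictive()` exposes five ways of turning this into
a distribution over the probe value:

| model | predictive over $y^\star$ |
|---|---|
| `PR`  | prior pushed through the probe: modes $\pm\mu_\pi x^{\star 2}$, variance $\sigma_\pi^2 x^{\star 4} + \sigma_g^2$ |
| `MLR` | $N(w_{ML}\, x^{\star 2},\, \sigma_g^2)$ |
| `MAPR`| $N(w_{MAP}\, x^{\star 2},\, \sigma_g^2)$ |
| `BR`  | posterior mixture pushed through the probe: means $m_k x^{\star 2}$, variance $v x^{\star 4} + \sigma_g^2$, posterior weights |
| `BRsigma` | as `BR` with the trial-by-trial estimate $\hat\sigma_g$ substituted for $\sigma_g$ in both the posterior precision and the predictive noise |

The generative noise plays the central conceptual role: it sets the relative
strength of the unimodal likelihood and the bimodal prior, and thereby the
transition of the Bayesian predictive from unimodal (informative data) to
bimodal (uninformative data). The point-estimate models cannot produce
bimodal predictions at all, and prior regression is bimodal regardless of the
stimulus. All predictions are fitting-free: fixed functions of the stimulus
and the true hyperparameters.

```{r predictive}
h_low  <- hyper_params(sigma_g = 0.03)
h_high <- hyper_params(sigma_g = 0.4)
stim <- stimulus(c(-0.3, -0.1, 0.1, 0.3), c(0.07, 0.02, 0.0, 0.1))
predictive("BR", stim, h_low)$weights    # effectively one mode
predictive("BR", stim, h_high)$weights   # both modes in play
```

## Decision rules and motor noise

`response_distribution()` composes a predictive with a decision rule and the
participant's internal noise $p(r|y^\star) = N(r; y^\star, \sigma_m^2)$:

* **sampling** (probability matching): the response is one draw from the
  predictive; motor noise enters as a closed-form convolution that adds
  $\sigma_m^2$ to every component variance. With $\sigma_m = 0$ this is the
  identity, which is why a non-positive $\sigma_m$ is accepted for this rule.
* **loss** (squared-loss Bayesian decision theory): the response is the
  predictive mean, so the response distribution is
  $N(\langle y \rangle, \sigma_m^2)$ and motor noise is the only source of
  variability. The output is always unimodal — a symmetric bimodal
  predictive collapses to a Gaussian centred between the modes — and
  $\sigma_m > 0$ is required for the density to exist.

Motor noise is participant-specific, not a model parameter. It is estimated
from the 20 responses to the noiseless practice stimulus as half the 16–84
inter-percentile range of the residuals about the true probe value
(`estimate_motor_noise()`), which equals the standard deviation for Gaussian
residuals and is robust to outliers. The estimator uses R's default quantile
definition (type 7); any standard convention moves the estimate by under two
percent at twenty responses. Zero-spread response sets are floored at
$10^{-3}$ with a warning rather than aborting a whole pipeline. The seven
main-experiment values are shipped as `exp1_motor_noise()`; their mean, 0.48,
is the constant applied to second-experiment participants, whose noise-free
responses were not collected.

## Model comparison

`compare_all()` scores every regression-model × decision-rule pair by the
summed log likelihood of each participant's responses under the
motor-noise-convolved response distributions, condition by condition. Because
nothing is fitted, no complexity correction is needed (the comparison is
equivalent to BIC) and deltas against the Bayesian-regression-with-sampling
baseline are directly interpretable. Per-response log densities are floored
at −746 (the double-precision underflow bound) so a single outlier cannot
send a model to $-\infty$; floored counts are reported, and group summaries
report the across-participant mean and SEM of the deltas (the SEM is taken on
deltas, not raw log likelihoods).

`random_effects()` aggregates per-participant evidences with the variational
Dirichlet scheme for hierarchical model selection: responsibilities
$g_{km} \propto \exp(\log E_{km} + \psi(\alpha_m) - \psi(\sum \alpha))$,
$\alpha_m = \alpha_0 + \sum_k g_{km}$, iterated until
$\max|\Delta\alpha| < 10^{-6}$ (cap $10^4$, non-convergence is an error),
with the uninformative prior $\alpha_0 = 1$. The reported quantity is the
normalised Dirichlet parameter, the expected model frequency for a random
participant. Note a structural consequence of $\alpha_0 = 1$: with $K$
participants the dominant model's normalised weight cannot exceed
$(1 + K)/(M + K)$, e.g. $8/9 \approx 0.889$ for seven participants and two
models, however decisive the evidence.

## Variance analysis

For each stimulus the empirical variance of its repeated responses
(`empirical_variance()`, unbiased $n-1$ divisor) is compared with each
model's analytic response variance (`predicted_variance()`). For a
two-component response mixture with equal component variances the variance
splits exactly into

$$\sigma^2_r = \sigma_m^2 + \sigma^2_{y} + c(1-c)(\mu_1 - \mu_2)^2,$$

a unimodal part plus a bimodal part controlled by the mode dispersion and the
prefactor $c(1-c)$ (zero at $c \in \{0,1\}$, maximal at $c = 1/2$).
`decompose_empirical()` computes the empirical counterparts: $c$ as the
fraction of positive responses (a response at exactly 0 counts as positive —
a measure-zero convention that simply has to be fixed), mode means as the
conditional averages, and the unimodal variance from the dominant mode only,
requiring at least 11 of 20 responses there so the estimate has sufficient
samples; exact 10–10 splits are flagged and omitted.

`variance_sweep()` traces the predicted variance across a dense noise grid:
250 log-spaced values of $\sigma_g$ on $[0.02, 0.6]$ × 20 stimuli each
(5000 stimuli covering the experimental range). One set of
quadratic-parameter and unit-noise draws is shared across the grid and scaled
by each grid value — a common-random-numbers device that removes
between-grid-point simulation jitter from the median curves while leaving
each grid point's stimulus distribution correct. On these curves the
Bayesian model's median variance rises monotonically from the MAP-like
regime to the prior-like regime, prior regression is flat apart from the
additive $\sigma_g^2$, and the point-estimate models barely move (ML and MAP
coincide here, both being $\sigma_g^2 + \sigma_m^2$).

## Dominant-mode conditioning

To compare models on mean and variance alone, stripped of mode choice, the
unimodal pipeline (`build_unimodal_dataset()`, `unimodal_compare()`) keeps a
stimulus's dominant-mode responses (the sign holding strictly more than half
of them) if and only if that sign matches the models' dominant mode (the
component set holding more than half the predictive mass). The symmetric
prior guarantees that all likelihood-using models share a dominant mode —
it is the sign of $w_{ML}$ — so the conditioning is taken from the Bayesian
predictive; the symmetric null model is a tie, broken deterministically
upward and flagged. Exact response ties are omitted with the reason
recorded. Bimodal model predictions are truncated to the shared mode and
renormalised (`truncate_and_renormalize()`, idempotent), which guarantees
every retained response positive density under the formerly bimodal models.
Retention fractions are reported per condition as retained responses over
all responses, averaged over participants.

## Synthetic observers, and what they do and do not show

`simulate_observer()` plays any model × rule × $\sigma_m$ configuration
through a generated experiment, drawing one response per scheduled trial.
This makes every downstream stage testable without human data and supports
model-recovery studies: data simulated from a model should be won by that
model, up to analytic near-equivalences at the edges of the noise range
(at $\sigma_g = 0.03$ the posterior-based models nearly coincide; at
$\sigma_g = 0.4$ Bayesian regression approaches prior regression).

The generator reproduces the study conditions — sample sizes, designs, noise
levels, the bimodal prior — but deliberately not the aspects of human data
the original analyses flagged: no trial-by-trial noise (mis)estimation by
the observer, no learning across trials, no sequential dependencies, no
heavy-tailed lapses. Passing recovery tests therefore certify the inference
machinery, not the behavioural conclusions; with real trial files the same
pipeline applies unchanged via `read_trials()`.

## Numerical choices

* Mixture weights are normalised in log space throughout; at
  $\sigma_g = 0.03$ posterior weight ratios routinely exceed $e^{700}$ and
  would underflow naive normalisation.
* $\hat\sigma_g$ is floored at $10^{-6}$ inside the noise-estimating model so
  residual-free stimuli degrade it gracefully toward maximum-likelihood-like
  certainty instead of an infinitely precise likelihood.
* The posterior MAP is taken from the two component-mean candidates plus
  local refinement (`optimize` over a ±3-SD window); exact global
  optimisation is unnecessary because the modes are separated by roughly
  $2\mu_\pi$, far more than the component widths, in all conditions of
  interest. Exact ties break to the positive mode with a flag.
* Per-response log densities floor at −746; the random-effects iteration
  stops at $\max|\Delta\alpha| < 10^{-6}$ or errors at $10^4$ iterations.
* Jittered designs resample at most $10^4$ times per stimulus before
  declaring the spacing constraint infeasible.

The test suite checks the closed forms against independent piecewise
adaptive quadrature of the generative densities (target agreement
$10^{-6}$ in maximum absolute deviation on 6-SD grids), the variational
random-effects solution against a Gibbs sampler, and the estimators against
brute-force and Monte-Carlo oracles. Simulation-based checks run at reduced
but statistically meaningful scales — e.g. 100 recovery replicates per
generating model on the full first-experiment design, 200
quadrature-checked stimuli, $10^4$–$10^6$-draw sampling checks — chosen so
the whole suite completes in a few minutes.

## Known limitations

* The noisy-inference account of decision variability and learning dynamics
  across trials are out of scope, as are Gaussian-process reformulations of
  the regression problem.
* The sweep grid's exact range and spacing are a package choice; it
  reproduces the qualitative variance-transition curves, not any particular
  figure axis.
* With $\alpha_0 = 1$ the random-effects weights are bounded away from 1 for
  small cohorts (see above); this is a property of the model, not a bug.
* Reading deposited trial files assumes the 11-column numeric dialect and
  the `subjN_sig_g = X.txt` naming convention (spaces tolerated); files
  outside it need the condition supplied explicitly.
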