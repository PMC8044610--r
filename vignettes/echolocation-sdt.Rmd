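---
title: "Methods: Bayesian signal detection for two-task echolocation experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian signal detection for two-task echolocation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echosdt)
```

## The experimental situation

A blindfolded listener sits in front of an automated rail on which a
sound-reflecting disk can be positioned at programmed distances, slightly to
the left or right, or turned away entirely. A loudspeaker click is played
once per trial; the listener answers either a detection question ("is a
reflector there?", yes/no) or, on other days, a localization question
("left or right?", with a reflector always present). A method of constant
stimuli governs the schedule: a fixed set of distances appears in random
order, many times per session.

`echosdt` treats one such experiment as a unit: it can *simulate* it from a
specified generative observer, and *analyze* it (real or simulated) with
equal-variance signal detection theory (SDT) estimated by MCMC.

## Observation model

Every trial is coded with a signal indicator $S$ and a response indicator
$y$. For detection, $S = 1$ whenever either reflector faces the listener
and $y = 1$ for a "yes". For localization there is no signal-absent
stimulus, so one side must be designated the "signal" by convention; the
package fixes the left side: $S = 1$ for a left reflector, $y = 1$ for a
"left" response. The convention only affects the sign of the localization
criterion.

The equal-variance SDT observer answers "yes"/"left" with probability

$$ p = (1 - S)\,[1 - \Phi(c + d'/2)] + S\,[1 - \Phi(c - d'/2)], $$

and each response is an independent Bernoulli draw at this probability —
`p_yes()` in the package. Two consequences worth noting:

* the classical closed forms $d' = \Phi^{-1}(H) - \Phi^{-1}(F)$ and
  $c = -[\Phi^{-1}(H) + \Phi^{-1}(F)]/2$ are exactly the inversion of this
  law at the empirical rates, so the Bayesian estimates and the closed forms
  agree whenever the rates are well inside $(0, 1)$ and $n$ is large (this
  equivalence is asserted to within 0.05 at $n = 10{,}000$ per cell in the
  test suite);
* when a cell produces $H = 1$ or $F = 0$ the closed forms are undefined.
  `dprime_from_rates()` deliberately raises a typed error rather than
  applying a continuity correction; the supported remedy is the Bayesian
  fit, whose prior keeps the estimate finite and whose interval honestly
  widens. Negative $d'$ is legal everywhere — an empirical pattern that
  real participants do produce at far distances — and is never clamped.

## The two models

Both models are fitted per participant, on the trial level, with
independent Normal(0, 3) priors on every parameter ("weakly informative":
about ±6 covers the entire plausible range of $d'$ and $c$ in this task;
the prior only matters in near-boundary cells).

* **Categorical**: $d'$ and $c$ free per task × distance. With the default
  design (2 tasks, 10 distances) that is 40 parameters, but the likelihood
  factorizes per cell, so the posterior is a product of independent 2-D
  posteriors — the sampler exploits this.
* **Exponential**: $d'(x) = \alpha_0 e^{\alpha_1 x}$ (detection) and
  $\beta_0 e^{\beta_1 x}$ (localization), criteria $c_0, c_1$ constant in
  distance: 6 parameters. The amplitude is the $d'$ extrapolated to
  distance 0 — distances enter in raw meters, uncentered, matching the
  natural parameterization. A negative rate expresses a fixed proportional
  sensitivity loss per meter.

Point estimates are posterior medians; intervals are 95% highest posterior
density (HPD) intervals. Derived quantities — the between-task $d'$
difference per distance (`task_contrasts()`), the mean of the ten
per-distance criteria and its between-task difference, and the Model-2
criterion contrast (`bias_table()`) — are always computed draw-wise,
never from the marginal summaries, so their intervals respect posterior
dependence. Report output conventionally rounds bias values to one decimal;
the tibbles retain full precision.

## Sampling machinery and numerical choices

No gradient-based sampler is available as a dependency here, and the
posteriors involved are low-dimensional and smooth, so the package ships a
self-contained MCMC scheme:

1. **Aggregation.** Responses are collapsed to binomial counts per
   (task, distance, signal) stratum. No binomial coefficient is carried, so
   a cell's log-likelihood equals the sum of trialwise Bernoulli
   log-probabilities exactly (a test asserts this to 1e-8).
2. **Initialization.** Per-cell starting values come from
   boundary-adjusted rates $(k + 0.5)/(n + 1)$; the posterior mode is then
   located with BFGS and the inverse Hessian supplies the initial proposal
   covariance. The exponential model is seeded by a log-linear regression
   of positive cell-wise $d'$ estimates on distance.
3. **Warmup.** An adaptive random-walk Metropolis phase rescales the step
   size toward the dimension-appropriate acceptance rate and re-estimates
   the proposal covariance over successive warmup windows. The categorical
   model's 2-D cell posteriors are advanced in parallel within one loop.
4. **Sampling.** After warmup the kernel becomes a mixture: 75%
   independence proposals from a multivariate $t_4$ fitted to the warmup
   draws (re-fitted once more after a short tuning segment), 25% residual
   random-walk moves. For these near-Gaussian posteriors the independence
   component accepts often enough that draws are close to independent,
   which is what makes the strict convergence criteria attainable at
   moderate chain lengths.
5. **Safety.** $p$ is clamped to $[10^{-12}, 1 - 10^{-12}]$ inside the
   likelihood; the clamp cannot bind at prior-plausible parameters and
   exists only to protect extreme proposals.

Defaults are 4 chains × 1500 kept draws after 1000 warmup iterations, all
driven by one integer seed; a fit is *converged* when every parameter has
split-$\hat R \le 1.01$ and effective sample size $\ge 400$. A fit
violating the $\hat R$ bound warns rather than failing, and the flag is
carried in `glance()`. With few trials or deliberately reduced draws the
flag trips occasionally near 1.01–1.03; that is the diagnostic doing its
job, not an error state.

**HPD intervals** follow the narrowest-window definition: the shortest
contiguous run of $\lceil 0.95 n \rceil$ sorted draws. Because the window
width is nearly flat around its minimum, the raw argmin wobbles; the
implementation minimizes a locally averaged width (window one tenth of the
candidate range), which stabilizes the interval position materially at
large $n$ without changing what is estimated. Calibration on $10^6$
standard-normal draws reproduces $(-1.96, 1.96)$ within ±0.02 (asserted in
the acceptance tests). Constant draws yield a zero-width interval; fewer
than 100 draws are refused.

**Seed policy.** A single root seed is expanded deterministically — via a
string hash of (participant, task, day, session) for the simulator, and of
the chain index for the sampler — so any subset of a run can be reproduced
in isolation and equal seeds give bit-identical outputs.

## What the simulator emulates, and what it does not

`echo_design()` defaults encode the reference protocol: distances 1.00,
1.36, …, 4.25 m; 4 days × 10 sessions × 50 trials per task; each session an
independently shuffled sequence with every distance exactly 5 times;
detection stimuli drawn left/right/absent with probabilities
0.25/0.25/0.5 and localization left/right 0.5/0.5; day 1 treated as
practice and dropped by `analysis_subset()`, leaving 150 analysis trials
per distance, task and participant (3,000 per participant). Reflector sides
are drawn i.i.d. per trial — no counterbalancing is imposed, since none is
specified for the protocol; whether the real apparatus balanced sides
within sessions is unknown, and the i.i.d. assumption is the weaker one.

The generative observer is exactly the fitted observation model. That makes
parameter-recovery simulations a clean test of the estimation machinery —
the acceptance suite simulates 20 replicate participants from the
exponential observer $(\alpha_0, \alpha_1, \beta_0, \beta_1, c_0, c_1) =
(3, -0.4, 2, -0.6, 0.1, -0.2)$, chosen as a realistic profile (strong
near-field detection decaying over the rail, weaker and faster-decaying
localization, near-neutral criteria), and requires each parameter's 95%
HPD to cover the truth in at least 17 of 20 replicates. But it also bounds
what passing says about real data: real listeners lapse, drift across
sessions and days, and may violate the equal-variance assumption; none of
that is generated, so the tests certify the statistics, not the psychology.
Day-to-day learning in particular is absent — the practice-day exclusion is
reproduced as a design rule, not as a performance difference.

## Group-level analysis

`rm_anova()` runs the classical 2 (Task) × 10 (Distance) within-subject
ANOVA on the grid of per-participant $d'$ point estimates, each effect
tested against its own effect-by-subject interaction, with partial
$\eta^2 = SS_{\text{effect}} / (SS_{\text{effect}} + SS_{\text{error}})$.
Two deliberate choices:

* **Categorical point estimates as input.** The grid is built from the
  Model-1 medians (`estimate_grid()`): they are the assumption-free
  "observed" values, whereas Model-2 estimates already impose the
  exponential shape the ANOVA would then partly re-discover.
* **No sphericity correction.** Reported degrees of freedom are the
  uncorrected ones — $(1, n-1)$, $(9, 9(n-1))$, $(9, 9(n-1))$ for $n$
  participants — matching standard practice for this design's reporting.
  An $F$-tail $p$-value is supplied for convenience.

Participant exclusion (for instance re-running without an outlying
listener) is a plain row filter on the estimate grid, not a special mode.
Degenerate grids are handled explicitly: constant estimates are an error
(no error variance, $F$ undefined), while an effect whose sums of squares
vanish exactly in an otherwise variable grid is reported as a null effect
($F = 0$, partial $\eta^2 = 0$) rather than as a 0/0 artifact.

## Echo-delay geometry

`predicted_ici()` idealizes the source–listener–reflector arrangement as
collinear: the reflected path exceeds the direct path by twice the
speaker-to-disk distance, so the interclick interval is
$1000 \cdot 2 (d_{\text{disk}} - d_{\text{speaker}}) / v$ ms and its slope
in disk distance is $2000 / v$ ms/m — 5.8 ms/m at the default 343 m/s
(dry air, 20 °C; the rounding to one decimal is robust across
340–346 m/s). The small lateral disk offset used to make left/right
positions possible changes path lengths by well under 5% and is ignored.
Measured intercepts additionally reflect the exact speaker and microphone
placement, so only the slope, not the intercept, should be compared against
measurements.

## Problem sizes used in the checks

The test suite runs entirely on synthetic data generated at test time.
Sizes were chosen to make each check sharp at interactive runtimes: full
default-design participants (3,000 analysis trials) for fit structure,
contrasts and recovery; $n = 10{,}000$ per cell for the closed-form
equivalence bound of 0.05; $10^5$–$10^6$ draws for law-of-large-numbers and
HPD calibration checks; 20 replicate participants at 2 chains × 750 draws
for coverage. A complete two-model fit of one participant takes a few
seconds on one CPU at default settings.

## Known limitations

* Equal-variance SDT only: no unequal-variance extension, ROC fitting or
  confidence ratings.
* No hierarchical pooling across participants — each listener is fitted
  independently, which is the right default for strongly heterogeneous
  echolocation abilities but forgoes shrinkage when participants are
  similar.
* No model comparison machinery (WAIC/LOO); the categorical/exponential
  pair is compared informally through their overlaid predictions.
* The Metropolis sampler is tailored to these low-dimensional, smooth
  posteriors; it is not a general-purpose replacement for gradient-based
  samplers in larger models.
* Acoustics are reduced to the collinear delay geometry: no sound-level,
  masking or binaural modeling.
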