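---
title: "Reverse correlation of larval navigation with LNP models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse correlation of larval navigation with LNP models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(navlnp)
```

## The model

Crawling *Drosophila* larvae navigate by alternating relatively straight
*runs* with reorienting *turns*; each turn is built from one or more
side-to-side *head sweeps*, and a sweep in a favourable direction is
*accepted*, launching the next run. `navlnp` treats the decision to initiate
a turn as a Linear–Nonlinear–Poisson (LNP) cascade:

1. **Linear stage.** The time derivative of the stimulus (light intensity,
   or optogenetically induced receptor activity) is convolved with a kernel
   $A(\tau)$ supported on the previous few seconds:
   $x(t) = \int_0^\infty A(\tau)\, S(t-\tau)\, d\tau$. The kernel is scaled
   so that $x$ has unit variance over the whole stimulus history.
2. **Nonlinear stage.** The instantaneous turn rate is a static function of
   the filter output. Because the stimulus ensemble of $x$ is standard
   normal by construction, a Gaussian turn-triggered ensemble with mean
   $\mu$ and sd $\sigma$ implies the *ratio-of-Gaussians* rate
   $$ r_{ROG}(x) = \bar r\,
      \frac{e^{-(x-\mu)^2/2\sigma^2}}{\sigma\, e^{-x^2/2}}, $$
   where $\bar r$ is the overall turn rate per second of run time.
3. **Poisson stage.** Turns are initiated stochastically: the probability of
   at least one turn in a frame of length $\Delta t$ is $1 - e^{-r\Delta t}$
   (behaviour is sampled at 14 frames/s, $\Delta t = 1/14$ s).

For two simultaneous channels (fictive odor $x_O$ and light $x_L$) the
package implements the two competing integration rules:

* **independent pathways** — $r(x_O, x_L) = f(x_O) + g(x_L)$, a sum of two
  single-channel ratio-of-Gaussians rates (6 parameters), and
* **early linear combination** —
  $r(x_O, x_L) = h(\cos\theta\, x_O + \sin\theta\, x_L)$, a single
  ratio-of-Gaussians rate applied to one weighted combination
  (4 parameters; $\theta = 0$ means odor only, $\theta = 90^\circ$ light
  only).

Both are fit by maximising the point-process log-likelihood
$$ \log P(\text{data}\mid\text{model}) = \sum_{\text{turn}} \log(r\Delta t)
   - \sum_{\text{no turn}} r\Delta t, $$
where the no-turn sum runs over run frames only (larvae mid-turn cannot
initiate another turn), and compared with the Akaike relative likelihood
$e^{(\mathrm{AIC}_b - \mathrm{AIC}_a)/2}$.

## Estimators

* `triggered_average()` — the turn-triggered average (TTA) of the stimulus
  derivative in 0.1 s lag bins, half-open on the left (the −1 s bin collects
  lags in (−1.05, −0.95] s). For white-derivative stimuli the negative-lag
  TTA is proportional to the kernel reversed in lag; positive lags are a
  causality control. Variants sort turns by size (threshold at the rms
  heading change) or align to accepted/rejected first head sweeps.
* `fit_kernel()` — smooths the negative-lag TTA with the impulse response of
  a third-order linear system. Two parameterisations are tried (a damped
  cosine $c\,t\,e^{-t/\tau}\cos(\omega t + \phi)$ and the critically damped
  $c\,t^2 e^{-t/\tau}$) and the lower-residual fit kept; if neither
  converges, the empirical TTA is lightly smoothed (Gaussian, σ = 0.2 s)
  and the fit flagged. The fit is *only* a smoother; no biophysical meaning
  is attached to its parameters, and positive lags never enter.
* `apply_filter()` — causal discrete convolution, lags starting one sample
  back (a decision never sees the intensity change within its own frame),
  normalised to unit output variance; frames with incomplete kernel support
  are flagged invalid rather than zero-padded.
* `binned_turn_rate()` / `fit_rog()` — the nonlinearity, either binned
  ($r = N_{turn}/(N_{all}\Delta t)$ in 0.25-wide bins of $x$, exposure
  counted over run frames) or as direct moments of the turn-triggered
  ensemble. The binned standard error is the counting error
  $\sqrt{N_{turn}}/(N_{all}\Delta t)$.
* `predict_step_response()` — the deterministic LNP prediction on a square
  wave, using the kernel calibration from the reverse-correlation stimulus
  and folding the prediction cyclically.
* `cross_moment()`, `kl_divergence()`, `quadrant_attention()` — the
  multisensory diagnostics: the turn-triggered product moment
  $E[x_O x_L \mid \text{turn}]$ (identically zero for independent pathways,
  $\cos\theta\sin\theta(\sigma^2+\mu^2-1)$ for the linear combination),
  nonparametric information measures, and the quadrant-wise test for
  attentional shifts in head-sweep acceptance.

## The virtual larva

`simulate_larva()` generates event streams from a ground-truth model so that
every estimator can be validated without recordings. Its defaults are the
study conditions end to end: Brownian intensity walks (σ = 3 levels per
update at 112 Hz, reflecting boundaries on [0, 255], giving diffusion
constant 504 levels²/s), behaviour at 14 frames/s, 50 tracks over a 20-min
stimulus, turn durations lognormal with mean ≈ 2 s, head-sweep durations
Gamma with mean 1.25 s, and baseline turn rates of order 0.05–0.1/s
(thousands of turns per tens of larva-hours).

Two behavioural couplings have no published quantitative form and are the
simulator's own, deliberately simple, inventions (flagged as such):

* **turn size** — the probability of drawing from the "large" magnitude
  distribution grows logistically with the mean unfavorable drive over the
  12 s preceding the turn (the slow-drift dependence seen in size-sorted
  TTAs);
* **head-sweep acceptance** — a sweep is accepted with probability
  `plogis(gain * fav + offset)` where `fav` is minus the mean unfavorable
  drive during the sweep; rejected sweeps spawn another, up to a cap.

In multimodal simulations both rules read the *same* linear combination
$u = \cos\theta\,x_O + \sin\theta\,x_L$ that drives turn initiation — the
shared-pathway ground truth against which the quadrant analysis is checked.

### What the simulator does and does not emulate

It reproduces the statistical structure the estimators rely on: Poisson
turn initiation from a filtered Gaussian stimulus, state exclusivity
(run/turn/head sweep), multiple tracks sharing one stimulus, and
stimulus-coupled sizes and acceptances. It does **not** model spatial
trajectories, head-angle kinematics, speed modulation, cross-talk between
light channels, or tracker artefacts (lost/merged tracks, segmentation
errors). Passing recovery tests therefore demonstrates estimator
correctness under the model's assumptions, not robustness to real-world
tracking noise.

## Numerical choices and caveats

* **Two sampling regimes.** With realistic ~2 s turns, time spent mid-turn
  is excluded from exposure. Because turns preferentially follow high-drive
  excursions and the filtered signal stays correlated for ~1 s, the
  run-frame ensemble is slightly depleted of high-drive frames. The
  likelihood conditions on the realised exposure, so maximum-likelihood
  fits recover generating parameters essentially unbiased; raw
  turn-triggered moments (`fit_rog()`, `cross_moment()`) are attenuated by
  several percent. Closed-form Gaussian predictions for the turn-triggered
  ensemble are exact only in the limit of negligible turn occupancy, so
  consistency tests against those closed forms use configurations with
  turn durations far below one frame, while parameter-recovery tests under
  realistic occupancy rely on the maximum-likelihood route.
* **Finite stimulus realizations.** The ratio-of-Gaussians rate with
  σ < 1 grows as $e^{(1-\sigma^{-2}/...)x^2}$ in the tails, so tail-weighted
  moments (notably the cross moment) have realization noise that decays only
  as the inverse square root of total stimulus time; null-hypothesis checks
  at the 0.02 scale use tens of larva-hours.
* **Derivative grid.** Forward difference assigned to the left endpoint,
  used consistently by the filter (which starts at lag one sample) and all
  triggered averages. Only consistency between simulator and estimators
  matters; no claim is made about the camera's exposure phase.
* **Reflection and rounding.** Proposals are reflected (iteratively if
  needed) while the walk is generated; the completed real-valued sequence is
  rounded half-away-from-zero once at the end.
* **Binned-rate errors.** The standard error uses the counting convention
  $\sqrt{N_{turn}}/(N_{all}\Delta t)$.
* **Optimisation.** Both multimodal fits run L-BFGS-B with analytic
  gradients on log-transformed positive parameters, from a moment-based
  start plus random perturbations (5 starts), with bounds
  $\bar r \in (e^{-20}, e^5)$, $\mu \in (-5, 5)$, $\sigma \in (0.05, 3)$,
  $\theta \in [0^\circ, 90^\circ]$. A rate of zero at an observed turn
  reports a −∞ log-likelihood with a diagnostic rather than an error.
* **Angle conventions.** Degrees in every interface, radians internally.
  Quadrant boundaries (a filtered value exactly 0) go to the positive side —
  a measure-zero event under the model.
* **k-NN divergence.** The nearest-neighbour estimator with k = 4 (the
  usual default in the estimator literature; exposed as an argument).
  Negative small-sample estimates are reported as-is. Coincident points are
  broken by a tiny jitter with a warning. The Gaussian-analytic route is a
  cross-check, appropriate because both the stimulus and turn-triggered
  ensembles are near-Gaussian by design.
* **Raw-coordinate rotation** reuses the angle fitted in filtered space (a
  refit is possible by passing a different angle); the odor signal is the
  *negated* normalised red-light derivative.
* **Pooling.** When several stimulus segments are analysed together, the
  filter normalisation uses the pooled stimulus history.
* **Edge handling.** Triggers whose lag window leaves the recorded signal
  are dropped and counted; frames with incomplete kernel support are
  invalid, never zero-padded.

## Problem sizes

The validation suite simulates tens of larva-hours per scenario — e.g.
50–100 tracks over 20–40 min stimuli (≈5,000–10,000 turns) for parameter
recovery and model selection, and ~32 larva-hours of Poisson-sampled
exposure for the cross-moment null — sizes chosen to put Monte-Carlo error
comfortably inside each test's tolerance while remaining desk-scale.

## A worked unimodal run

```{r example, eval = FALSE}
stim <- brownian_stimulus(1200, sigma = 3, seed = 1, channel = "red")
sig  <- resample_to_frames(stim_derivative(stim, sign = -1))  # fictive odor

truth <- lnp_model("unimodal", default_kernel(), rog_nl(0.1, 1, 0.8))
sim <- simulate_larva(truth, list(x = sig),
                      behavior_config(n_tracks = 50, seed = 2))

tta <- triggered_average(sim$events, sig)
kf  <- fit_kernel(tta)
x   <- apply_filter(kf$kernel, sig)
fit <- fit_rog(x, sim$events)
tidy(fit)
autoplot(tta)
autoplot(binned_turn_rate(x, sim$events), nl = fit$nl)
```

## Known limitations

* The moment-route nonlinearity estimates inherit the run-ensemble
  depletion bias described above (a property of the estimator definition,
  shared with any analysis that conditions exposure on run state).
* The head-sweep and turn-size generative rules are plausible placeholders,
  not fitted to data; only their qualitative structure (monotone coupling to
  the shared drive) should be relied on.
* KL divergences between high-dimensional or strongly non-Gaussian
  ensembles would need larger samples than the defaults used here; the
  package only exercises 1D and 2D cases.
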