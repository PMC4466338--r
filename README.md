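# navlnp

Reverse-correlation analysis of *Drosophila* larva navigation with
Linear–Nonlinear–Poisson (LNP) models.

Larvae crawl in runs punctuated by turns; each turn probes directions with
head sweeps that are accepted or rejected. When the stimulus is a Brownian
intensity walk — whose derivative is white on all time scales — the decision
to turn can be reverse-correlated: the turn-triggered average (TTA) of the
stimulus derivative recovers the linear filter $A(\tau)$, and the turn rate
as a function of the unit-variance filter output $x$ follows a
ratio-of-Gaussians nonlinearity

$$ r_{ROG}(x) = \bar r \, \frac{e^{-(x-\mu)^2/2\sigma^2}}{\sigma\,e^{-x^2/2}},
\qquad \bar r = \frac{N_{turn}}{T},\; \mu = E[x \mid turn],\;
\sigma^2 = E[(x-\mu)^2 \mid turn]. $$

With two simultaneous channels (fictive odor $x_O$, light $x_L$) the package
asks *how* the cues are integrated, fitting and comparing by maximum
likelihood and AIC:

* **independent pathways** (6 parameters): $r = f(x_O) + g(x_L)$, which
  forces $E[x_O x_L \mid turn] = 0$;
* **early linear combination** (4 parameters):
  $r = h(\cos\theta\,x_O + \sin\theta\,x_L)$, under which the rotated
  coordinate $u$ carries all the information about turning and its
  orthogonal partner $v$ none.

The package is aimed at computational neuroethologists who want a tested,
reusable implementation of this analysis: a synthetic "virtual larva"
(runs, turns, head sweeps driven by a ground-truth LNP model), the
estimators (TTA, kernel smoothing by a third-order impulse response, binned
and moment nonlinearities, step-response prediction), the multisensory
machinery (turn-triggered ensembles, cross-moment diagnostic,
maximum-likelihood fits, coordinate rotation, k-NN and Gaussian-analytic
Kullback–Leibler divergences, quadrant attention analysis), and CSV/JSON
round-trip formats with an end-to-end pipeline.

## A worked example

```r
library(navlnp)

# 20-min Brownian red-light stimulus; fictive odor = negated derivative
stim <- brownian_stimulus(1200, sigma = 3, seed = 1, channel = "red")
sig  <- resample_to_frames(stim_derivative(stim, sign = -1))

truth <- lnp_model("unimodal", default_kernel(), rog_nl(0.1, 1, 0.8))
sim <- simulate_larva(truth, list(x = sig), behavior_config(n_tracks = 50, seed = 2))
sim
#> <larva_sim> unimodal model: 50 tracks, 4657 turns, 8865 head sweeps

tta <- triggered_average(sim$events, sig)
kf  <- fit_kernel(tta)
x   <- apply_filter(kf$kernel, sig)
fit <- fit_rog(x, sim$events)
fit
#> <rog_fit> rbar 0.09487 /s, mu 0.958, sigma 0.841 (4657 turns, 49088 s run time)
```

The recovered kernel correlates with the generating kernel at r > 0.95, and
the nonlinearity parameters land within a few percent of the generating
(0.1, 1, 0.8); the baseline rate and turn-triggered mean sit slightly low
because frames spent mid-turn are excluded from exposure (see the vignette;
the maximum-likelihood fits do not share this attenuation). Plots:
`autoplot(tta)`, `autoplot(binned_turn_rate(x, sim$events), nl = fit$nl)`.

For two channels:

```r
ens  <- build_ensemble(events, x_odor, x_light)
cross_moment(ens)                    # ~0 for independent pathways
flin <- fit_linear_combination(ens)  # 4-parameter fit, angle theta
find <- fit_independent(ens)         # 6-parameter fit
aic_compare(find, flin)              # Akaike relative likelihood
```

A thin command-line wrapper for stimulus generation, simulation and the
pipeline lives in `inst/scripts/navlnp.R`.

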