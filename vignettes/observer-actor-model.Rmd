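---
title: "The Bayesian observer–actor model behind timepriors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Bayesian observer–actor model behind timepriors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(timepriors)
```

## The generative model

On each trial of a motor-sensory reproduction task a target duration $x$
is drawn from a discrete block distribution $p(x)$ (durations 75 ms
apart). The observer forms a noisy internal measurement

$$x_m \sim p_s(x_m \mid x) = \mathcal{N}\!\big(x_m;\, x,\, \sigma_s(x)\big),$$

where $\sigma_s(x) = w_s\,x$ for *scalar* noise (constant coefficient of
variation, the Weber-like regime of interval timing) or
$\sigma_s = w_s \times 787.5$ ms for *constant* noise. The observer then
chooses the reproduction that minimizes the subjectively expected loss,

$$u^*(x_m) \;=\; \arg\min_u \int\!\!\int \tilde f^2(r, x)\;
p_m(r \mid u)\; \pi(x)\, p_s(x_m \mid x)\; \mathrm{d}r\, \mathrm{d}x,$$

with $\pi(x)$ the *subjective* prior (which need not equal $p(x)$),
$\tilde f$ the subjective error map, and $p_m(r \mid u) =
\mathcal{N}(r; u, \sigma_m(u))$ the motor likelihood (again constant or
scalar, coefficient $w_m$). The observed response is distributed as

$$p(r \mid x) \;=\; \int p_s(x_m \mid x)\; p_m\!\big(r \mid u^*(x_m)\big)\,
\mathrm{d}x_m,$$

optionally mixed with a uniform lapse component of rate $\lambda$. Note
that $p(x)$ itself never enters $p(r \mid x)$: behaviour depends only on
the internal representations.

### Model components

* **Error maps** (squared to obtain the loss): Standard $r - x$,
  Fractional $(r-x)/x$, and Skewed $(r-x)/r$. The skewed map is
  denominated in the response, producing the response-dependent asymmetry
  used as feedback in some blocks; the fractional map is close to a
  logarithmic loss for small errors, since $(r-x)/x = \log(r/x) +
  O(\epsilon^2)$. `LossSpec` carries a free exponent for non-quadratic
  variants, but the default comparison set is quadratic only — the
  non-quadratic family multiplies the model space without closed forms.
* **Candidate priors** (schemes a–g, `make_candidate_prior()`): the true
  discrete distribution (a); a moment-matched Gaussian (b); mixtures of
  37.5-ms or 75-ms kernels at the true support with the true weights
  (c, d); a continuous uniform over the range (e); and peak-emergence
  mixtures (f, g) placing a narrow Gaussian at each mode with weight equal
  to the probability mass emerging above the uniform background
  (computed as exact rationals: 1/2 for the Peaked block, 3/4 for
  High-Peaked, 1/4 per mode for Medium Bimodal, 9/28 per mode for Wide
  Bimodal) plus a broad background Gaussian at the range mean with the sd
  of the discrete uniform over the range. The narrow sds are 37.5/75 ms
  (61.2/122.4 ms for the Wide range, the sd of three 75-ms-spaced
  points).

### Decision rule: closed forms and the numeric path

For quadratic losses the inner integrals reduce to posterior moments of
$x$ given $x_m$:

* standard loss: $u^* = \mathbb{E}[x \mid x_m]$ (constant motor noise) or
  $\mathbb{E}[x \mid x_m] / (1 + w_m^2)$ (scalar);
* fractional loss: $u^* = \mathbb{E}[x^{-1} \mid x_m] \,/\,
  \big(c\,\mathbb{E}[x^{-2} \mid x_m]\big)$ with $c = 1 + w_m^2$ for
  scalar motor noise;
* skewed loss: the expected loss is $1 - 2\,\mathbb{E}[x \mid x_m]\,
  g_1(u) + \mathbb{E}[x^2 \mid x_m]\, g_2(u)$ with $g_k(u) =
  \mathbb{E}[r^{-k} \mid u]$; $g_1, g_2$ are tabulated on a dense action
  grid once per motor model and the minimum refined by a three-point
  parabola.

`decision_rule(method = "numeric")` instead minimizes `expected_loss()`
by bounded golden-section search on [150, 1800] ms; the two routes are
required to agree within 0.5 ms where both apply, and that agreement is
part of the test suite.

## Numerical conventions

* **Duration grid.** All densities live on [150, 1800] ms — a superset of
  every block's allowed-response window — and are truncated and
  renormalized there (this includes scalar-noise Gaussians, whose mass
  below zero is thereby removed; at the noise levels of interest the
  affected mass is negligible). Public single-observer operations use
  1-ms grids.
* **Adaptive quadrature in the likelihood engine.** Evidence integration
  and MCMC evaluate the trial likelihood thousands of times, so the
  engine integrates over the measurement with 61 nodes spanning
  $x \pm 5\sigma_s$ and subsamples continuous priors to 5-ms steps. All
  Gaussian kernels involved have sds of at least ~30 ms at plausible
  parameters, so these grids resolve the integrands far below the
  statistical noise of any dataset; the 10⁶-draw forward-simulation
  χ² check in the acceptance suite validates the quadrature end to end.
* **Parameter integration.** The marginal likelihood integrates
  $(w_s, w_m)$ over independent Beta(1.3, 2.6) priors on a 60×60
  log-spaced grid over [0.01, 0.6]; each node carries the exact Beta
  mass of its log-spaced cell (endpoint cells absorb the tails), so a
  constant likelihood integrates exactly and the truncation introduces
  no offset. The Laplace route optimizes in $\log w$ coordinates
  (Jacobian included) from a coarse-scan start, with a finite-difference
  Hessian; a MAP near the grid edge flags the approximation unreliable.
  Likelihood tails that underflow at extreme nodes are floored at
  1e-300 so those nodes contribute essentially nothing rather than
  erroring.
* **Lapse marginalization.** A template may fix $\lambda$ or marginalize
  it uniformly over a small grid (e.g. 0, 0.01, 0.03, 0.1) inside the
  evidence integrand — a documented stand-in for treating $\lambda$ as a
  third free parameter, which would cube the integration cost for little
  gain at these data sizes.

## Nonparametric prior reconstruction

The log-prior is parameterized by its values at 10 control points (14 for
the Wide range) at 75-ms steps spanning the block range ±150 ms (Short
300–975, Medium 450–1125, Long 600–1275, Wide 300–1275 ms). Between
control points the log-density is interpolated by the posterior mean of a
GP with squared-exponential covariance — an interpolating device only,
not part of the inference. Defaults: length scale 100 ms (comparable to
the 75-ms control spacing: long enough to be smooth, short enough not to
erase structure at the spacing scale), signal sd 2 log-units, jitter
1e-6. Two consequences worth knowing:

* the GP mean is set 10 log-units below the *average control value*, so
  (i) the density decays to ~e⁻¹⁰ of typical levels within about one
  control spacing outside the range, and (ii) adding a constant to all
  control values shifts the whole log-density by that constant, which
  normalization absorbs — the posterior is exactly shift invariant;
* interpolating toward an offset mean produces a small between-node
  ripple (up to ~18% in density for a perfectly flat profile at these
  settings). The ripple is well below the 1.5× threshold used to call a
  reconstructed peak, and sensitivity to halving/doubling the length
  scale is limited to this cosmetic level.

Sampling uses coordinate-wise slice sampling (stepping-out, unit initial
width, at most 10 expansions per side, shrinkage acceptance) over the
control values, capped at |log value| ≤ 20 for numerical safety.

**Why a hyperprior is needed.** Prior structure finer than the
sensorimotor smoothing scale is barely identified: a comb of spikes
scores within a few log units of the generating flat prior even at 1000
trials, because kernels of 60–100 ms blur the decision rule and the
response density. Under a flat (capped) hyperprior the posterior is then
*entropically* dominated by sparse spike solutions — every control point
that carries no mass is unconstrained and contributes ~30 log-units of
free volume — and chains collapse onto arbitrary combs. The default
therefore adds a weak smoothness hyperprior: a Gaussian with the
interpolator's own squared-exponential covariance on the *mean-centered*
control values. Centering preserves exact shift invariance; the kernel
penalizes white-noise roughness much more than smooth large-amplitude
structure, so genuinely peaked or skewed priors remain representable
(density swings of e^±4 cost little along smooth directions).
`hyperprior = "flat"` restores the pure-likelihood posterior for
comparison. Chains start by default from a Gaussian moment-matched to
the retained responses (jittered per chain; `init = "random"` is
available) so that desk-scale budgets are spent in the data-relevant
basin.

The study-scale schedule is 10 chains × (3000 burn-in + 1500 saved) =
15 000 priors; the bundled validation studies use desk-scale schedules
(2 chains × a few hundred samples), which the split-$\hat R$ helper and
the seeded-replication tests show to be sufficient for moment-level
summaries at a few hundred trials. Fixed components (noise kinds,
$w_s, w_m$, loss) are taken from the model-comparison stage at the MAP by
default (`fixed_components_from_evidence()`; posterior-mean is available
as a switch — the two differ negligibly when the parameter posterior is
unimodal and tight, the regime in which fixing components is sensible at
all).

The point summary for plotting and peak diagnostics
(`posterior_mean_prior()`) is the average of the sampled *densities*:
the mean of the log control values is meaningless under shift
invariance. Moments of the reconstruction are always computed **per
sampled prior and then averaged**. The alternative — moments of the averaged density — is
biased: a mixture of light-tailed samples is itself heavy-tailed or
multimodal, which would manufacture exactly the kurtosis effects one
wants to measure. A constructed two-density example in the test suite
pins this distinction down.

## The synthetic-subject generator

`simulate_trials()` reproduces the statistical structure the analysis
assumes: targets come from runs of 84–96 trials containing each interval
in exact proportion (96 for High-Peaked, whose rare targets are each
preceded by 3–5 consecutive peak targets; 90 for Wide Uniform), responses
follow the observer's decision rule with truncated motor noise, lapses
replace the response with a uniform draw, and retention applies the
block-dependent windows (Short 225–1237, Medium 300–1462, Long 375–1687,
Wide 225–1687 ms; boundaries inclusive — the windows are wide, the
convention only needs fixing). `subsample_balanced()` equalizes
per-interval counts for non-uniform blocks (excluding Wide Bimodal, where
counts are already small). The default synthetic subject uses scalar
sensory and motor noise with $w_s = w_m = 0.1$ and a scheme-(c) smoothed
prior — the configuration the model comparison typically favours for
trained participants — with ~1000 trials on uniform blocks and ~500 on
peaked ones.

What the generator deliberately does **not** emulate: learning dynamics
(it simulates post-plateau behaviour only), hardware timestamp errors
(gross outliers are represented by lapses), feedback rendering, the
250-ms minimum wait, and any trial-to-trial carryover. Passing
recovery tests therefore show that the *analysis* is correct and
well-calibrated under the model's own assumptions — they cannot show that
human data satisfy those assumptions.

## Validation studies and problem sizes

The package ships its validation as code: `response_simulation_check()`
(10⁶-draw χ² against the generative chain, 30 equal-probability bins),
`component_recovery_study()` (confusion of 3 losses × 2 sensory kinds
over seeded subjects, Laplace evidence), and `prior_recovery_study()`
(moment recovery within 2 posterior sds; flat-prior data checked for
spurious multimodality). The test suite runs these at desk scale —
10 replicate seeds per truth cell for component recovery; 300–500 trials
and 2-chain × 200-sample MCMC for reconstruction — sizes chosen so the
whole suite completes in tens of minutes on one CPU while leaving each
check statistically meaningful. `scripts/acceptance.R` re-runs the same
battery and writes the numbers as JSON.

## Known limitations

* Sensory-kind identifiability at $w = 0.1$ on the Medium range is
  intrinsically weak for broad-prior subjects: constant-sensory models
  can trade noise into a free scalar motor coefficient. Recovery is
  reliable for subjects with structured (smoothed-discrete) priors; for
  broad Gaussian priors expect evidence gaps of only a few log units per
  1000 trials.
* Only Gaussian likelihoods are implemented; heavy-tailed variants are a
  hypothesis the model family cannot currently express.
* The observer is stationary: no sequential updating of the prior, no
  session effects.
* Priors are represented on a bounded grid; a subjective prior with
  substantial mass outside [150, 1800] ms (implausible for these tasks)
  would be truncated.
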