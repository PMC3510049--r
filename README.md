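# timepriors

Bayesian observer–actor models for motor-sensory time interval
reproduction, with marginal-likelihood model comparison and nonparametric
reconstruction of subjective priors.

## The problem

In interval reproduction experiments a participant experiences a target
duration *x* (drawn from a block-specific discrete distribution *p(x)* over
durations 75 ms apart) and reproduces it by holding a button for *r* ms,
receiving trial-by-trial error feedback. Responses show *central tendency*
(biases toward the mean of the contextual distribution) and *scalar
variability* (response sd grows with the interval). Both are signatures of
Bayesian integration: the observer combines a noisy measurement of the
interval with an internal (subjective) prior over durations, and acts to
minimize an internal loss shaped by the feedback.

This package implements that analysis end to end for researchers in
time-perception psychophysics and computational modelling:

1. **Forward model.** An ideal observer measures `x_m ~ p_s(x_m | x)`
   (Gaussian, sd either constant or proportional to the interval, with
   coefficient of variation `w_s`), picks the action minimizing the
   subjectively expected loss

   `u*(x_m) = argmin_u ∫∫ f̃²(r, x) p_m(r | u) π(x) p_s(x_m | x) dr dx`

   and produces `r ~ p_m(r | u*)` (Gaussian, coefficient `w_m`). The
   predicted response distribution is

   `p(r | x) = ∫ p_s(x_m | x) p_m(r | u*(x_m)) dx_m`,

   optionally mixed with a uniform lapse component (rate λ). Error maps
   f̃: Standard `r − x`, Fractional `(r − x)/x`, Skewed `(r − x)/r`.
   Candidate priors π range from the true discrete distribution through
   Gaussian and smoothed approximations to peak-emergence mixtures
   (schemes a–g).
2. **Model comparison.** Marginal likelihood of each observer model,
   integrating the trial likelihood over independent Beta(1.3, 2.6) priors
   on `(w_s, w_m)` by 2-D grid quadrature and by Laplace approximation;
   posterior component probabilities and Bayesian-model-averaged bias/sd
   curves (no point fitting).
3. **Prior reconstruction.** The log-prior is parameterized by 10 control
   points (14 for the Wide range) at 75-ms steps, interpolated with a
   squared-exponential Gaussian process, and sampled from
   `Pr(data | prior, model)` by coordinate-wise slice-sampling MCMC; the
   first four moments are computed per sampled prior and then averaged.
4. **Synthetic subjects.** A seeded generator reproduces the task's block
   designs (Uniform, Peaked, High-Peaked, Bimodal, Wide-Bimodal over
   Short/Medium/Long/Wide ranges), exact-proportion runs of 84–96 trials
   (with the High-Peaked "3–5 peak intervals before each rare target"
   constraint), lapses, and the block-dependent response-retention
   windows — so every stage is testable without human data.

## Worked example

```r
library(timepriors)

dist <- make_block_distribution("medium_peaked")
moments(dist)
#> mean 731.2 ms, sd 106.6 ms, skewness 1.14, ex. kurtosis 0.09

# an observer with scalar noise (w_s = w_m = 0.1), a smoothed prior and
# quadratic standard loss
obs <- observer_model(
  sensory = noise_model("scalar", w = 0.10),
  motor   = noise_model("scalar", w = 0.10),
  prior   = make_candidate_prior("c", "medium_peaked"),
  loss    = loss_spec("standard"))

bias_sd_curves(obs, dist)
#>     x  bias    sd
#> 1 600  43.2  69.1
#> 2 675   3.5  77.3
#> 3 750 -21.5  94.0
#> 4 825 -31.7 108.9
#> 5 900 -43.7 112.2
#> 6 975 -69.3 108.6
```

Short intervals are over-reproduced and long ones under-reproduced
(central tendency), the bias is nearly zero at the 675-ms peak the prior
over-weights, and the response sd grows with the interval (scalar
property) with a dip near the peak — the bias–variance trade-off of a
peaked prior.

```r
# simulate that observer and ask the model comparison who generated it
tr <- simulate_trials(block_design("medium_peaked", "standard"), obs,
                      n_trials = 500, seed = 1)
space <- model_space(sensory = c("constant", "scalar"), motor = "scalar",
                     prior_schemes = "c", losses = c("standard", "skewed"))
evs <- lapply(space, function(tp)
  marginal_likelihood(tr, tp, method = "laplace"))
evidence_table(evs)[, c("sensory", "loss", "log_evidence", "posterior")]
#>    sensory     loss log_evidence posterior
#> 1 constant standard        -2942  4.04e-01
#> 2   scalar standard        -2942  5.96e-01
#> 3 constant   skewed        -2975  1.88e-15
#> 4   scalar   skewed        -2974  5.41e-15
modal_components(evs)
#>  sensory    motor prior_scheme     loss
#> "scalar" "scalar"          "c" "standard"
```

The skewed-loss models lose by ~33 log units; the sensory-noise kind is
identified correctly but (on a single 500-trial block) far less
decisively — which is exactly why the package also provides
`component_recovery_study()` to measure recovery rates over many seeded
subjects, and `slice_sample_priors()` / `prior_recovery_study()` for the
nonparametric prior stage.

A thin command-line wrapper over the same pipeline lives at
`inst/cli/timepriors.R` (verbs `simulate`, `compare`, `reconstruct`,
`report`), driven by a YAML config; see `?run_pipeline`.

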