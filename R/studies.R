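# Parameter- and component-recovery studies on synthetic subjects. These
# are the package's built-in validation experiments: they generate data
# from known observers and check that the analysis recovers the truth.

#' Simulate one synthetic subject over several blocks
#'
#' The default subject follows the configuration most supported in the
#' task: scalar sensory and motor noise with coefficient 0.1, a smoothed
#' approximation of the block distribution as prior (scheme `"c"`), and the
#' loss matching the feedback regime. Trial counts default to the analysed
#' sizes of the task: about 1000 for uniform blocks and 500 for peaked
#' ones.
#'
#' @param blocks Character vector of block names.
#' @param sensory_kind,motor_kind Noise kinds.
#' @param w_s,w_m Coefficients of variation.
#' @param prior_scheme Truth prior scheme (per block).
#' @param loss Truth loss kind.
#' @param n_trials Per-block trial counts (recycled).
#' @param lapse_rate Truth lapse rate.
#' @param seed Integer seed.
#' @return A combined trial table.
#' @export
simulate_subject <- function(blocks = c("medium_uniform", "medium_peaked"),
                             sensory_kind = "scalar", motor_kind = "scalar",
                             w_s = 0.1, w_m = 0.1, prior_scheme = "c",
                             loss = "standard",
                             n_trials = ifelse(grepl("uniform", blocks),
                                               1000, 500),
                             lapse_rate = 0, seed = 1L) {
  n_trials <- rep(n_trials, length.out = length(blocks))
  out <- lapply(seq_along(blocks), function(i) {
    bn <- blocks[i]
    truth <- observer_model(noise_model(sensory_kind, w_s),
                            noise_model(motor_kind, w_m),
                            make_candidate_prior(prior_scheme, bn),
                            loss_spec(loss), lapse_rate = lapse_rate)
    as.data.frame(simulate_trials(block_design(bn, "standard"), truth,
                                  n_trials[i], seed = seed * 131L + i,
                                  subject_id = paste0("subject_", seed)))
  })
  tr <- do.call(rbind, out)
  class(tr) <- c("trial_set", "data.frame")
  tr
}

#' Component-recovery confusion study
#'
#' Generates synthetic subjects under every combination of loss kind and
#' sensory noise kind (scalar motor noise, `w_s = w_m = 0.1`, smoothed
#' prior, Medium Uniform + Medium Peaked blocks), runs the Bayesian model
#' comparison for each, and tabulates the modal posterior components.
#'
#' @param n_seeds Replicates per truth combination.
#' @param losses,sensory_kinds Truth levels crossed.
#' @param evidence_method Evidence route (`"laplace"` is the fast one).
#' @param seed Base seed.
#' @return Data frame with one row per replicate: truth levels, recovered
#'   modal levels, and logical `loss_ok`, `sensory_ok`.
#' @export
component_recovery_study <- function(n_seeds = 10,
                                     losses = c("standard", "fractional",
                                                "skewed"),
                                     sensory_kinds = c("constant", "scalar"),
                                     evidence_method = "laplace",
                                     seed = 1L) {
  combos <- expand.grid(loss = losses, sensory = sensory_kinds,
                        rep = seq_len(n_seeds), stringsAsFactors = FALSE)
  space <- model_space(sensory = c("constant", "scalar"), motor = "scalar",
                       prior_schemes = "c", losses = losses)
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    tr <- simulate_subject(sensory_kind = combos$sensory[k],
                           loss = combos$loss[k],
                           seed = seed + 7919L * k)
    evs <- lapply(space, function(tp) {
      marginal_likelihood(tr, tp, method = evidence_method)
    })
    mc <- modal_components(evs)
    data.frame(truth_loss = combos$loss[k],
               truth_sensory = combos$sensory[k],
               rep = combos$rep[k],
               modal_loss = mc[["loss"]],
               modal_sensory = mc[["sensory"]],
               modal_motor = mc[["motor"]],
               loss_ok = mc[["loss"]] == combos$loss[k],
               sensory_ok = mc[["sensory"]] == combos$sensory[k])
  })
  do.call(rbind, rows)
}

#' Prior-moment recovery study
#'
#' Simulates a subject with a known generative prior on one block, runs
#' the nonparametric reconstruction with the true noise/loss components
#' fixed, and compares the recovered posterior moments with the
#' generative ones.
#'
#' @param prior_scheme Generative prior scheme (`"b"` Gaussian, `"c"`
#'   smoothed discrete, `"e"` flat, ...).
#' @param block Block name.
#' @param n_trials Trials simulated.
#' @param chains,burn_in,keep MCMC schedule (desk-scale default).
#' @param w_s,w_m Truth coefficients (also used as the fixed components).
#' @param seed Integer seed.
#' @return List with `truth` (generative [moments()]), `summary` (the
#'   [summarize_prior_moments()] table), `within_2sd` (logical per moment
#'   for mean, sd, skewness), `sample` (the `prior_posterior_sample`).
#' @export
prior_recovery_study <- function(prior_scheme = "b",
                                 block = "medium_uniform", n_trials = 400,
                                 chains = 2, burn_in = 300, keep = 300,
                                 w_s = 0.1, w_m = 0.1, seed = 1L) {
  gen_prior <- make_candidate_prior(prior_scheme, block)
  truth <- observer_model(noise_model("scalar", w_s),
                          noise_model("scalar", w_m),
                          gen_prior, loss_spec("standard"))
  tr <- simulate_trials(block_design(block, "standard"), truth, n_trials,
                        seed = seed)
  fx <- fixed_components(noise_model("scalar", w_s),
                         noise_model("scalar", w_m), loss_spec("standard"))
  ps <- slice_sample_priors(tr, fx, chains = chains, burn_in = burn_in,
                            keep = keep, seed = seed + 1L)
  truth_mom <- moments(gen_prior)
  s <- summarize_prior_moments(ps)
  tv <- c(mean = truth_mom$mean, sd = truth_mom$sd,
          skewness = truth_mom$skewness)
  within <- vapply(names(tv), function(m) {
    row <- s[s$moment == m, ]
    abs(row$estimate - tv[[m]]) <= 2 * row$sd
  }, logical(1))
  list(truth = truth_mom, summary = s, within_2sd = within, sample = ps)
}

#' Forward-simulation check of the response distribution
#'
#' Compares the quadrature response density with a large Monte-Carlo
#' simulation of the generative chain (draw a measurement, apply the
#' decision rule, add motor noise, mix lapses): the simulated responses are
#' binned into equal-probability bins of the quadrature distribution and
#' tested with a chi-square goodness-of-fit test.
#'
#' @param model An [observer_model()].
#' @param x Target interval (ms).
#' @param n_draws Simulated trials.
#' @param bins Number of equal-probability bins.
#' @param seed Integer seed.
#' @return List with `norm_error` (deviation of the quadrature integral
#'   from 1), `p_value` (chi-square), and the bin `counts`.
#' @export
response_simulation_check <- function(model, x, n_draws = 1e6, bins = 30,
                                      seed = 1) {
  set.seed(seed)
  rd <- response_distribution(x, model)
  d <- rd$density
  n <- length(d)
  # trapezoid cumulative (not cumsum of node weights, which would shift
  # every quantile by half a grid cell)
  mass <- c(0, cumsum((d[-1] + d[-n]) / 2 * diff(rd$r)))
  norm_error <- abs(mass[n] - 1)
  cdf <- mass / mass[n]
  edges <- stats::approx(cdf, rd$r, xout = seq_len(bins - 1) / bins,
                         ties = "ordered")$y

  sds <- noise_sd(model$sensory, x)
  xm <- pmin(pmax(stats::rnorm(n_draws, x, sds), GRID_MIN), GRID_MAX)
  rule <- decision_rule(model, default_grid(1))
  u <- stats::approx(rule$xm_grid, rule$u_star, xout = xm, rule = 2)$y
  sdm <- noise_sd(model$motor, u)
  r <- stats::rnorm(n_draws, u, sdm)
  out <- which(r < GRID_MIN | r > GRID_MAX)
  while (length(out) > 0) {
    r[out] <- stats::rnorm(length(out), u[out], sdm[out])
    out <- out[r[out] < GRID_MIN | r[out] > GRID_MAX]
  }
  if (model$lapse_rate > 0) {
    lap <- stats::runif(n_draws) < model$lapse_rate
    r[lap] <- stats::runif(sum(lap), model$lapse_range[1],
                           model$lapse_range[2])
  }
  counts <- tabulate(findInterval(r, edges) + 1L, nbins = bins)
  test <- stats::chisq.test(counts, p = rep(1 / bins, bins))
  list(norm_error = norm_error, p_value = test$p.value, counts = counts)
}
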