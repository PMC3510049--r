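# Shared fixtures: small observers and trial sets built in code.

test_observer <- function(sensory_kind = "scalar", w_s = 0.1,
                          motor_kind = "scalar", w_m = 0.1,
                          scheme = "b", block = "medium_uniform",
                          loss = "standard", lapse_rate = 0) {
  observer_model(noise_model(sensory_kind, w_s),
                 noise_model(motor_kind, w_m),
                 make_candidate_prior(scheme, block),
                 loss_spec(loss), lapse_rate = lapse_rate)
}

# flat continuous prior over the whole duration grid
flat_grid_prior <- function(step = 1) {
  g <- default_grid(step)
  continuous_prior(g, rep(1, length(g)), label = "flat")
}

# toy trial table with hand-set responses (possibly none)
toy_trials <- function(responses, block = "medium_uniform", target = 750) {
  n <- length(responses)
  data.frame(subject_id = rep("toy", n), block = rep(block, n),
             session = rep(1L, n), run = rep(1L, n),
             trial_index = seq_len(n), target_ms = rep(target, n),
             response_ms = responses, retained = rep(NA, n),
             lapse = rep(FALSE, n))
}

# checks the High-Peaked ordering constraint: every non-peak target is
# immediately preceded by 3-5 consecutive peak targets (independent oracle
# based on run-length encoding)
high_peaked_constraint_ok <- function(run, peak = 675) {
  r <- rle(run == peak)
  n <- length(r$values)
  for (k in which(!r$values)) {
    if (r$lengths[k] > 1) return(FALSE)  # two adjacent rare targets
    if (k == 1) return(FALSE)            # rare target opens the run
    if (r$lengths[k - 1] < 3 || r$lengths[k - 1] > 5) return(FALSE)
  }
  all(r$lengths[!r$values] == 1)
}
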