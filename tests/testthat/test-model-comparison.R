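# Marginal likelihood, component posteriors and model averaging.

test_that("log likelihood is additive and order invariant", {
  tpl <- observer_template("scalar", "scalar", "b", "standard")
  empty <- toy_trials(numeric(0))
  empty$retained <- logical(0)
  expect_equal(log_likelihood(empty, tpl, 0.1, 0.1), 0)

  tr <- simulate_trials(block_design("medium_uniform", "standard"),
                        test_observer(), 100, seed = 21)
  ll <- log_likelihood(tr, tpl, 0.1, 0.1)
  doubled <- rbind(as.data.frame(tr), as.data.frame(tr))
  expect_equal(log_likelihood(doubled, tpl, 0.1, 0.1), 2 * ll,
               tolerance = 1e-9)
  shuffled <- tr[sample(nrow(tr)), ]
  expect_equal(log_likelihood(shuffled, tpl, 0.1, 0.1), ll,
               tolerance = 1e-9)
})

test_that("responses outside the duration grid are flagged", {
  tr <- toy_trials(c(700, 1900))
  tr$retained <- TRUE
  tpl <- observer_template()
  expect_error(log_likelihood(tr, tpl, 0.1, 0.1), "mismatch")
})

test_that("likelihood agrees with Monte-Carlo density estimates", {
  set.seed(31)
  truth <- test_observer(scheme = "c", block = "medium_uniform")
  tr <- simulate_trials(block_design("medium_uniform", "standard"),
                        truth, 20, seed = 31)
  tr <- tr[tr$retained, ]
  tpl <- observer_template("scalar", "scalar", "c", "standard")
  cache <- timepriors:::.likelihood_cache(tr, tpl)
  dens <- timepriors:::.cache_densities(cache, tpl, 0.1, 0.1)
  rule <- decision_rule(truth, default_grid(1))
  h <- 15
  for (b in seq_along(cache$blocks)) {
    blk <- cache$blocks[[b]]
    for (i in seq_along(blk$x)) {
      x <- blk$x[i]
      xm <- rnorm(2e5, x, 0.1 * x)
      u <- approx(rule$xm_grid, rule$u_star, xout = xm, rule = 2)$y
      r_sim <- rnorm(2e5, u, 0.1 * u)
      for (j in seq_along(blk$r[[i]])) {
        r0 <- blk$r[[i]][j]
        inside <- abs(r_sim - r0) < h
        phat <- mean(inside) / (2 * h)
        se <- sqrt(mean(inside) * (1 - mean(inside)) / 2e5) / (2 * h)
        # bin-averaged density vs point density: allow curvature slack
        expect_lt(abs(dens[[b]][[i]][j] - phat),
                  4 * se + 0.08 * dens[[b]][[i]][j])
      }
    }
  }
})

test_that("a constant likelihood integrates to itself", {
  empty <- toy_trials(numeric(0))
  empty$retained <- logical(0)
  tpl <- observer_template()
  ev <- marginal_likelihood(empty, tpl, method = "both", grid_n = 40)
  expect_equal(ev$log_evidence_grid, 0, tolerance = 1e-10)
  expect_equal(ev$log_evidence_laplace, 0, tolerance = 0.2)
})

test_that("evidence is invariant to trial order and drops with bad trials", {
  tr <- simulate_trials(block_design("medium_uniform", "standard"),
                        test_observer(), 150, seed = 41)
  tpl <- observer_template("scalar", "scalar", "b", "standard")
  e1 <- marginal_likelihood(tr, tpl, method = "laplace")
  shuffled <- tr[sample(nrow(tr)), ]
  e2 <- marginal_likelihood(shuffled, tpl, method = "laplace")
  expect_equal(e1$log_evidence_laplace, e2$log_evidence_laplace,
               tolerance = 1e-4)

  # trials essentially impossible under the family lower the evidence
  bad <- as.data.frame(tr)[1:5, ]
  bad$response_ms <- 1650
  worse <- marginal_likelihood(rbind(as.data.frame(tr), bad), tpl,
                               method = "laplace")
  expect_lt(worse$log_evidence_laplace, e1$log_evidence_laplace - 10)
})

test_that("component posteriors sum to one and collapse for one model", {
  tr <- simulate_trials(block_design("medium_uniform", "standard"),
                        test_observer(), 120, seed = 51)
  space <- model_space(sensory = "scalar", motor = "scalar",
                       prior_schemes = "b", losses = "standard")
  evs <- lapply(space, marginal_likelihood, trials = tr, method = "laplace")
  cp <- component_posteriors(evs)
  expect_equal(cp$loss$posterior, 1)
  expect_equal(cp$sensory$level, "scalar")
  mc <- modal_components(evs)
  expect_equal(unname(mc[c("sensory", "motor", "prior_scheme", "loss")]),
               c("scalar", "scalar", "b", "standard"))

  space2 <- model_space(sensory = c("constant", "scalar"), motor = "scalar",
                        prior_schemes = "b",
                        losses = c("standard", "skewed"))
  evs2 <- lapply(space2, marginal_likelihood, trials = tr,
                 method = "laplace")
  cp2 <- component_posteriors(evs2)
  for (fam in names(cp2)) {
    expect_equal(sum(cp2[[fam]]$posterior), 1, tolerance = 1e-9)
  }
})

test_that("exact component ties break toward the simpler level", {
  df <- data.frame(sensory = c("constant", "scalar"),
                   motor = "scalar", prior_scheme = "b",
                   loss = c("skewed", "standard"),
                   log_evidence = c(-100, -100))
  mc <- modal_components(df)
  expect_equal(unname(mc[["sensory"]]), "constant")
  expect_equal(unname(mc[["loss"]]), "standard")
})

test_that("model averaging reduces to the dominant model's curve", {
  tr <- simulate_trials(block_design("medium_uniform", "standard"),
                        test_observer(), 200, seed = 61)
  tpl <- observer_template("scalar", "scalar", "b", "standard")
  ev <- marginal_likelihood(tr, tpl, method = "grid", grid_n = 25)
  bma1 <- model_average_curves(list(ev), "medium_uniform", r_step = 5)

  # adding a hopeless competitor (posterior ~ 0) must not move the curve
  tpl2 <- observer_template("scalar", "scalar", "e", "skewed")
  ev2 <- marginal_likelihood(tr, tpl2, method = "grid", grid_n = 25)
  stopifnot(ev$log_evidence - ev2$log_evidence > 7)  # posterior < 1e-3
  bma2 <- model_average_curves(list(ev, ev2), "medium_uniform", r_step = 5)
  expect_equal(bma2$bias, bma1$bias, tolerance = 1e-3)
  expect_equal(bma2$sd, bma1$sd, tolerance = 1e-3)

  # reordering the models cannot change the average
  bma3 <- model_average_curves(list(ev2, ev), "medium_uniform", r_step = 5)
  expect_equal(bma3$bias, bma2$bias, tolerance = 1e-12)
})

test_that("BMA curves track the generative observer's predictions", {
  truth <- test_observer(scheme = "b")
  tr <- simulate_trials(block_design("medium_uniform", "standard"),
                        truth, 400, seed = 71)
  tpl <- observer_template("scalar", "scalar", "b", "standard")
  ev <- marginal_likelihood(tr, tpl, method = "grid", grid_n = 25)
  bma <- model_average_curves(list(ev), "medium_uniform", r_step = 5)
  cur <- bias_sd_curves(truth, make_block_distribution("medium_uniform"))
  tr_ret <- tr[tr$retained, ]
  for (i in seq_along(cur$x)) {
    n_i <- sum(tr_ret$target_ms == cur$x[i])
    mc_se <- cur$sd[i] / sqrt(n_i)
    expect_lt(abs(bma$bias[i] - cur$bias[i]), 2 * mc_se)
  }
})

test_that("lapse-grid templates marginalize the lapse rate uniformly", {
  tr <- simulate_trials(block_design("medium_uniform", "standard"),
                        test_observer(lapse_rate = 0.03), 80, seed = 81)
  lgrid <- c(0, 0.01, 0.03, 0.1)
  tpl_g <- observer_template("scalar", "scalar", "b", "standard",
                             lapse_rate = NULL, lapse_grid = lgrid)
  ll_marg <- log_likelihood(tr, tpl_g, 0.1, 0.1)
  ll_fixed <- vapply(lgrid, function(lam) {
    log_likelihood(tr, observer_template("scalar", "scalar", "b",
                                         "standard", lapse_rate = lam),
                   0.1, 0.1)
  }, numeric(1))
  # log mean exp of the fixed-lapse likelihoods
  m <- max(ll_fixed)
  expect_equal(ll_marg, m + log(mean(exp(ll_fixed - m))), tolerance = 1e-9)
})
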