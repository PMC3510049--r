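# Observer-actor core: likelihoods, error maps, optimal action, response
# distribution and predicted bias/SD curves.

test_that("sensory and motor likelihoods have the stated sds", {
  const <- noise_model("constant", 0.1)
  expect_equal(sensory_density(800, 800, const),
               dnorm(800, 800, 78.75))  # 0.1 x 787.5 ms at every interval
  expect_equal(sensory_density(700, 500, const), dnorm(700, 500, 78.75))

  scal <- noise_model("scalar", 0.1)
  expect_equal(sensory_density(850, 800, scal), dnorm(850, 800, 80))
  expect_equal(motor_density(850, 800, scal), dnorm(850, 800, 80))
  expect_error(sensory_density(700, -5, scal), "nonpositive")

  g <- default_grid()
  integ <- sum(trapz_weights(g) * sensory_density(g, 800, scal))
  expect_equal(integ, 1, tolerance = 1e-6)
})

test_that("error maps produce the stated signed errors", {
  expect_equal(error_map(900, 800, loss_spec("standard")), 100)
  for (kind in c("standard", "fractional", "skewed")) {
    expect_equal(error_map(750, 750, loss_spec(kind)), 0)
  }
  expect_equal(error_map(900, 800, loss_spec("fractional")), 100 / 800)
  expect_equal(error_map(900, 800, loss_spec("skewed")), 100 / 900)
  expect_error(error_map(-1, 800, loss_spec("skewed")), "undefined")
})

test_that("squared fractional error approximates squared log error", {
  # Taylor oracle: (r - x)/x = log(r/x) + O(eps^2)
  x <- 800
  r <- x * 1.05
  frac <- ((r - x) / x)^2
  lg <- log(r / x)^2
  expect_lt(abs(frac - lg) / lg, 0.11)
  r <- x * 1.005
  expect_lt(abs(((r - x) / x)^2 - log(r / x)^2) / log(r / x)^2, 0.011)
})

test_that("expected loss is minimized at the conjugate-Gaussian mean", {
  mu_p <- 800
  sd_p <- 100
  sd_s <- 60
  g <- default_grid(2)
  prior <- continuous_prior(g, dnorm(g, mu_p, sd_p))
  obs <- observer_model(noise_model("constant", sd_s / 787.5),
                        noise_model("constant", 1e-6),
                        prior, loss_spec("standard"))
  for (xm in c(650, 800, 950)) {
    want <- (sd_p^2 * xm + sd_s^2 * mu_p) / (sd_p^2 + sd_s^2)
    got <- optimize(function(u) expected_loss(u, xm, obs, r_step = 5),
                    interval = c(400, 1200))$minimum
    expect_equal(got, want, tolerance = 0.25)
  }
})

test_that("a noiseless observer with a flat prior reproduces its input", {
  obs <- observer_model(noise_model("scalar", 1e-6),
                        noise_model("scalar", 1e-6),
                        flat_grid_prior(), loss_spec("standard"))
  xm <- seq(500, 1100, by = 100)
  dr <- decision_rule(obs, xm)
  expect_equal(dr$u_star, xm, tolerance = 0.1)
})

test_that("the decision rule is monotone and shows central tendency", {
  obs <- test_observer("constant", 0.1, "constant", 0.1, scheme = "b")
  dr <- decision_rule(obs, seq(450, 1150, by = 10))
  expect_true(all(diff(dr$u_star) >= -1e-9))

  obs2 <- test_observer("scalar", 0.15, "scalar", 0.1, scheme = "b")
  xm <- c(620, 700, 900, 960)
  dr2 <- decision_rule(obs2, xm)
  mu <- moments(obs2$prior)$mean
  shrunk <- (dr2$u_star - xm) * sign(mu - xm)
  expect_true(all(shrunk > 0))            # pulled toward the prior mean
  expect_true(all(abs(dr2$u_star - mu) < abs(xm - mu)))
})

test_that("closed-form and numeric decision rules agree", {
  g <- default_grid(5)
  prior <- continuous_prior(g, dnorm(g, 787.5, 128.1))
  xm <- seq(550, 1050, by = 50)
  for (lk in c("standard", "fractional")) {
    obs <- observer_model(noise_model("scalar", 0.12),
                          noise_model("scalar", 0.08),
                          prior, loss_spec(lk))
    analytic <- decision_rule(obs, xm, method = "closed_form")$u_star
    numeric <- vapply(xm, function(x) {
      optimize(function(u) expected_loss(u, x, obs, r_step = 5),
               interval = c(150, 1800), tol = 1e-4)$minimum
    }, numeric(1))
    expect_equal(analytic, numeric, tolerance = 0.5)
  }
})

test_that("the response distribution normalizes and mixes lapses linearly", {
  obs <- test_observer()
  rd <- response_distribution(750, obs)
  expect_equal(sum(trapz_weights(rd$r) * rd$density), 1, tolerance = 1e-6)

  obs_l <- test_observer(lapse_rate = 0.5)
  rd_l <- response_distribution(750, obs_l)
  lap <- dunif(rd$r, 150, 1800)
  expect_equal(rd_l$density, 0.5 * rd$density + 0.5 * lap,
               tolerance = 1e-12)
})

test_that("bias is antisymmetric for a symmetric setup and zero at the mean", {
  g <- default_grid()
  prior <- make_candidate_prior("e", "medium_uniform")
  obs <- observer_model(noise_model("constant", 0.1),
                        noise_model("constant", 0.08),
                        prior, loss_spec("standard"))
  cur <- bias_sd_curves(obs, make_block_distribution("medium_uniform"))
  # support is symmetric about 787.5: bias(600 + d) = -bias(975 - d)
  expect_equal(cur$bias, -rev(cur$bias), tolerance = 0.05)

  obs_b <- observer_model(noise_model("constant", 0.1),
                          noise_model("constant", 0.08),
                          make_candidate_prior("b", "medium_uniform"),
                          loss_spec("standard"))
  rd <- response_distribution(787.5, obs_b)
  m1 <- sum(trapz_weights(rd$r) * rd$density * rd$r)
  expect_lt(abs(m1 - 787.5), 0.5)  # little bias at the prior mean
})

test_that("uniform-prior observers show the central-tendency bias pattern", {
  obs <- test_observer(scheme = "b")
  cur <- bias_sd_curves(obs, make_block_distribution("medium_uniform"))
  expect_gt(cur$bias[1], 0)                    # shortest pulled up
  expect_lt(cur$bias[nrow(cur)], 0)            # longest pulled down
})

test_that("a peaked prior reduces predicted sd near the peak", {
  flat <- test_observer(scheme = "b", block = "medium_uniform")
  peaked <- test_observer(scheme = "f", block = "medium_high_peaked")
  dist <- make_block_distribution("medium_high_peaked")
  sd_flat <- bias_sd_curves(flat, dist)$sd
  sd_peak <- bias_sd_curves(peaked, dist)$sd
  at_peak <- which(dist$support == 675)
  expect_lt(sd_peak[at_peak], sd_flat[at_peak])
})

test_that("quadrature bias/sd agree with Monte-Carlo simulation", {
  set.seed(42)
  obs <- test_observer(scheme = "c", block = "medium_peaked")
  des <- block_design("medium_peaked", "standard")
  tr <- simulate_trials(des, obs, 24000, seed = 99)
  tr <- tr[tr$retained, ]
  cur <- bias_sd_curves(obs, make_block_distribution("medium_peaked"))
  for (i in seq_along(cur$x)) {
    r <- tr$response_ms[tr$target_ms == cur$x[i]]
    se_bias <- sd(r) / sqrt(length(r))
    expect_lt(abs(mean(r) - cur$x[i] - cur$bias[i]), 3 * se_bias)
    se_sd <- sd(r) / sqrt(2 * (length(r) - 1))
    expect_lt(abs(sd(r) - cur$sd[i]), 3 * se_sd)
  }
})
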