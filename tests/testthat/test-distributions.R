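# Experimental distributions, candidate priors and their moments.

test_that("block distributions match the stated designs exactly", {
  mp <- make_block_distribution("medium_peaked")
  expect_equal(mp$support, seq(600, 975, by = 75))
  expect_equal(mp$probs, c(1 / 12, 7 / 12, 1 / 12, 1 / 12, 1 / 12, 1 / 12))

  mu <- make_block_distribution("medium_uniform")
  expect_equal(mu$probs, rep(1 / 6, 6))

  hp <- make_block_distribution("medium_high_peaked")
  expect_equal(hp$probs[hp$support == 675], 19 / 24)
  expect_equal(sum(hp$probs), 1)

  wb <- make_block_distribution("wide_bimodal")
  extremal <- wb$probs[wb$support %in% c(450, 525, 600, 975, 1050, 1125)]
  middle <- wb$probs[wb$support %in% c(675, 750, 825, 900)]
  expect_equal(unique(extremal / middle[1]), 4)  # four times as frequent

  for (bn in block_names()) {
    d <- make_block_distribution(bn)
    expect_equal(sum(d$probs), 1, tolerance = 1e-12)
    expect_true(all(diff(d$support) == 75))
  }
})

test_that("unknown block names raise an informative error", {
  expect_error(make_block_distribution("medium_spiky"), "valid blocks")
})

test_that("moments agree with direct probability-weighted sums", {
  # independent brute-force oracle for the wide bimodal block
  s <- seq(450, 1125, by = 75)
  p <- ifelse(s %in% c(675, 750, 825, 900), 1 / 28, 1 / 7)
  m <- sum(p * s)
  v <- sum(p * (s - m)^2)
  sk <- sum(p * (s - m)^3) / v^1.5
  ku <- sum(p * (s - m)^4) / v^2 - 3
  got <- moments(make_block_distribution("wide_bimodal"))
  expect_equal(got$mean, m)
  expect_equal(got$sd, sqrt(v))
  expect_equal(got$skewness, sk)
  expect_equal(got$excess_kurtosis, ku)
})

test_that("symmetric distributions have zero skewness", {
  for (bn in c("short_uniform", "medium_uniform", "long_uniform",
               "wide_uniform", "medium_bimodal", "wide_bimodal")) {
    expect_equal(moments(make_block_distribution(bn))$skewness, 0,
                 tolerance = 1e-12)
  }
})

test_that("single-point distributions refuse higher moments", {
  d <- interval_distribution(c(600, 675), c(1, 0))
  expect_error(moments(d), "degenerate")
})

test_that("smoothing schemes preserve the mean and add kernel variance", {
  for (bn in c("medium_uniform", "medium_peaked")) {
    d <- make_block_distribution(bn)
    md <- moments(d)
    for (sch in c("c", "d")) {
      mo <- moments(make_candidate_prior(sch, bn))
      sd0 <- if (sch == "c") 37.5 else 75
      expect_equal(mo$mean, md$mean, tolerance = 1e-3)
      # law of total variance: mixture var = discrete var + kernel var
      expect_equal(mo$sd^2, md$sd^2 + sd0^2, tolerance = 1e-2 * md$sd^2)
    }
  }
})

test_that("scheme b matches the discrete mean and sd", {
  mo <- moments(make_candidate_prior("b", "medium_uniform"))
  expect_equal(mo$mean, 787.5, tolerance = 0.05)
  expect_equal(mo$sd, 128.0869, tolerance = 0.05)
})

test_that("scheme e is uniform over the block range", {
  pr <- make_candidate_prior("e", "medium_uniform")
  inside <- pr$grid >= 600 & pr$grid <= 975
  expect_true(all(pr$density[!inside] == 0))
  integral <- sum(diff(pr$grid)[1] *
                    (pr$density[-1] + pr$density[-length(pr$density)]) / 2)
  expect_equal(integral, 1, tolerance = 1e-8)
  expect_lt(diff(range(pr$density[inside])) / max(pr$density), 1e-12)
})

test_that("schemes f/g follow the peak-emergence construction", {
  # medium uniform: reduces to the single background Gaussian (scheme b)
  f_mu <- make_candidate_prior("f", "medium_uniform")
  b_mu <- make_candidate_prior("b", "medium_uniform")
  expect_equal(f_mu$density, b_mu$density, tolerance = 1e-10)

  # peaked: mean is the pi0-weighted combination of peak and range mean
  f_mp <- make_candidate_prior("f", "medium_peaked")
  mo <- moments(f_mp)
  expect_equal(mo$mean, 0.5 * 675 + 0.5 * 787.5, tolerance = 0.5)

  # high-peaked pulls harder toward the peak
  f_hp <- make_candidate_prior("f", "medium_high_peaked")
  expect_equal(moments(f_hp)$mean, 0.75 * 675 + 0.25 * 787.5,
               tolerance = 0.5)

  # not defined outside the medium/wide-bimodal families
  expect_error(make_candidate_prior("f", "short_uniform"), "not defined")
  expect_false("f" %in% valid_schemes("short_uniform"))
  expect_true("g" %in% valid_schemes("wide_bimodal"))
})

test_that("every constructed prior normalizes to one", {
  for (bn in c("medium_uniform", "medium_peaked", "wide_bimodal")) {
    for (sch in valid_schemes(bn)) {
      pr <- make_candidate_prior(sch, bn)
      if (inherits(pr, "interval_distribution")) {
        expect_equal(sum(pr$probs), 1, tolerance = 1e-12)
      } else {
        w <- diff(pr$grid)[1]
        integral <- sum(w * (pr$density[-1] +
                               pr$density[-length(pr$density)]) / 2)
        expect_equal(integral, 1, tolerance = 1e-8)
      }
    }
  }
})

test_that("constructors validate their invariants", {
  expect_error(interval_distribution(c(600, 675), c(0.6, 0.5)), "sum to 1")
  expect_error(interval_distribution(c(675, 600), c(0.5, 0.5)), "increasing")
  expect_error(continuous_prior(1:10, rep(-1, 10)), "nonnegative")
})

test_that("the block registry round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_block_registry(path)
  before <- make_block_distribution("medium_peaked")
  withr::defer(timepriors:::.block_registry(reset = TRUE))
  read_block_registry(path)
  after <- make_block_distribution("medium_peaked")
  expect_equal(after$support, before$support)
  expect_equal(after$probs, before$probs)
})
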