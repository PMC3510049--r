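# Nonparametric reconstruction of the subjective prior: control-point
# log-prior, squared-exponential GP interpolation, slice-sampling MCMC and
# moment summaries of the sampled priors.

#' Control-point grid for a block range
#'
#' Ten control points (14 for the Wide range) at 75-ms steps, centred on
#' the block's interval range and extending 150 ms beyond it on each side
#' to allow for tails or shifts: Short 300--975, Medium 450--1125,
#' Long 600--1275, Wide 300--1275 ms.
#'
#' @param range One of `"short"`, `"medium"`, `"long"`, `"wide"`, or a
#'   block name.
#' @return Numeric vector of control-point durations (ms).
#' @export
control_points <- function(range) {
  if (range %in% block_names()) range <- block_range(range)
  range <- match.arg(range, c("short", "medium", "long", "wide"))
  switch(range,
         short = seq(300, 975, by = 75),
         medium = seq(450, 1125, by = 75),
         long = seq(600, 1275, by = 75),
         wide = seq(300, 1275, by = 75))
}

#' Squared-exponential GP interpolator settings
#'
#' The log-prior is interpolated between control points by the posterior
#' mean of a Gaussian process with squared-exponential covariance
#' `signal_sd^2 exp(-(t - t')^2 / (2 length_scale^2))` and a small jitter
#' term for conditioning. The GP is an interpolating device only, not part
#' of the inference. The process mean is set `mean_offset` log-units below
#' the average control value, so the density decays to a negligible level
#' within about one length scale outside the control range, and adding a
#' constant to all control values shifts the whole log-density by that
#' constant (normalization then absorbs it exactly).
#'
#' @param length_scale Kernel length scale (ms).
#' @param signal_sd Kernel signal scale (log-density units).
#' @param jitter Diagonal noise term.
#' @param mean_offset GP mean relative to the average control value.
#' @return An object of class `gp_interpolator`.
#' @export
gp_interpolator <- function(length_scale = 100, signal_sd = 2,
                            jitter = 1e-6, mean_offset = -10) {
  stopifnot(length_scale > 0, signal_sd > 0, jitter >= 0)
  structure(list(length_scale = length_scale, signal_sd = signal_sd,
                 jitter = jitter, mean_offset = mean_offset),
            class = "gp_interpolator")
}

.se_kernel <- function(a, b, gp) {
  gp$signal_sd^2 * exp(-outer(a, b, "-")^2 / (2 * gp$length_scale^2))
}

# Interpolation weight matrix A such that log f(grid) = m + A (y - m),
# with m the GP mean. Precompute once per (control grid, evaluation grid).
gp_weights <- function(cp_times, grid, gp = gp_interpolator()) {
  K <- .se_kernel(cp_times, cp_times, gp)
  diag(K) <- diag(K) + gp$jitter
  ch <- tryCatch(chol(K), error = function(e) {
    stop("control-point covariance is not positive definite; ",
         "increase the jitter term")
  })
  Ks <- .se_kernel(grid, cp_times, gp)
  t(backsolve(ch, backsolve(ch, t(Ks), transpose = TRUE)))
}

#' Interpolate control-point log-prior values onto a grid
#'
#' @param log_values Log-prior values at the control points.
#' @param cp_times Control-point durations (ms), e.g. [control_points()].
#' @param gp A [gp_interpolator()].
#' @param grid Evaluation grid (ms); defaults to the control range extended
#'   by 150 ms on each side at 5-ms spacing.
#' @param weights Optional precomputed [gp_weights()] matrix for `grid`.
#' @return A [continuous_prior()] (exponentiated and renormalized).
#' @export
interpolate_prior <- function(log_values, cp_times, gp = gp_interpolator(),
                              grid = NULL, weights = NULL) {
  if (is.null(grid)) {
    grid <- seq(min(cp_times) - 150, max(cp_times) + 150, by = 5)
  }
  if (is.null(weights)) weights <- gp_weights(cp_times, grid, gp)
  m <- mean(log_values) + gp$mean_offset
  logf <- m + as.vector(weights %*% (log_values - m))
  continuous_prior(grid, exp(logf - max(logf)), label = "reconstructed")
}

# ---------------------------------------------------------------------------
# Posterior over control-point priors

#' Fixed observer components for prior reconstruction
#'
#' Bundle of the components held fixed while the prior is inferred
#' nonparametrically: noise models (with their coefficients, typically the
#' MAP from the model comparison), loss, and lapse rate.
#'
#' @param sensory,motor [noise_model()] objects.
#' @param loss A [loss_spec()].
#' @param lapse_rate Lapse rate in `[0, 1)`.
#' @return A list of class `fixed_components`.
#' @export
fixed_components <- function(sensory, motor, loss = loss_spec(),
                             lapse_rate = 0) {
  structure(list(sensory = sensory, motor = motor, loss = loss,
                 lapse_rate = lapse_rate,
                 lapse_range = c(GRID_MIN, GRID_MAX)),
            class = "fixed_components")
}

#' Fixed components from a model-comparison result
#'
#' Takes the modal noise and loss kinds and the MAP `(w_s, w_m)` of the
#' highest-evidence model, the way the reconstruction stage consumes the
#' model-comparison stage.
#'
#' @param evidences A list of `model_evidence` objects.
#' @param at `"map"` (default) uses the best model's MAP parameters;
#'   `"posterior_mean"` uses its posterior-mean parameters (grid method
#'   required).
#' @return A [fixed_components()] object.
#' @export
fixed_components_from_evidence <- function(evidences,
                                           at = c("map", "posterior_mean")) {
  at <- match.arg(at)
  df <- evidence_table(evidences)
  best <- evidences[[which.max(df$log_evidence)]]
  mc <- modal_components(evidences)
  w <- best$map
  if (at == "posterior_mean" && !is.null(best$param_grid)) {
    pg <- best$param_grid
    w <- c(sum(pg$w_s * pg$weight), sum(pg$w_m * pg$weight))
  }
  fixed_components(noise_model(mc[["sensory"]], w[1]),
                   noise_model(mc[["motor"]], w[2]),
                   loss_spec(mc[["loss"]]))
}

# Cached pieces of the reconstruction likelihood for one block's trials.
# The fixed components are known up front, so everything except the prior
# mass vector is precomputed: per target, the measurement nodes, their
# sensory weights, and the sensory-likelihood moment matrices over the
# reconstruction grid.
.recon_cache <- function(trials, cp_times, gp, fixed, grid_step = 5,
                         xm_sds = 5, xm_n = 41) {
  trials <- retained_trials(trials)
  if (length(unique(trials$block)) > 1L) {
    stop("prior reconstruction expects trials from a single block")
  }
  grid <- seq(min(cp_times) - 150, max(cp_times) + 150, by = grid_step)
  groups <- split(trials$response_ms, trials$target_ms)
  xs <- as.numeric(names(groups))
  gprep <- lapply(seq_along(xs), function(i) {
    x <- xs[i]
    sds <- noise_sd(fixed$sensory, x)
    xm <- seq(max(GRID_MIN, x - xm_sds * sds),
              min(GRID_MAX, x + xm_sds * sds), length.out = xm_n)
    ps_mass <- stats::dnorm(xm, x, sds) * trapz_weights(xm)
    ps_mass <- ps_mass / sum(ps_mass)
    sdx <- noise_sd(fixed$sensory, grid)
    n <- length(xm)
    m <- length(grid)
    Z <- (rep(xm, times = m) - rep(grid, each = n)) / rep(sdx, each = n)
    Es <- matrix(exp(-0.5 * Z * Z) / rep(sdx, each = n), n, m)
    list(x = x, xm = xm, ps_mass = ps_mass, r = groups[[i]],
         E1 = Es,
         Ex = Es * rep(grid, each = n),
         Ex2 = Es * rep(grid^2, each = n),
         Ei1 = Es * rep(1 / grid, each = n),
         Ei2 = Es * rep(1 / grid^2, each = n))
  })
  gtab <- if (fixed$loss$map_kind == "skewed") {
    skew_g_table(fixed$motor, default_grid(2))
  }
  K <- .se_kernel(cp_times, cp_times, gp)
  diag(K) <- diag(K) + gp$jitter
  list(grid = grid, gw = trapz_weights(grid),
       A = gp_weights(cp_times, grid, gp), K_chol = chol(K),
       groups = gprep, gtab = gtab, fixed = fixed,
       x = xs, r = groups, n = nrow(trials))
}

# Smoothness hyperprior on mean-centered control values: a Gaussian with
# the interpolator's own squared-exponential covariance. Centering keeps
# the posterior exactly shift invariant. Without some proper hyperprior
# the posterior is entropically dominated by sparse spike solutions:
# control points carrying no mass are unconstrained by the likelihood, so
# the flat(-capped) hyperprior rewards shapes with many `dead' points.
.log_hyperprior <- function(cache, y) {
  yc <- y - mean(y)
  q <- backsolve(cache$K_chol, yc, transpose = TRUE)
  -0.5 * sum(q * q)
}

# normalized prior mass vector on the reconstruction grid
.recon_prior_mass <- function(cache, gp, log_values) {
  m <- mean(log_values) + gp$mean_offset
  logf <- m + as.vector(cache$A %*% (log_values - m))
  dens <- exp(logf - max(logf))
  mass <- dens * cache$gw
  mass / sum(mass)
}

# log likelihood given the prior mass vector on the reconstruction grid
.recon_loglik <- function(cache, mass) {
  fixed <- cache$fixed
  tot <- 0
  for (g in cache$groups) {
    norm <- as.vector(g$E1 %*% mass)
    ps <- list(m1 = as.vector(g$Ex %*% mass) / norm,
               m2 = as.vector(g$Ex2 %*% mass) / norm,
               i1 = as.vector(g$Ei1 %*% mass) / norm,
               i2 = as.vector(g$Ei2 %*% mass) / norm)
    u <- ustar_from_stats(ps, fixed$motor, fixed$loss, cache$gtab)
    sdu <- noise_sd(fixed$motor, u)
    zfrac <- stats::pnorm(GRID_MAX, u, sdu) - stats::pnorm(GRID_MIN, u, sdu)
    n <- length(g$r)
    m <- length(u)
    D <- matrix(stats::dnorm(rep(g$r, times = m), rep(u, each = n),
                             rep(sdu, each = n)) / rep(zfrac, each = n),
                n, m)
    d <- as.vector(D %*% g$ps_mass)
    d <- .mix_lapse(d, g$r, fixed$lapse_rate, fixed$lapse_range)
    tot <- tot + sum(log(pmax(d, 1e-300)))
  }
  tot
}

#' Log posterior of control-point log-prior values
#'
#' `log Pr(data | prior, model)` plus the regularizing hyperprior over
#' control values, with the prior induced by GP interpolation. The default
#' hyperprior is a weak smoothness penalty: a Gaussian with the
#' interpolator's squared-exponential covariance on the *mean-centered*
#' control values (so adding a constant to all control values still
#' leaves the result unchanged). `hyperprior = "flat"` gives the pure
#' likelihood, capped at `|value| <= 20` for numerical safety -- note that
#' without any proper hyperprior the posterior is dominated by sparse
#' spike-shaped priors whose dead control points are unconstrained.
#'
#' @param log_values Control-point log-prior values.
#' @param trials Trial table (single block, retained trials used).
#' @param fixed A [fixed_components()] bundle.
#' @param cp_times Control-point durations; defaults to the block's
#'   [control_points()].
#' @param gp A [gp_interpolator()].
#' @param hyperprior `"gp"` (smoothness penalty, default) or `"flat"`.
#' @return Scalar log posterior (up to a constant).
#' @export
log_posterior <- function(log_values, trials, fixed, cp_times = NULL,
                          gp = gp_interpolator(),
                          hyperprior = c("gp", "flat")) {
  hyperprior <- match.arg(hyperprior)
  if (is.null(cp_times)) cp_times <- control_points(trials$block[1])
  if (any(abs(log_values) > 20)) return(-Inf)
  cache <- .recon_cache(trials, cp_times, gp, fixed)
  lp <- .recon_loglik(cache, .recon_prior_mass(cache, gp, log_values))
  if (hyperprior == "gp") lp <- lp + .log_hyperprior(cache, log_values)
  lp
}

# ---------------------------------------------------------------------------
# Slice sampling

# Univariate slice sampler step (Neal 2003): stepping-out with at most
# `max_steps` width expansions per side, then shrinkage sampling.
slice_step <- function(x0, f0, logf, w = 1, max_steps = 10,
                       lower = -20, upper = 20) {
  z <- f0 - stats::rexp(1)
  u <- stats::runif(1)
  L <- x0 - w * u
  R <- L + w
  j <- floor(stats::runif(1) * max_steps)
  k <- max_steps - 1 - j
  while (j > 0 && L > lower && logf(L) > z) {
    L <- L - w
    j <- j - 1
  }
  while (k > 0 && R < upper && logf(R) > z) {
    R <- R + w
    k <- k - 1
  }
  L <- max(L, lower)
  R <- min(R, upper)
  repeat {
    x1 <- stats::runif(1, L, R)
    f1 <- logf(x1)
    if (f1 >= z) return(list(x = x1, f = f1))
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# Generic coordinate-wise slice sampler over a log density.
slice_sample_chain <- function(log_density, init, n_iter, w = 1,
                               max_steps = 10, lower = -20, upper = 20,
                               callback = NULL) {
  y <- init
  f <- log_density(y)
  if (!is.finite(f)) stop("non-finite log posterior at initialization")
  d <- length(y)
  out <- matrix(NA_real_, n_iter, d)
  for (it in seq_len(n_iter)) {
    for (i in seq_len(d)) {
      res <- slice_step(y[i], f, function(v) {
        yy <- y
        yy[i] <- v
        log_density(yy)
      }, w = w, max_steps = max_steps, lower = lower, upper = upper)
      y[i] <- res$x
      f <- res$f
    }
    out[it, ] <- y
    if (!is.null(callback)) callback(it, y, f)
  }
  out
}

#' Sample subjective priors from their posterior by slice sampling
#'
#' Runs coordinate-wise slice-sampling MCMC over the control-point
#' log-prior values, targeting `Pr(data | prior, model)` with the other
#' observer components fixed. Chains are initialized at dispersed random
#' points; the first four moments of each sampled prior are recorded.
#'
#' @param trials Trial table (single block).
#' @param fixed A [fixed_components()] bundle.
#' @param cp_times Control points; default from the block.
#' @param gp A [gp_interpolator()].
#' @param chains,burn_in,keep MCMC schedule. The study-scale schedule is 10
#'   chains, 3000 burn-in and 1500 saved samples per chain (15000 priors);
#'   smaller schedules are appropriate for desk-scale runs.
#' @param seed Integer seed; chain `c` uses `seed + c`.
#' @param grid_step Reconstruction grid spacing (ms).
#' @param init `"empirical"` starts each chain at the log-density of a
#'   Gaussian moment-matched to the retained responses (jittered per
#'   chain) -- a smooth, data-informed starting point; `"random"` starts
#'   at independent standard-normal control values. The posterior over
#'   priors has long, nearly flat ridges (structure finer than the
#'   sensorimotor noise scale is barely identified), so desk-scale chains
#'   started at random points can spend their whole budget in arbitrary
#'   comb-shaped modes; the empirical start spends the budget in the
#'   data-relevant basin.
#' @param hyperprior `"gp"` (default) or `"flat"`; see [log_posterior()].
#' @return An object of class `prior_posterior_sample`: control times,
#'   sample matrix (with chain index), per-sample moments, the GP settings
#'   and reconstruction grid.
#' @export
slice_sample_priors <- function(trials, fixed, cp_times = NULL,
                                gp = gp_interpolator(), chains = 10,
                                burn_in = 3000, keep = 1500, seed = 1,
                                grid_step = 5,
                                init = c("empirical", "random"),
                                hyperprior = c("gp", "flat")) {
  init <- match.arg(init)
  hyperprior <- match.arg(hyperprior)
  if (is.null(cp_times)) cp_times <- control_points(trials$block[1])
  cache <- .recon_cache(trials, cp_times, gp, fixed, grid_step)
  ld <- function(y) {
    if (any(abs(y) > 20)) return(-Inf)
    lp <- .recon_loglik(cache, .recon_prior_mass(cache, gp, y))
    if (hyperprior == "gp") lp <- lp + .log_hyperprior(cache, y)
    lp
  }
  d <- length(cp_times)
  if (init == "empirical") {
    ret <- retained_trials(trials)
    y0 <- stats::dnorm(cp_times, mean(ret$response_ms),
                       stats::sd(ret$response_ms), log = TRUE)
    y0 <- pmax(y0 - max(y0), -8)
  } else {
    y0 <- rep(0, d)
  }
  samples <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seed + ch)
    start <- if (init == "empirical") y0 + stats::rnorm(d, 0, 0.5)
             else stats::rnorm(d, 0, 1)
    draw <- slice_sample_chain(ld, start, burn_in + keep)
    samples[[ch]] <- draw[(burn_in + 1):(burn_in + keep), , drop = FALSE]
  }
  all <- do.call(rbind, samples)
  chain_id <- rep(seq_len(chains), each = keep)
  mom <- t(apply(all, 1, function(y) {
    mass <- .recon_prior_mass(cache, gp, y)
    .node_moments(list(x = cache$grid, mass = mass))
  }))
  structure(list(cp_times = cp_times, samples = all, chain = chain_id,
                 moments = as.data.frame(mom), chains = chains,
                 burn_in = burn_in, keep = keep, gp = gp,
                 grid = cache$grid, seed = seed),
            class = "prior_posterior_sample")
}

# moments from quadrature nodes (mean, sd, skewness, excess kurtosis)
.node_moments <- function(pn) {
  m <- sum(pn$mass * pn$x)
  v <- sum(pn$mass * (pn$x - m)^2)
  s <- sqrt(v)
  z <- (pn$x - m) / s
  c(mean = m, sd = s, skewness = sum(pn$mass * z^3),
    excess_kurtosis = sum(pn$mass * z^4) - 3)
}

#' Summarize moments of sampled priors
#'
#' Mean and standard deviation, across sampled priors, of each of the first
#' four moments. The moments are computed per sampled prior and then
#' averaged (never the moments of the average density, which would inflate
#' the kurtosis of a mixture of light-tailed samples). Multiple sample
#' objects (e.g. several synthetic subjects) are pooled.
#'
#' @param ... One or more `prior_posterior_sample` objects.
#' @return Data frame with rows `mean`, `sd`, `skewness`,
#'   `excess_kurtosis` and columns `estimate` (mean across samples) and
#'   `sd` (standard deviation across samples).
#' @export
summarize_prior_moments <- function(...) {
  objs <- list(...)
  if (length(objs) == 1L && is.list(objs[[1]]) &&
      !inherits(objs[[1]], "prior_posterior_sample")) {
    objs <- objs[[1]]
  }
  mom <- do.call(rbind, lapply(objs, function(o) o$moments))
  data.frame(moment = colnames(mom),
             estimate = colMeans(mom),
             sd = apply(mom, 2, stats::sd),
             row.names = NULL)
}

#' Posterior-mean reconstructed prior
#'
#' The average of the sampled prior densities (the `average inferred
#' prior' used for plotting and peak diagnostics). Averaging densities,
#' not control values: the posterior over control values has an exact
#' flat direction (adding a constant changes nothing) and near-flat
#' ridges, so the mean log-value vector is not a meaningful shape summary.
#'
#' @param ps A `prior_posterior_sample`.
#' @return A [continuous_prior()].
#' @export
posterior_mean_prior <- function(ps) {
  A <- gp_weights(ps$cp_times, ps$grid, ps$gp)
  gw <- trapz_weights(ps$grid)
  acc <- numeric(length(ps$grid))
  for (i in seq_len(nrow(ps$samples))) {
    y <- ps$samples[i, ]
    m <- mean(y) + ps$gp$mean_offset
    lf <- m + as.vector(A %*% (y - m))
    dens <- exp(lf - max(lf))
    acc <- acc + dens / sum(dens * gw)
  }
  continuous_prior(ps$grid, acc / nrow(ps$samples),
                   label = "posterior_mean")
}

#' Detect spurious interior peaks
#'
#' Flags an interior control point whose reconstructed density exceeds both
#' neighbours by more than `ratio` -- used to check that flat-prior data do
#' not yield spurious multimodality.
#'
#' @param prior A [continuous_prior()].
#' @param cp_times Control points at which to compare.
#' @param ratio Peak ratio threshold.
#' @return `TRUE` if any interior control point is a peak by this
#'   criterion.
#' @export
has_spurious_peak <- function(prior, cp_times, ratio = 1.5) {
  d <- stats::approx(prior$grid, prior$density, xout = cp_times)$y
  n <- length(d)
  any(d[2:(n - 1)] > ratio * d[1:(n - 2)] & d[2:(n - 1)] > ratio * d[3:n])
}

#' Split-half R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half.
#'
#' @param x Matrix of draws, iterations by chains.
#' @return Scalar R-hat.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x) %/% 2L
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[(nrow(x) - n + 1L):nrow(x), , drop = FALSE])
  m <- ncol(halves)
  mu <- colMeans(halves)
  s2 <- apply(halves, 2, stats::var)
  W <- mean(s2)
  B <- n * stats::var(mu)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Write sampled priors as delimited text
#'
#' One row per saved sample: chain, iteration, the control-point log
#' values, and the four moments.
#'
#' @param ps A `prior_posterior_sample`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_prior_samples <- function(ps, path) {
  df <- data.frame(chain = ps$chain,
                   iteration = rep(seq_len(ps$keep), ps$chains))
  colnames(ps$samples) <- paste0("cp_", ps$cp_times)
  df <- cbind(df, ps$samples, ps$moments)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
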