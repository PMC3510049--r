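# Bayesian observer-actor core: likelihoods, loss maps, optimal action,
# marginal response distribution, predicted bias/SD curves.

#' Sensory or motor noise model
#'
#' Gaussian noise whose standard deviation is either constant across
#' intervals (`w` times a fixed reference duration, 787.5 ms by default) or
#' `scalar', i.e. proportional to the interval (`w` is then the Weber
#' fraction / coefficient of variation).
#'
#' @param kind `"constant"` or `"scalar"`.
#' @param w Coefficient of variation, > 0.
#' @param reference Reference duration (ms) for the constant kind.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("scalar", "constant"), w,
                        reference = 787.5) {
  kind <- match.arg(kind)
  if (!is.numeric(w) || w <= 0) stop("w must be > 0")
  structure(list(kind = kind, w = w, reference = reference),
            class = "noise_model")
}

# sd of the noise at duration(s) `at`
noise_sd <- function(noise, at) {
  if (noise$kind == "constant") {
    rep(noise$w * noise$reference, length(at))
  } else {
    if (any(at <= 0)) stop("scalar noise undefined for nonpositive durations")
    noise$w * at
  }
}

#' Loss specification (squared subjective error map)
#'
#' The observer's loss is `|f(r, x)|^exponent` where `f` is the subjective
#' error map: Standard `r - x`, Fractional `(r - x)/x`, or Skewed
#' `(r - x)/r` (the response-denominated asymmetric map used as feedback in
#' some blocks). The basic model uses `exponent = 2`.
#'
#' @param map_kind `"standard"`, `"fractional"` or `"skewed"`.
#' @param exponent Positive loss exponent; 2 for the basic (quadratic) model.
#' @return An object of class `loss_spec`.
#' @export
loss_spec <- function(map_kind = c("standard", "fractional", "skewed"),
                      exponent = 2) {
  map_kind <- match.arg(map_kind)
  if (!is.numeric(exponent) || exponent <= 0) stop("exponent must be > 0")
  structure(list(map_kind = map_kind, exponent = exponent),
            class = "loss_spec")
}

#' Full observer-actor model
#'
#' @param sensory,motor [noise_model()] objects (coefficients `w_s`, `w_m`).
#' @param prior Subjective prior: an [interval_distribution()] or
#'   [continuous_prior()].
#' @param loss A [loss_spec()].
#' @param lapse_rate Probability in `[0, 1)` that a trial is a lapse, in
#'   which case the response is uniform on `lapse_range`.
#' @param lapse_range Duration interval (ms) of the lapse distribution.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(sensory, motor, prior, loss = loss_spec(),
                           lapse_rate = 0,
                           lapse_range = c(GRID_MIN, GRID_MAX)) {
  stopifnot(inherits(sensory, "noise_model"), inherits(motor, "noise_model"),
            inherits(loss, "loss_spec"))
  if (lapse_rate < 0 || lapse_rate >= 1) stop("lapse_rate must be in [0, 1)")
  if (!(inherits(prior, "interval_distribution") ||
        inherits(prior, "continuous_prior"))) {
    stop("prior must be an interval_distribution or continuous_prior")
  }
  structure(list(sensory = sensory, motor = motor, prior = prior,
                 loss = loss, lapse_rate = lapse_rate,
                 lapse_range = lapse_range),
            class = "observer_model")
}

#' Sensory and motor likelihoods
#'
#' Gaussian densities of the internal measurement `x_m` given the true
#' interval `x` (sensory) and of the response `r` given the motor command
#' `u` (motor).
#'
#' @param x_m,r Evaluation points (ms).
#' @param x,u Conditioning duration (ms).
#' @param noise A [noise_model()].
#' @return Density values.
#' @export
sensory_density <- function(x_m, x, noise) {
  stats::dnorm(x_m, mean = x, sd = noise_sd(noise, x))
}

#' @rdname sensory_density
#' @export
motor_density <- function(r, u, noise) {
  stats::dnorm(r, mean = u, sd = noise_sd(noise, u))
}

#' Subjective error map
#'
#' Signed error displayed (or internally assumed) for response `r` to target
#' `x`: Standard `r - x`, Fractional `(r - x)/x`, Skewed `(r - x)/r`.
#'
#' @param r Response duration (ms).
#' @param x Target duration (ms).
#' @param loss A [loss_spec()]; only its `map_kind` is used.
#' @return Signed error values.
#' @export
error_map <- function(r, x, loss) {
  switch(loss$map_kind,
         standard = r - x,
         fractional = {
           if (any(x <= 0)) stop("fractional error undefined for x <= 0")
           (r - x) / x
         },
         skewed = {
           if (any(r <= 0)) stop("skewed error undefined for r <= 0")
           (r - x) / r
         })
}

# ---------------------------------------------------------------------------
# Posterior statistics of x given a measurement x_m

# For each x_m, the posterior over x is proportional to prior(x) times the
# sensory likelihood N(x_m; x, sd_s(x)). Returns posterior moments needed by
# the closed-form decision rules (E[x], E[x^2], E[1/x], E[1/x^2]) and the
# unnormalized marginal of x_m.
posterior_stats <- function(xm, pn, sensory) {
  n <- length(xm)
  m <- length(pn$x)
  sdx <- noise_sd(sensory, pn$x)
  Z <- (rep(xm, times = m) - rep(pn$x, each = n)) / rep(sdx, each = n)
  # log unnormalized posterior, stabilized per row so that near-noiseless
  # observers (tiny w) do not underflow to an all-zero posterior
  L <- matrix(-0.5 * Z * Z - rep(log(sdx), each = n) +
                rep(log(pn$mass), each = n), n, m)
  rmax <- L[cbind(seq_len(n), max.col(L, ties.method = "first"))]
  bad <- !is.finite(rmax)
  if (any(bad)) {
    stop("prior has zero posterior mass for some measurements (x_m = ",
         signif(xm[bad][1], 6), "); widen the prior grid")
  }
  W <- exp(L - rmax)
  norm <- rowSums(W)
  list(log_z = log(norm) + rmax,
       m1 = as.vector(W %*% pn$x) / norm,
       m2 = as.vector(W %*% (pn$x^2)) / norm,
       i1 = as.vector(W %*% (1 / pn$x)) / norm,
       i2 = as.vector(W %*% (1 / pn$x^2)) / norm)
}

# Tabulate g1(u) = E[1/r | u] and g2(u) = E[1/r^2 | u] under the motor
# likelihood truncated to [GRID_MIN, GRID_MAX]; needed for the skewed loss.
skew_g_table <- function(motor, u_grid, r_step = 2) {
  r <- seq(GRID_MIN, GRID_MAX, by = r_step)
  wq <- trapz_weights(r)
  n <- length(r)
  m <- length(u_grid)
  sdu <- noise_sd(motor, u_grid)
  Z <- (rep(r, times = m) - rep(u_grid, each = n)) / rep(sdu, each = n)
  M <- matrix(exp(-0.5 * Z * Z) * wq, n, m)
  norm <- colSums(M)
  list(u = u_grid,
       g1 = colSums(M / r) / norm,
       g2 = colSums(M / r^2) / norm)
}

# Closed-form / tabulated optimal action for a batch of posterior stats.
# For the skewed map, the expected loss given x_m is
#   1 - 2 E[x|x_m] g1(u) + E[x^2|x_m] g2(u),
# minimized on the u table with 3-point parabolic refinement.
ustar_from_stats <- function(ps, motor, loss, gtab = NULL) {
  scalar_m <- motor$kind == "scalar"
  if (loss$map_kind == "standard") {
    u <- if (scalar_m) ps$m1 / (1 + motor$w^2) else ps$m1
  } else if (loss$map_kind == "fractional") {
    u <- if (scalar_m) ps$i1 / ((1 + motor$w^2) * ps$i2) else ps$i1 / ps$i2
  } else {
    if (is.null(gtab)) gtab <- skew_g_table(motor, default_grid(2))
    H <- -2 * outer(gtab$g1, ps$m1) + outer(gtab$g2, ps$m2)
    j <- max.col(-t(H), ties.method = "first")
    nu <- length(gtab$u)
    u <- gtab$u[j]
    int <- j > 1L & j < nu
    if (any(int)) {
      ji <- j[int]
      cols <- which(int)
      hm <- H[cbind(ji - 1L, cols)]
      h0 <- H[cbind(ji, cols)]
      hp <- H[cbind(ji + 1L, cols)]
      denom <- hp - 2 * h0 + hm
      step <- gtab$u[2L] - gtab$u[1L]
      adj <- ifelse(denom > 0, -0.5 * step * (hp - hm) / denom, 0)
      u[int] <- u[int] + pmax(pmin(adj, step), -step)
    }
  }
  pmin(pmax(u, GRID_MIN), GRID_MAX)
}

# ---------------------------------------------------------------------------
# Expected loss and decision rule (public, reference-quality quadrature)

#' Subjectively expected loss of an action
#'
#' The expected loss of producing motor command `u` after measuring `x_m`:
#' the double integral of the loss over the posterior of `x` given `x_m`
#' and the motor likelihood of `r` given `u`, with all densities truncated
#' and renormalized on the duration grid.
#'
#' @param u Candidate action (ms); may be a vector.
#' @param x_m Internal measurement (ms), scalar.
#' @param model An [observer_model()].
#' @param r_step Quadrature step (ms) for the response integral.
#' @return Nonnegative expected loss value(s).
#' @export
expected_loss <- function(u, x_m, model, r_step = 1) {
  pn <- prior_nodes(model$prior)
  sdx <- noise_sd(model$sensory, pn$x)
  post <- pn$mass * exp(-0.5 * ((x_m - pn$x) / sdx)^2) / sdx
  if (sum(post) <= 0) stop("prior has zero posterior mass at x_m")
  post <- post / sum(post)
  r <- seq(GRID_MIN, GRID_MAX, by = r_step)
  wq <- trapz_weights(r)
  # loss averaged over the posterior of x, as a function of r
  E <- outer(r, pn$x, function(rr, xx) {
    abs(error_map(rr, xx, model$loss))^model$loss$exponent
  })
  lbar <- as.vector(E %*% post)
  vapply(u, function(ui) {
    sdm <- noise_sd(model$motor, ui)
    if (sdm < 4 * r_step) {
      # near-deterministic motor output: refine the response quadrature
      # locally so the narrow Gaussian is resolved
      rr <- seq(max(GRID_MIN, ui - 10 * sdm), min(GRID_MAX, ui + 10 * sdm),
                length.out = 201)
      pm <- stats::dnorm(rr, ui, sdm) * trapz_weights(rr)
      lb <- stats::approx(r, lbar, xout = rr, rule = 2)$y
      return(sum(pm * lb) / sum(pm))
    }
    pm <- stats::dnorm(r, ui, sdm) * wq
    sum(pm * lbar) / sum(pm)
  }, numeric(1))
}

#' Optimal action as a function of the measurement
#'
#' Tabulates the action `u*(x_m)` minimizing the subjectively expected loss
#' on a measurement grid. For the standard and fractional quadratic losses
#' the minimization is analytic (posterior-moment closed forms); for the
#' skewed loss (or `method = "numeric"`) it is a bounded numerical
#' minimization on `[150, 1800]` ms.
#'
#' @param model An [observer_model()].
#' @param xm_grid Measurement grid (ms).
#' @param method `"auto"` (closed form where available), `"closed_form"`,
#'   or `"numeric"` (bounded [stats::optimize()] of [expected_loss()]).
#' @return An object of class `decision_rule` with fields `xm_grid` and
#'   `u_star`.
#' @export
decision_rule <- function(model, xm_grid = default_grid(5),
                          method = c("auto", "closed_form", "numeric")) {
  method <- match.arg(method)
  if (method == "numeric") {
    u <- vapply(xm_grid, function(xm) {
      stats::optimize(function(uu) expected_loss(uu, xm, model),
                      interval = c(GRID_MIN, GRID_MAX), tol = 1e-3)$minimum
    }, numeric(1))
  } else {
    if (method == "closed_form" && model$loss$map_kind == "skewed") {
      stop("no closed form for the skewed loss; use method = 'auto' or ",
           "'numeric'")
    }
    pn <- prior_nodes(model$prior)
    ps <- posterior_stats(xm_grid, pn, model$sensory)
    gtab <- if (model$loss$map_kind == "skewed") {
      skew_g_table(model$motor, default_grid(1))
    }
    u <- ustar_from_stats(ps, model$motor, model$loss, gtab)
  }
  at_bound <- u <= GRID_MIN | u >= GRID_MAX
  if (any(at_bound)) {
    warning("optimal action at an optimization bound for ",
            sum(at_bound), " measurement(s); bounds may be too tight")
  }
  structure(list(xm_grid = xm_grid, u_star = u, model = model),
            class = "decision_rule")
}

# ---------------------------------------------------------------------------
# Response distribution and bias/SD curves

# Internal: response density of the observer at target x, evaluated at
# arbitrary r values. Integrates over the measurement with nodes at
# x +/- xm_sds sensory sds (clipped to the grid), and mixes in the lapse
# component. `gtab` caches the skewed-loss table across calls.
response_density_at <- function(model, x, r, pn, gtab = NULL,
                                xm_sds = 5, xm_n = 61) {
  sds <- noise_sd(model$sensory, x)
  lo <- max(GRID_MIN, x - xm_sds * sds)
  hi <- min(GRID_MAX, x + xm_sds * sds)
  xm <- seq(lo, hi, length.out = xm_n)
  ps_mass <- stats::dnorm(xm, x, sds) * trapz_weights(xm)
  ps_mass <- ps_mass / sum(ps_mass)
  st <- posterior_stats(xm, pn, model$sensory)
  u <- ustar_from_stats(st, model$motor, model$loss, gtab)
  sdu <- noise_sd(model$motor, u)
  # truncated-normal motor components on the grid interval
  zfrac <- stats::pnorm(GRID_MAX, u, sdu) - stats::pnorm(GRID_MIN, u, sdu)
  n <- length(r)
  m <- length(xm)
  D <- matrix(stats::dnorm(rep(r, times = m), rep(u, each = n),
                           rep(sdu, each = n)) / rep(zfrac, each = n), n, m)
  dens <- as.vector(D %*% ps_mass)
  if (model$lapse_rate > 0) {
    lr <- model$lapse_range
    lap <- stats::dunif(r, lr[1], lr[2])
    dens <- (1 - model$lapse_rate) * dens + model$lapse_rate * lap
  }
  dens
}

#' Marginal response distribution of an ideal observer
#'
#' The density of the reproduced duration `r` for a target interval `x`,
#' obtained by integrating the motor likelihood of the optimal action over
#' the distribution of internal measurements, mixed with the uniform lapse
#' component when the lapse rate is positive.
#'
#' @param x Target interval (ms), scalar.
#' @param model An [observer_model()].
#' @param r_grid Durations at which to evaluate the density.
#' @return A list with `r` (grid) and `density`; the trapezoidal integral
#'   over the default grid is 1 up to quadrature tolerance.
#' @export
response_distribution <- function(x, model, r_grid = default_grid()) {
  pn <- prior_nodes(model$prior)
  gtab <- if (model$loss$map_kind == "skewed") {
    skew_g_table(model$motor, default_grid(1))
  }
  dens <- response_density_at(model, x, r_grid, pn, gtab)
  mass <- trapz_integral(r_grid, dens)
  if (mass < 1 - 1e-4) {
    warning("r_grid truncates ", signif(1 - mass, 3),
            " of the response density mass")
  }
  list(r = r_grid, density = dens, x = x)
}

#' Predicted response bias and standard deviation per interval
#'
#' For each support point of the experimental distribution, computes the
#' mean response bias `E[r|x] - x` and the response standard deviation
#' `Std[r|x]` of the observer, by quadrature over the response density.
#'
#' @param model An [observer_model()].
#' @param dist An [interval_distribution()] giving the intervals at which to
#'   evaluate the curves.
#' @param r_step Quadrature step (ms).
#' @return A data frame with columns `x`, `bias`, `sd`.
#' @export
bias_sd_curves <- function(model, dist, r_step = 1) {
  r <- seq(GRID_MIN, GRID_MAX, by = r_step)
  wq <- trapz_weights(r)
  pn <- prior_nodes(model$prior)
  gtab <- if (model$loss$map_kind == "skewed") {
    skew_g_table(model$motor, default_grid(1))
  }
  out <- lapply(dist$support, function(x) {
    dens <- response_density_at(model, x, r, pn, gtab)
    mass <- sum(wq * dens)
    m1 <- sum(wq * dens * r) / mass
    m2 <- sum(wq * dens * r^2) / mass
    c(bias = m1 - x, sd = sqrt(max(m2 - m1^2, 0)))
  })
  out <- do.call(rbind, out)
  data.frame(x = dist$support, bias = out[, "bias"], sd = out[, "sd"])
}
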