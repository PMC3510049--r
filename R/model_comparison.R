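# Marginal likelihoods over the discrete observer-model family, posterior
# model/component probabilities, and Bayesian-model-averaged predictions.

#' Observer-model template
#'
#' One member of the discrete model family: noise kinds, prior approximation
#' scheme and loss kind, with the two coefficients of variation `(w_s, w_m)`
#' left free. The same template applies across all blocks of a dataset (the
#' approximation scheme is assumed consistent across blocks).
#'
#' @param sensory,motor `"constant"` or `"scalar"`.
#' @param prior_scheme A scheme letter `"a"`--`"g"` (see
#'   [make_candidate_prior()]).
#' @param loss `"standard"`, `"fractional"` or `"skewed"`.
#' @param lapse_rate Fixed lapse rate, or `NULL` to use `lapse_grid`.
#' @param lapse_grid Optional grid of lapse rates marginalized uniformly
#'   (e.g. `c(0, 0.01, 0.03, 0.1)`); ignored when `lapse_rate` is given.
#' @return An object of class `observer_template`.
#' @export
observer_template <- function(sensory = "scalar", motor = "scalar",
                              prior_scheme = "b", loss = "standard",
                              lapse_rate = 0, lapse_grid = NULL) {
  sensory <- match.arg(sensory, c("constant", "scalar"))
  motor <- match.arg(motor, c("constant", "scalar"))
  prior_scheme <- match.arg(prior_scheme, letters[1:7])
  loss <- match.arg(loss, c("standard", "fractional", "skewed"))
  structure(list(sensory = sensory, motor = motor,
                 prior_scheme = prior_scheme, loss = loss,
                 lapse_rate = lapse_rate, lapse_grid = lapse_grid),
            class = "observer_template")
}

#' Discrete model space
#'
#' Cartesian product of component choices, one [observer_template()] per
#' combination.
#'
#' @param sensory,motor,prior_schemes,losses Component levels to cross.
#' @param lapse_rate,lapse_grid Passed to every template.
#' @return A list of templates, with a `components` data-frame attribute.
#' @export
model_space <- function(sensory = c("constant", "scalar"),
                        motor = c("constant", "scalar"),
                        prior_schemes = c("a", "b", "c", "d", "e"),
                        losses = c("standard", "fractional", "skewed"),
                        lapse_rate = 0, lapse_grid = NULL) {
  grid <- expand.grid(sensory = sensory, motor = motor,
                      prior_scheme = prior_schemes, loss = losses,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0L) stop("model space restriction eliminates all models")
  out <- lapply(seq_len(nrow(grid)), function(i) {
    observer_template(grid$sensory[i], grid$motor[i], grid$prior_scheme[i],
                      grid$loss[i], lapse_rate = lapse_rate,
                      lapse_grid = lapse_grid)
  })
  attr(out, "components") <- grid
  out
}

#' Instantiate a template for a block
#'
#' @param template An [observer_template()].
#' @param block_name A registered block name.
#' @param w_s,w_m Coefficients of variation.
#' @param grid Duration grid for continuous candidate priors.
#' @return An [observer_model()].
#' @export
observer_for_block <- function(template, block_name, w_s, w_m,
                               grid = default_grid()) {
  observer_model(noise_model(template$sensory, w_s),
                 noise_model(template$motor, w_m),
                 make_candidate_prior(template$prior_scheme, block_name,
                                      grid),
                 loss_spec(template$loss),
                 lapse_rate = if (is.null(template$lapse_rate)) 0
                              else template$lapse_rate)
}

# ---------------------------------------------------------------------------
# Likelihood engine

# Per-dataset cache: for each block, the prior quadrature nodes (independent
# of w_s/w_m) and the retained trials grouped by target.
.likelihood_cache <- function(trials, template, prior_step = 5) {
  trials <- retained_trials(trials)
  if (nrow(trials) == 0L) return(list(blocks = list(), n = 0L))
  off <- which(trials$response_ms < GRID_MIN | trials$response_ms > GRID_MAX)
  if (length(off)) {
    stop("response ", signif(trials$response_ms[off[1]], 6), " ms (target ",
         trials$target_ms[off[1]], " ms) lies outside the duration grid: ",
         "grid/window mismatch")
  }
  blocks <- split(trials, trials$block)
  cache <- lapply(names(blocks), function(bn) {
    prior <- make_candidate_prior(template$prior_scheme, bn)
    pn <- prior_nodes(prior, step = prior_step)
    tb <- blocks[[bn]]
    groups <- split(tb$response_ms, tb$target_ms)
    list(block = bn, pn = pn,
         x = as.numeric(names(groups)), r = groups)
  })
  list(blocks = cache, n = nrow(trials))
}

# Per-trial response densities (without the lapse mixture) for one
# parameter value; returns a list of density vectors aligned with the cache
# grouping.
.cache_densities <- function(cache, template, w_s, w_m, xm_n = 41) {
  sensory <- noise_model(template$sensory, w_s)
  motor <- noise_model(template$motor, w_m)
  loss <- loss_spec(template$loss)
  gtab <- if (template$loss == "skewed") {
    skew_g_table(motor, default_grid(5), r_step = 5)
  }
  mdl <- list(sensory = sensory, motor = motor, loss = loss,
              lapse_rate = 0, lapse_range = c(GRID_MIN, GRID_MAX))
  lapply(cache$blocks, function(blk) {
    lapply(seq_along(blk$x), function(i) {
      response_density_at(mdl, blk$x[i], blk$r[[i]], blk$pn, gtab,
                          xm_n = xm_n)
    })
  })
}

.mix_lapse <- function(dens, r, lapse_rate, lapse_range) {
  if (lapse_rate <= 0) return(dens)
  (1 - lapse_rate) * dens +
    lapse_rate * stats::dunif(r, lapse_range[1], lapse_range[2])
}

# log likelihood for one (w_s, w_m); marginalizes uniformly over a lapse
# grid when the template specifies one
.cache_loglik <- function(cache, template, w_s, w_m, xm_n = 41,
                          lapse_range = c(GRID_MIN, GRID_MAX)) {
  if (cache$n == 0L) return(0)
  dens <- .cache_densities(cache, template, w_s, w_m, xm_n)
  lgrid <- if (!is.null(template$lapse_grid)) template$lapse_grid
           else template$lapse_rate
  ll <- vapply(lgrid, function(lam) {
    tot <- 0
    for (b in seq_along(cache$blocks)) {
      blk <- cache$blocks[[b]]
      for (i in seq_along(blk$x)) {
        d <- .mix_lapse(dens[[b]][[i]], blk$r[[i]], lam, lapse_range)
        # tails can underflow at extreme parameter nodes; floor so those
        # nodes contribute ~nothing to the evidence instead of erroring
        tot <- tot + sum(log(pmax(d, 1e-300)))
      }
    }
    tot
  }, numeric(1))
  if (length(ll) > 1L) logsumexp(ll) - log(length(ll)) else ll
}

#' Log likelihood of a trial set under an observer model
#'
#' Sum of per-trial log response densities (independent trials), using the
#' marginal response distribution of the observer with the given
#' coefficients of variation. Only retained trials contribute.
#'
#' @param trials A trial table.
#' @param template An [observer_template()].
#' @param w_s,w_m Coefficients of variation.
#' @param prior_step Subsampling step (ms) for continuous prior quadrature.
#' @return Scalar log likelihood (0 for an empty trial set).
#' @export
log_likelihood <- function(trials, template, w_s, w_m, prior_step = 5) {
  cache <- .likelihood_cache(trials, template, prior_step)
  .cache_loglik(cache, template, w_s, w_m)
}

# ---------------------------------------------------------------------------
# Marginal likelihood (evidence)

# Beta(1.3, 2.6) prior on each coefficient of variation
BETA_SHAPE1 <- 1.3
BETA_SHAPE2 <- 2.6

.log_param_prior <- function(w) {
  stats::dbeta(w, BETA_SHAPE1, BETA_SHAPE2, log = TRUE)
}

#' Marginal likelihood of an observer-model template
#'
#' Integrates the trial likelihood over the independent Beta(1.3, 2.6)
#' priors on `(w_s, w_m)`, by two-dimensional quadrature on a log-spaced
#' grid and/or by Laplace approximation around the MAP (in log-parameter
#' coordinates). The two routes should agree closely whenever the MAP is
#' interior to the grid.
#'
#' @param trials A trial table (one subject; may span several blocks).
#' @param template An [observer_template()].
#' @param method `"both"`, `"grid"` or `"laplace"`.
#' @param grid_n Nodes per dimension for the quadrature grid.
#' @param w_range Range of `w` covered by the grid.
#' @param prior_step Subsampling step (ms) for continuous prior quadrature.
#' @return An object of class `model_evidence` with fields
#'   `log_evidence_grid`, `log_evidence_laplace`, `log_evidence` (grid when
#'   available, else Laplace), `map` (the MAP `w_s`, `w_m`), `param_grid`
#'   (node weights, for posterior-parameter averaging), `boundary` flag and
#'   the template.
#' @export
marginal_likelihood <- function(trials, template,
                                method = c("both", "grid", "laplace"),
                                grid_n = 60, w_range = c(0.01, 0.6),
                                prior_step = 5) {
  method <- match.arg(method)
  cache <- .likelihood_cache(trials, template, prior_step)
  ll <- function(ws, wm) .cache_loglik(cache, template, ws, wm)

  out <- list(template = template, n_trials = cache$n,
              log_evidence_grid = NA_real_,
              log_evidence_laplace = NA_real_,
              map = c(w_s = NA_real_, w_m = NA_real_),
              boundary = FALSE, param_grid = NULL)

  if (method %in% c("both", "grid")) {
    w <- exp(seq(log(w_range[1]), log(w_range[2]), length.out = grid_n))
    lw <- log(w)
    # exact Beta prior mass of the log-spaced cell around each node
    # (endpoint cells absorb the tails, so a constant likelihood
    # integrates exactly)
    cellb <- c(0, exp((lw[-1] + lw[-grid_n]) / 2), 1)
    lm <- log(diff(stats::pbeta(cellb, BETA_SHAPE1, BETA_SHAPE2)))
    L <- matrix(NA_real_, grid_n, grid_n)
    for (i in seq_len(grid_n)) {
      for (j in seq_len(grid_n)) L[i, j] <- ll(w[i], w[j])
    }
    integ <- L + outer(lm, lm, "+")
    out$log_evidence_grid <- logsumexp(integ)
    post <- exp(integ - out$log_evidence_grid)
    idx <- which(post == max(post), arr.ind = TRUE)[1, ]
    out$map <- c(w_s = w[idx[1]], w_m = w[idx[2]])
    nodes <- expand.grid(w_s = w, w_m = w)
    out$param_grid <- data.frame(nodes, weight = as.vector(post))
    if (idx[1] %in% c(1L, grid_n) || idx[2] %in% c(1L, grid_n)) {
      out$boundary <- TRUE
    }
  }

  if (method %in% c("both", "laplace")) {
    lap <- .laplace_evidence(ll)
    out$log_evidence_laplace <- lap$log_evidence
    if (method == "laplace") {
      out$map <- lap$map
      out$boundary <- lap$boundary
    }
    if (lap$boundary) {
      warning("MAP near the parameter-space boundary; Laplace evidence ",
              "may be unreliable")
    }
  }

  out$log_evidence <- if (!is.na(out$log_evidence_grid)) {
    out$log_evidence_grid
  } else {
    out$log_evidence_laplace
  }
  class(out) <- "model_evidence"
  out
}

# Laplace approximation in eta = log w coordinates (Jacobian included).
.laplace_evidence <- function(ll) {
  lpost <- function(eta) {
    w <- exp(eta)
    if (any(w >= 1)) return(-Inf)
    ll(w[1], w[2]) + sum(.log_param_prior(w) + eta)
  }
  # coarse scan, then Nelder-Mead refinement
  scan <- exp(seq(log(0.04), log(0.3), length.out = 3))
  best <- NULL
  for (a in scan) for (b in scan) {
    v <- lpost(log(c(a, b)))
    if (is.null(best) || v > best$v) best <- list(v = v, eta = log(c(a, b)))
  }
  opt <- stats::optim(best$eta, function(e) -lpost(e),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-6, maxit = 200))
  eta <- opt$par
  f0 <- -opt$value
  h <- 0.02
  H <- matrix(NA_real_, 2, 2)
  fpp <- function(d1, d2) lpost(eta + c(d1, d2))
  H[1, 1] <- (fpp(h, 0) - 2 * f0 + fpp(-h, 0)) / h^2
  H[2, 2] <- (fpp(0, h) - 2 * f0 + fpp(0, -h)) / h^2
  H[1, 2] <- H[2, 1] <-
    (fpp(h, h) - fpp(h, -h) - fpp(-h, h) + fpp(-h, -h)) / (4 * h^2)
  detH <- H[1, 1] * H[2, 2] - H[1, 2]^2
  w_map <- exp(eta)
  boundary <- any(w_map < 0.012 | w_map > 0.55)
  log_ev <- if (detH > 0 && H[1, 1] < 0) {
    f0 + log(2 * pi) - 0.5 * log(detH)
  } else {
    NA_real_
  }
  list(log_evidence = log_ev, map = c(w_s = w_map[1], w_m = w_map[2]),
       boundary = boundary || !is.finite(log_ev))
}

#' @export
print.model_evidence <- function(x, ...) {
  t <- x$template
  cat(sprintf("model [%s/%s sens/mot, prior %s, %s loss]: ", t$sensory,
              t$motor, t$prior_scheme, t$loss))
  cat(sprintf("log evidence grid %.2f, Laplace %.2f; MAP w_s=%.3f w_m=%.3f\n",
              x$log_evidence_grid, x$log_evidence_laplace,
              x$map[1], x$map[2]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Posterior over models and components

#' Evidence table
#'
#' @param evidences A list of `model_evidence` objects.
#' @return Data frame with one row per model: components, log evidences,
#'   posterior probability (flat model prior) and MAP parameters.
#' @export
evidence_table <- function(evidences) {
  df <- do.call(rbind, lapply(evidences, function(e) {
    t <- e$template
    data.frame(sensory = t$sensory, motor = t$motor,
               prior_scheme = t$prior_scheme, loss = t$loss,
               log_evidence_grid = e$log_evidence_grid,
               log_evidence_laplace = e$log_evidence_laplace,
               log_evidence = e$log_evidence,
               map_w_s = unname(e$map[1]), map_w_m = unname(e$map[2]))
  }))
  df$posterior <- exp(df$log_evidence - logsumexp(df$log_evidence))
  df
}

#' Posterior probability of each model component
#'
#' For each component family (sensory kind, motor kind, prior scheme, loss
#' kind), sums posterior model probabilities over the other components.
#'
#' @param evidences A list of `model_evidence` objects, or an
#'   [evidence_table()] data frame.
#' @return Named list of data frames (`sensory`, `motor`, `prior_scheme`,
#'   `loss`), each with `level` and `posterior`.
#' @export
component_posteriors <- function(evidences) {
  df <- if (is.data.frame(evidences)) evidences else evidence_table(evidences)
  if (is.null(df$posterior)) {
    df$posterior <- exp(df$log_evidence - logsumexp(df$log_evidence))
  }
  fams <- c("sensory", "motor", "prior_scheme", "loss")
  out <- lapply(fams, function(f) {
    agg <- stats::aggregate(df$posterior, by = list(level = df[[f]]), FUN = sum)
    names(agg)[2] <- "posterior"
    agg[order(-agg$posterior), , drop = FALSE]
  })
  names(out) <- fams
  out
}

# simpler level first, used for tie-breaking modal components
.component_order <- list(
  sensory = c("constant", "scalar"),
  motor = c("constant", "scalar"),
  prior_scheme = letters[1:7],
  loss = c("standard", "fractional", "skewed")
)

#' Modal component levels
#'
#' The highest-posterior level of each component family; exact ties are
#' broken toward the simpler level (constant before scalar, standard
#' before skewed).
#'
#' @param evidences As in [component_posteriors()].
#' @return Named character vector.
#' @export
modal_components <- function(evidences) {
  cp <- component_posteriors(evidences)
  vapply(names(cp), function(f) {
    tab <- cp[[f]]
    best <- tab$posterior >= max(tab$posterior) - 1e-12
    lv <- tab$level[best]
    ord <- .component_order[[f]]
    lv[order(match(lv, ord))][1]
  }, character(1))
}

# ---------------------------------------------------------------------------
# Bayesian model averaging of predicted curves

#' Bayesian-model-averaged bias and SD curves
#'
#' Posterior-weighted average of the predicted per-interval response bias
#' and standard deviation, averaging both over models and over the
#' `(w_s, w_m)` posterior of each model (no point fitting). Models below
#' `min_model_weight` posterior probability are skipped; each model's
#' parameter posterior is truncated to its `top_nodes` heaviest quadrature
#' nodes (renormalized).
#'
#' @param evidences List of `model_evidence` objects computed with the grid
#'   method (Laplace-only evidences fall back to their MAP point).
#' @param block_name Block whose intervals the curves are evaluated at.
#' @param min_model_weight,top_nodes Truncation controls.
#' @param r_step Quadrature step (ms) for the response moments.
#' @return Data frame `x`, `bias`, `sd`.
#' @export
model_average_curves <- function(evidences, block_name,
                                 min_model_weight = 1e-3, top_nodes = 25,
                                 r_step = 2) {
  dist <- make_block_distribution(block_name)
  df <- evidence_table(evidences)
  keep <- which(df$posterior > min_model_weight)
  bias <- sd <- rep(0, length(dist$support))
  wtot <- 0
  for (k in keep) {
    e <- evidences[[k]]
    pg <- e$param_grid
    if (is.null(pg)) {
      pg <- data.frame(w_s = e$map[1], w_m = e$map[2], weight = 1)
    }
    pg <- pg[order(-pg$weight), , drop = FALSE]
    pg <- pg[seq_len(min(top_nodes, nrow(pg))), , drop = FALSE]
    pg$weight <- pg$weight / sum(pg$weight)
    for (i in seq_len(nrow(pg))) {
      obs <- observer_for_block(e$template, block_name,
                                pg$w_s[i], pg$w_m[i])
      cur <- bias_sd_curves(obs, dist, r_step = r_step)
      wgt <- df$posterior[k] * pg$weight[i]
      bias <- bias + wgt * cur$bias
      sd <- sd + wgt * cur$sd
      wtot <- wtot + wgt
    }
  }
  data.frame(x = dist$support, bias = bias / wtot, sd = sd / wtot)
}
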