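# Experimental interval distributions and candidate subjective priors.

#' Discrete experimental interval distribution
#'
#' A discrete distribution over target interval durations, as used in the
#' interval reproduction task: each block presents one of a small set of
#' durations spaced 75 ms apart, with block-specific probabilities.
#'
#' @param support Durations in ms, strictly increasing.
#' @param probs Probabilities, nonnegative, summing to 1.
#' @param label Text identifier (e.g. `"medium_peaked"`).
#' @return An object of class `interval_distribution`.
#' @export
interval_distribution <- function(support, probs, label = "custom") {
  if (length(support) != length(probs)) {
    stop("support and probs must have the same length")
  }
  if (any(diff(support) <= 0)) stop("support must be strictly increasing")
  if (any(probs < 0)) stop("probabilities must be nonnegative")
  if (abs(sum(probs) - 1) > 1e-12) stop("probabilities must sum to 1")
  structure(list(support = as.numeric(support), probs = as.numeric(probs),
                 label = label),
            class = "interval_distribution")
}

#' Continuous prior density on a duration grid
#'
#' @param grid Regularly spaced durations in ms.
#' @param density Nonnegative density values on `grid`; renormalized so the
#'   trapezoidal integral is 1.
#' @param label Text identifier.
#' @return An object of class `continuous_prior`.
#' @export
continuous_prior <- function(grid, density, label = "custom") {
  if (length(grid) != length(density)) stop("grid and density lengths differ")
  if (any(density < 0)) stop("density must be nonnegative")
  z <- trapz_integral(grid, density)
  if (z <= 0) stop("density integrates to zero")
  structure(list(grid = as.numeric(grid), density = as.numeric(density) / z,
                 label = label),
            class = "continuous_prior")
}

#' @export
print.interval_distribution <- function(x, ...) {
  cat("Discrete interval distribution:", x$label, "\n")
  print(data.frame(ms = x$support, prob = signif(x$probs, 4)))
  invisible(x)
}

#' @export
print.continuous_prior <- function(x, ...) {
  cat("Continuous prior:", x$label, "on [", min(x$grid), ",", max(x$grid),
      "] ms (", length(x$grid), "points )\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Block registry

# The experimental blocks. Ranges: Short 450-825, Medium 600-975,
# Long 750-1125, Wide 450-1125 ms, 75-ms spacing (6 intervals, 10 for Wide).
# Probabilities are stored as exact rationals (num/den) to avoid drift.
.block_registry_default <- function() {
  rng <- list(short = seq(450, 825, by = 75),
              medium = seq(600, 975, by = 75),
              long = seq(750, 1125, by = 75),
              wide = seq(450, 1125, by = 75))
  peak_probs <- function(support, peak, p_num, p_den) {
    p <- rep((p_den - p_num) / (length(support) - 1) / p_den, length(support))
    p[support == peak] <- p_num / p_den
    p
  }
  list(
    short_uniform = list(range = "short", support = rng$short,
                         probs = rep(1 / 6, 6)),
    medium_uniform = list(range = "medium", support = rng$medium,
                          probs = rep(1 / 6, 6)),
    long_uniform = list(range = "long", support = rng$long,
                        probs = rep(1 / 6, 6)),
    wide_uniform = list(range = "wide", support = rng$wide,
                        probs = rep(1 / 10, 10)),
    medium_peaked = list(range = "medium", support = rng$medium,
                         probs = peak_probs(rng$medium, 675, 7, 12)),
    medium_high_peaked = list(range = "medium", support = rng$medium,
                              probs = peak_probs(rng$medium, 675, 19, 24)),
    medium_bimodal = list(range = "medium", support = rng$medium,
                          probs = ifelse(rng$medium %in% c(600, 975),
                                         1 / 3, 1 / 12)),
    wide_bimodal = list(range = "wide", support = rng$wide,
                        probs = ifelse(rng$wide %in% c(675, 750, 825, 900),
                                       1 / 28, 1 / 7))
  )
}

.block_registry <- local({
  reg <- NULL
  function(reset = FALSE) {
    if (is.null(reg) || reset) reg <<- .block_registry_default()
    reg
  }
})

#' Names of the registered experimental blocks
#' @return Character vector of block names.
#' @export
block_names <- function() names(.block_registry())

#' Interval range of a block
#'
#' @param block_name A registered block name.
#' @return One of `"short"`, `"medium"`, `"long"`, `"wide"`.
#' @export
block_range <- function(block_name) {
  .block_entry(block_name)$range
}

.block_entry <- function(block_name) {
  reg <- .block_registry()
  if (!block_name %in% names(reg)) {
    stop("unknown block '", block_name, "'; valid blocks: ",
         paste(names(reg), collapse = ", "))
  }
  reg[[block_name]]
}

#' Construct a block's experimental distribution
#'
#' Returns the exact discrete distribution of target intervals used in the
#' named block: Uniform blocks assign equal probability to each interval;
#' Peaked/High-Peaked blocks present the 675-ms `peak' interval with
#' probability 7/12 and 19/24 respectively (the remaining intervals being
#' equiprobable); the Medium Bimodal block presents 600 and 975 ms with
#' probability 1/3 each, and the Wide Bimodal block makes the six extremal
#' intervals four times as frequent as the four middle ones.
#'
#' @param block_name One of [block_names()].
#' @return An [interval_distribution()].
#' @export
make_block_distribution <- function(block_name) {
  e <- .block_entry(block_name)
  interval_distribution(e$support, e$probs, label = block_name)
}

#' Write / read the block registry as a YAML config
#'
#' The registry of named blocks (supports and probabilities) can be
#' serialized so custom distributions can be added without code changes.
#'
#' @param path File path.
#' @return `write_block_registry` returns `path` invisibly;
#'   `read_block_registry` returns the registry list invisibly after
#'   installing it as the active registry.
#' @export
write_block_registry <- function(path) {
  reg <- .block_registry()
  yaml::write_yaml(lapply(reg, function(e) {
    list(range = e$range, support = as.numeric(e$support),
         probs = as.numeric(e$probs))
  }), path, precision = 15)
  invisible(path)
}

#' @rdname write_block_registry
#' @export
read_block_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  reg <- lapply(raw, function(e) {
    list(range = e$range, support = as.numeric(e$support),
         probs = as.numeric(e$probs) / sum(e$probs))
  })
  env <- environment(.block_registry)
  assign("reg", reg, envir = env)
  invisible(reg)
}

# ---------------------------------------------------------------------------
# Moments

#' Central moments of a distribution
#'
#' Mean, standard deviation, skewness (third standardized central moment)
#' and excess kurtosis (fourth standardized central moment minus 3) of a
#' discrete interval distribution or a continuous prior. Continuous priors
#' are integrated by the trapezoid rule on their grid.
#'
#' @param dist An [interval_distribution()] or [continuous_prior()].
#' @return A list of class `moment_summary` with elements `mean`, `sd`,
#'   `skewness`, `excess_kurtosis`.
#' @export
moments <- function(dist) {
  pn <- prior_nodes(dist)
  m <- sum(pn$mass * pn$x)
  v <- sum(pn$mass * (pn$x - m)^2)
  if (v <= 0) {
    stop("degenerate (single-point) distribution: skewness and kurtosis ",
         "are undefined")
  }
  s <- sqrt(v)
  z <- (pn$x - m) / s
  structure(list(mean = m, sd = s,
                 skewness = sum(pn$mass * z^3),
                 excess_kurtosis = sum(pn$mass * z^4) - 3),
            class = "moment_summary")
}

#' @export
print.moment_summary <- function(x, ...) {
  cat(sprintf("mean %.1f ms, sd %.1f ms, skewness %.2f, ex. kurtosis %.2f\n",
              x$mean, x$sd, x$skewness, x$excess_kurtosis))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Candidate prior approximation schemes (a)-(g)

# Mixture-of-Gaussians density on a grid, truncated and renormalized.
.gaussian_mixture_prior <- function(grid, means, sds, weights, label) {
  dens <- rep(0, length(grid))
  weights <- weights / sum(weights)
  for (k in seq_along(means)) {
    dens <- dens + weights[k] * stats::dnorm(grid, means[k], sds[k])
  }
  continuous_prior(grid, dens, label = label)
}

# sd of the discrete uniform distribution over a block's range
.uniform_range_sd <- function(support) {
  u <- rep(1 / length(support), length(support))
  m <- sum(u * support)
  sqrt(sum(u * (support - m)^2))
}

#' Candidate subjective-prior approximation schemes
#'
#' Builds one of the candidate approximation schemes an observer might use
#' for a block's interval distribution:
#' \describe{
#'   \item{a}{the true discrete distribution;}
#'   \item{b}{a single Gaussian with the true mean and variance;}
#'   \item{c}{a mixture of Gaussians (sd 37.5 ms) centred on the true
#'     intervals, mixing weights equal to the true probabilities;}
#'   \item{d}{as (c) with sd 75 ms;}
#'   \item{e}{a continuous uniform from the shortest to the longest
#'     interval;}
#'   \item{f}{for peaked blocks, a two-component mixture: a narrow Gaussian
#'     (sd 37.5 ms) at the 675-ms peak with weight equal to the proportion
#'     of peak presentations emerging above the uniform background, plus a
#'     broad Gaussian at the range mean with the sd of the discrete uniform
#'     over the range. For bimodal blocks, a three-component analogue with
#'     narrow Gaussians at the two modes (sd 37.5 ms Medium, 61.2 ms Wide).
#'     For the Medium Uniform block the scheme reduces to the single broad
#'     Gaussian;}
#'   \item{g}{as (f) with the narrow sds doubled.}
#' }
#'
#' @param scheme One of `"a"`--`"g"`.
#' @param block_name A registered block name.
#' @param grid Duration grid for continuous schemes.
#' @return An [interval_distribution()] for scheme `"a"`, otherwise a
#'   [continuous_prior()].
#' @export
make_candidate_prior <- function(scheme, block_name, grid = default_grid()) {
  scheme <- match.arg(scheme, c("a", "b", "c", "d", "e", "f", "g"))
  dist <- make_block_distribution(block_name)
  lbl <- paste0(block_name, "_scheme_", scheme)
  if (scheme == "a") return(dist)
  if (scheme == "b") {
    mo <- moments(dist)
    return(.gaussian_mixture_prior(grid, mo$mean, mo$sd, 1, lbl))
  }
  if (scheme %in% c("c", "d")) {
    sd0 <- if (scheme == "c") 37.5 else 75
    return(.gaussian_mixture_prior(grid, dist$support,
                                   rep(sd0, length(dist$support)),
                                   dist$probs, lbl))
  }
  if (scheme == "e") {
    a <- min(dist$support); b <- max(dist$support)
    dens <- as.numeric(grid >= a & grid <= b)
    return(continuous_prior(grid, dens, label = lbl))
  }
  # schemes f/g: peak-emergence mixtures, defined for the Medium family and
  # Wide Bimodal; the narrow sd is 37.5 ms (61.2 ms for Wide), doubled for g
  .fg_prior(scheme, block_name, dist, grid, lbl)
}

.fg_prior <- function(scheme, block_name, dist, grid, lbl) {
  range_support <- .block_entry(block_name)$support
  sd_bg <- .uniform_range_sd(range_support)
  mean_bg <- mean(range_support)
  if (block_name == "medium_uniform") {
    return(.gaussian_mixture_prior(grid, mean_bg, sd_bg, 1, lbl))
  }
  if (block_name %in% c("medium_peaked", "medium_high_peaked")) {
    # emergent peak weight: peak probability minus the uniform background
    pi0 <- if (block_name == "medium_peaked") 1 / 2 else 3 / 4
    sd_pk <- if (scheme == "f") 37.5 else 75
    return(.gaussian_mixture_prior(grid, c(675, mean_bg), c(sd_pk, sd_bg),
                                   c(pi0, 1 - pi0), lbl))
  }
  if (block_name == "medium_bimodal") {
    pi0 <- 1 / 4  # per mode: 1/3 - 1/12
    sd_pk <- if (scheme == "f") 37.5 else 75
    return(.gaussian_mixture_prior(grid, c(600, 975, mean_bg),
                                   c(sd_pk, sd_pk, sd_bg),
                                   c(pi0, pi0, 1 - 2 * pi0), lbl))
  }
  if (block_name == "wide_bimodal") {
    pi0 <- 9 / 28  # per mode: 3 x (1/7 - 1/28)
    sd_pk <- if (scheme == "f") 61.2 else 122.4
    return(.gaussian_mixture_prior(grid, c(525, 1050, mean_bg),
                                   c(sd_pk, sd_pk, sd_bg),
                                   c(pi0, pi0, 1 - 2 * pi0), lbl))
  }
  stop("schemes f/g are not defined for block '", block_name, "'")
}

#' Prior schemes available for a block
#'
#' @param block_name A registered block name.
#' @return Character vector of scheme letters valid for the block.
#' @export
valid_schemes <- function(block_name) {
  base <- c("a", "b", "c", "d", "e")
  if (block_name %in% c("medium_uniform", "medium_peaked",
                        "medium_high_peaked", "medium_bimodal",
                        "wide_bimodal")) {
    c(base, "f", "g")
  } else {
    base
  }
}
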