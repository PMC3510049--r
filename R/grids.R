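# Internal quadrature and grid helpers shared by all modules.

# Default duration grid (ms). Covers every block's allowed-response window
# with margin; all densities in the package are truncated and renormalized
# on this interval.
GRID_MIN <- 150
GRID_MAX <- 1800

#' Default duration grid
#'
#' Regular grid of durations (in ms) on which continuous priors and response
#' densities are represented. The default spans 150--1800 ms at 1-ms spacing,
#' a superset of every block's allowed-response window.
#'
#' @param step Grid spacing in ms.
#' @return Numeric vector of durations.
#' @export
default_grid <- function(step = 1) {
  seq(GRID_MIN, GRID_MAX, by = step)
}

# Trapezoidal quadrature weights for an (arbitrary, increasing) node vector.
trapz_weights <- function(x) {
  n <- length(x)
  if (n < 2L) return(rep(1, n))
  d <- diff(x)
  w <- numeric(n)
  w[1L] <- d[1L] / 2
  w[n] <- d[n - 1L] / 2
  if (n > 2L) w[2:(n - 1L)] <- (d[-1L] + d[-(n - 1L)]) / 2
  w
}

trapz_integral <- function(x, y) sum(trapz_weights(x) * y)

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Reduce a distribution-like object to quadrature nodes with point masses.
# Continuous priors may be subsampled to `step` ms for speed; discrete
# distributions are returned exactly.
prior_nodes <- function(prior, step = NULL) {
  if (inherits(prior, "interval_distribution")) {
    return(list(x = prior$support, mass = prior$probs, discrete = TRUE))
  }
  if (!inherits(prior, "continuous_prior")) {
    stop("prior must be an interval_distribution or continuous_prior")
  }
  g <- prior$grid
  dens <- prior$density
  if (!is.null(step)) {
    by <- max(1L, round(step / (g[2L] - g[1L])))
    idx <- unique(c(seq(1L, length(g), by = by), length(g)))
    g <- g[idx]
    dens <- dens[idx]
  }
  mass <- dens * trapz_weights(g)
  s <- sum(mass)
  if (s <= 0) stop("prior has zero mass on the grid")
  list(x = g, mass = mass / s, discrete = FALSE)
}
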