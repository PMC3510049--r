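# Synthetic trial generation: block designs, exact-proportion runs,
# ground-truth observers, lapses and the trial-retention rules.

# Allowed response windows per interval range (ms), inclusive on both ends.
.allowed_windows <- list(short = c(225, 1237), medium = c(300, 1462),
                         long = c(375, 1687), wide = c(225, 1687))

#' Allowed response window of a block
#'
#' Responses outside this block-dependent window are discarded from
#' analysis: 225--1237 ms (Short range), 300--1462 ms (Medium),
#' 375--1687 ms (Long), 225--1687 ms (Wide). Boundaries are inclusive.
#'
#' @param block_name A registered block name.
#' @return Numeric length-2 vector `(min, max)` in ms.
#' @export
allowed_window <- function(block_name) {
  .allowed_windows[[block_range(block_name)]]
}

# Default run length per block: runs have 84-96 trials and the per-interval
# counts must be integral. 84 works for sixths and twelfths; the High-Peaked
# block (24ths) needs 96; the Wide Uniform block (tenths) uses 90.
.default_run_length <- function(block_name) {
  switch(block_name,
         medium_high_peaked = 96L,
         wide_uniform = 90L,
         84L)
}

#' Block design for a simulated session
#'
#' @param block_name A registered block name.
#' @param feedback `"skewed"` or `"standard"` -- the error map displayed as
#'   feedback (the regime the synthetic subject is assumed to be trained
#'   under; it determines nothing in the generative code beyond metadata,
#'   since the ground-truth observer carries its own loss).
#' @param run_length Trials per run, 84--96 (90 for Wide Uniform); the
#'   product with each interval probability must be an integer so each run
#'   reflects the distribution exactly.
#' @param n_sessions Number of sessions (metadata).
#' @return An object of class `block_design`.
#' @export
block_design <- function(block_name, feedback = c("standard", "skewed"),
                         run_length = .default_run_length(block_name),
                         n_sessions = 2L) {
  feedback <- match.arg(feedback)
  dist <- make_block_distribution(block_name)
  counts <- dist$probs * run_length
  if (any(abs(counts - round(counts)) > 1e-9)) {
    stop("run_length ", run_length, " is incompatible with the '",
         block_name, "' probabilities; use a multiple of ", .lcm_den(dist))
  }
  structure(list(block_name = block_name, distribution = dist,
                 feedback = feedback, run_length = as.integer(run_length),
                 n_sessions = as.integer(n_sessions),
                 allowed_window = allowed_window(block_name)),
            class = "block_design")
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

# smallest run length giving integral per-interval counts
.lcm_den <- function(dist) {
  dens <- vapply(dist$probs, function(p) {
    # probabilities are small rationals; recover the denominator
    for (d in 1:100) if (abs(p * d - round(p * d)) < 1e-9) return(d)
    NA_real_
  }, numeric(1))
  Reduce(function(a, b) a * b / .gcd(a, b), dens)
}

#' Build one run of target intervals
#'
#' Produces a permuted sequence of `run_length` targets in which each
#' interval appears exactly `run_length * p` times. For the High-Peaked
#' block the order additionally satisfies the constraint that every
#' non-peak target is immediately preceded by 3--5 consecutive peak
#' targets.
#'
#' @param design A [block_design()].
#' @param seed Integer seed (optional); the current RNG stream is used when
#'   `NULL`.
#' @return Numeric vector of target durations (ms).
#' @export
build_run <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dist <- design$distribution
  counts <- round(dist$probs * design$run_length)
  if (design$block_name == "medium_high_peaked") {
    return(.build_high_peaked_run(dist, counts))
  }
  sample(rep(dist$support, counts))
}

# High-Peaked runs: rare targets are separated by runs of 3-5 peak targets.
# Compose the peak count into one run of length 3-5 before each rare target
# (trailing peaks, if any, are appended after the last rare target).
.build_high_peaked_run <- function(dist, counts) {
  peak <- 675
  rare <- rep(dist$support[dist$support != peak],
              counts[dist$support != peak])
  n_rare <- length(rare)
  n_peak <- counts[dist$support == peak]
  lens <- rep(3L, n_rare)
  spare <- n_peak - 3L * n_rare
  if (spare < 0) stop("not enough peak targets for the 3-5 constraint")
  # distribute surplus peaks one at a time over groups still below 5;
  # any remainder beyond 5 per group trails at the end of the run
  while (spare > 0 && any(lens < 5L)) {
    i <- sample(which(lens < 5L), 1L)
    lens[i] <- lens[i] + 1L
    spare <- spare - 1L
  }
  rare <- sample(rare)
  out <- unlist(lapply(seq_len(n_rare), function(i) {
    c(rep(peak, lens[i]), rare[i])
  }))
  c(out, rep(peak, spare))
}

#' Simulate trials from a ground-truth observer
#'
#' Generates `n_trials` trials following the generative chain of the task:
#' the target is drawn from exact-proportion runs, the internal measurement
#' from the sensory likelihood, the motor command from the observer's
#' optimal decision rule, and the response from the motor likelihood
#' (truncated to the duration grid), or from the uniform lapse distribution
#' with probability `lapse_rate`.
#'
#' @param design A [block_design()].
#' @param truth An [observer_model()] -- the ground-truth synthetic subject.
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @param subject_id Identifier recorded in the trial table.
#' @return A `trial_set`: data frame with columns `subject_id`, `block`,
#'   `session`, `run`, `trial_index`, `target_ms`, `response_ms`,
#'   `retained`, `lapse`, plus attributes `design` and `seed`.
#' @export
simulate_trials <- function(design, truth, n_trials, seed = 1L,
                            subject_id = "synthetic") {
  set.seed(seed)
  n_runs <- ceiling(n_trials / design$run_length)
  x <- unlist(lapply(seq_len(n_runs), function(i) build_run(design)))
  run <- rep(seq_len(n_runs), each = design$run_length)
  x <- x[seq_len(n_trials)]
  run <- run[seq_len(n_trials)]

  # decision rule tabulated once on a dense measurement grid (2-ms steps;
  # the rule is smooth, linear interpolation error is far below the noise)
  rule <- decision_rule(truth, default_grid(2))
  sds <- noise_sd(truth$sensory, x)
  xm <- pmin(pmax(stats::rnorm(n_trials, x, sds), GRID_MIN), GRID_MAX)
  u <- stats::approx(rule$xm_grid, rule$u_star, xout = xm, rule = 2)$y
  sdm <- noise_sd(truth$motor, u)
  r <- stats::rnorm(n_trials, u, sdm)
  # motor densities are truncated-renormalized on the grid: redraw outliers
  out <- which(r < GRID_MIN | r > GRID_MAX)
  while (length(out) > 0) {
    r[out] <- stats::rnorm(length(out), u[out], sdm[out])
    out <- out[r[out] < GRID_MIN | r[out] > GRID_MAX]
  }
  lapse <- stats::runif(n_trials) < truth$lapse_rate
  if (any(lapse)) {
    r[lapse] <- stats::runif(sum(lapse), truth$lapse_range[1],
                             truth$lapse_range[2])
  }
  trials <- data.frame(subject_id = subject_id,
                       block = design$block_name,
                       session = ((run - 1L) %/% 6L) + 1L,
                       run = run,
                       trial_index = seq_len(n_trials),
                       target_ms = x,
                       response_ms = r,
                       retained = NA,
                       lapse = lapse)
  trials <- filter_trials(trials)
  attr(trials, "design") <- design
  attr(trials, "seed") <- seed
  class(trials) <- c("trial_set", "data.frame")
  trials
}

#' Apply the trial-retention rule
#'
#' Flags each trial as retained if and only if its response falls inside
#' the block-dependent allowed window (boundaries inclusive). Discarded
#' trials are kept in the table, flagged `retained = FALSE`.
#'
#' @param trials A trial table with columns `block` and `response_ms`.
#' @return The table with its `retained` column set.
#' @export
filter_trials <- function(trials) {
  win <- t(vapply(trials$block, allowed_window, numeric(2)))
  trials$retained <- trials$response_ms >= win[, 1] &
    trials$response_ms <= win[, 2]
  trials
}

#' Balance per-interval counts by random subsampling
#'
#' For non-uniform blocks, randomly subsamples the frequently presented
#' intervals among retained trials so that every interval contributes the
#' same number of trials to the model comparison (the minimum per-interval
#' retained count). Not applicable to the Wide Bimodal block, which is
#' analysed in full because per-interval counts are already small.
#'
#' @param trials A trial table (single block).
#' @param seed Integer seed (optional).
#' @return The table with over-represented retained trials flagged
#'   `retained = FALSE`.
#' @export
subsample_balanced <- function(trials, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  blocks <- unique(trials$block)
  if (length(blocks) != 1L) stop("subsample_balanced expects a single block")
  if (blocks == "wide_bimodal") {
    stop("balanced subsampling is not applied to the wide_bimodal block ",
         "(too few trials per interval)")
  }
  keep_idx <- which(trials$retained)
  counts <- table(trials$target_ms[keep_idx])
  n_min <- min(counts)
  drop <- unlist(lapply(names(counts), function(lv) {
    idx <- keep_idx[trials$target_ms[keep_idx] == as.numeric(lv)]
    if (length(idx) > n_min) sample(idx, length(idx) - n_min) else integer(0)
  }))
  if (length(drop)) trials$retained[drop] <- FALSE
  trials
}

#' Write / read a trial table as tab-delimited text
#'
#' @param trials A trial table.
#' @param path File path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns
#'   the trial table.
#' @export
write_trials <- function(trials, path) {
  utils::write.table(as.data.frame(trials), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(tr) <- c("trial_set", "data.frame")
  tr
}

# retained trials only, as needed by the likelihood
retained_trials <- function(trials) {
  if (!is.null(trials$retained)) trials[trials$retained, , drop = FALSE]
  else trials
}
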