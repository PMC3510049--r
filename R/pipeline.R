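# Pipeline orchestration: simulate -> compare -> reconstruct, with config
# files, manifests and reproducible seeding.

#' Pipeline run configuration
#'
#' Builds (and validates) the configuration driving [run_pipeline()].
#' Configurations round-trip losslessly through YAML.
#'
#' @param x A named list, or path to a YAML file.
#' @return A list of class `run_config` with elements:
#' \describe{
#'   \item{stages}{subset of `c("simulate", "compare", "reconstruct")`.}
#'   \item{designs}{list of design specs: `block`, `feedback`, `n_trials`,
#'     optional `run_length`.}
#'   \item{truth}{ground-truth observer spec for synthetic runs: `sensory`
#'     and `motor` (`kind`, `w`), `prior_scheme`, `loss`, `lapse_rate`.}
#'   \item{model_space}{optional restriction lists `sensory`, `motor`,
#'     `prior_schemes`, `losses`.}
#'   \item{comparison}{`method`, `grid_n`.}
#'   \item{reconstruction}{`chains`, `burn_in`, `keep`, `block`.}
#'   \item{seed}{master integer seed; per-stage streams are derived.}
#'   \item{out_dir}{artifact directory.}
#' }
#' @export
run_config <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- yaml::read_yaml(x)
  stopifnot(is.list(x))
  defaults <- list(
    stages = c("simulate", "compare", "reconstruct"),
    designs = list(list(block = "medium_uniform", feedback = "standard",
                        n_trials = 500)),
    truth = list(sensory = list(kind = "scalar", w = 0.1),
                 motor = list(kind = "scalar", w = 0.1),
                 prior_scheme = "c", loss = "standard", lapse_rate = 0),
    model_space = list(sensory = c("constant", "scalar"),
                       motor = c("constant", "scalar"),
                       prior_schemes = c("a", "b", "c", "d", "e"),
                       losses = c("standard", "fractional", "skewed")),
    comparison = list(method = "laplace", grid_n = 60),
    reconstruction = list(chains = 2, burn_in = 300, keep = 300),
    seed = 1L,
    out_dir = "timepriors_run"
  )
  cfg <- utils::modifyList(defaults, x)
  # designs is an unnamed list of specs: replace, never element-merge
  if (!is.null(x$designs)) cfg$designs <- x$designs
  cfg$stages <- match.arg(cfg$stages,
                          c("simulate", "compare", "reconstruct"),
                          several.ok = TRUE)
  structure(cfg, class = c("run_config", "list"))
}

#' Write a configuration to YAML
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# observer from a truth spec in the config, for a given block
.truth_observer <- function(truth, block) {
  observer_model(
    noise_model(truth$sensory$kind, truth$sensory$w),
    noise_model(truth$motor$kind, truth$motor$w),
    make_candidate_prior(truth$prior_scheme, block),
    loss_spec(truth$loss),
    lapse_rate = if (is.null(truth$lapse_rate)) 0 else truth$lapse_rate
  )
}

#' Restrict the model space from a configuration
#'
#' @param config A [run_config()] (its `model_space` element may name a
#'   subset of levels for each component family; an empty restriction
#'   means the full space).
#' @return A [model_space()] list.
#' @export
restrict_model_space <- function(config) {
  ms <- config$model_space
  if (is.null(ms)) ms <- list()
  full <- list(sensory = c("constant", "scalar"),
               motor = c("constant", "scalar"),
               prior_schemes = c("a", "b", "c", "d", "e"),
               losses = c("standard", "fractional", "skewed"))
  for (nm in names(ms)) {
    if (!nm %in% names(full)) stop("unknown model-space component '", nm, "'")
    bad <- setdiff(ms[[nm]], full[[nm]])
    if (length(bad)) {
      stop("unknown ", nm, " level(s): ", paste(bad, collapse = ", "))
    }
  }
  ms <- utils::modifyList(full, ms)
  model_space(sensory = ms$sensory, motor = ms$motor,
              prior_schemes = ms$prior_schemes, losses = ms$losses)
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in order: `simulate` writes a trial table
#' per design; `compare` computes the evidence table over the (possibly
#' restricted) model space; `reconstruct` slice-samples the subjective
#' prior for one block using the fixed components implied by the
#' comparison. Later stages read earlier stages' artifacts, so a stage can
#' be re-run from prior outputs; a missing upstream artifact is an error
#' naming the stage to run first. A JSON manifest records the config,
#' seeds and package version.
#'
#' @param config A [run_config()] (or list / YAML path accepted by it).
#' @return The artifact directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  config <- run_config(unclass(config))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  trials_path <- file.path(config$out_dir, "trials.tsv")
  evidence_path <- file.path(config$out_dir, "evidence.tsv")
  samples_path <- file.path(config$out_dir, "prior_samples.tsv")
  summary_path <- file.path(config$out_dir, "prior_moments.tsv")

  if ("simulate" %in% config$stages) {
    all <- lapply(seq_along(config$designs), function(i) {
      d <- config$designs[[i]]
      des <- block_design(d$block, d$feedback,
                         run_length = if (is.null(d$run_length)) {
                           .default_run_length(d$block)
                         } else {
                           d$run_length
                         })
      simulate_trials(des, .truth_observer(config$truth, d$block),
                      d$n_trials, seed = seed + 1000L * i,
                      subject_id = "synthetic")
    })
    trials <- do.call(rbind, lapply(all, as.data.frame))
    write_trials(trials, trials_path)
    message("simulate: wrote ", nrow(trials), " trials to ", trials_path)
  }

  evidences <- NULL
  if ("compare" %in% config$stages) {
    if (!file.exists(trials_path)) {
      stop("missing ", trials_path, "; run the 'simulate' stage first")
    }
    trials <- read_trials(trials_path)
    space <- restrict_model_space(config)
    evidences <- lapply(space, function(tp) {
      marginal_likelihood(trials, tp, method = config$comparison$method,
                          grid_n = config$comparison$grid_n)
    })
    tab <- evidence_table(evidences)
    utils::write.table(tab, evidence_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    message("compare: wrote ", nrow(tab), " model evidences to ",
            evidence_path)
  }

  if ("reconstruct" %in% config$stages) {
    if (!file.exists(trials_path)) {
      stop("missing ", trials_path, "; run the 'simulate' stage first")
    }
    trials <- read_trials(trials_path)
    rb <- config$reconstruction$block
    if (is.null(rb)) rb <- trials$block[1]
    trials <- trials[trials$block == rb, , drop = FALSE]
    fx <- if (!is.null(evidences)) {
      fixed_components_from_evidence(evidences)
    } else if (file.exists(evidence_path)) {
      tab <- utils::read.delim(evidence_path)
      best <- tab[which.max(tab$log_evidence), ]
      fixed_components(noise_model(best$sensory, best$map_w_s),
                       noise_model(best$motor, best$map_w_m),
                       loss_spec(best$loss))
    } else {
      stop("missing ", evidence_path, "; run the 'compare' stage first")
    }
    ps <- slice_sample_priors(trials, fx,
                              chains = config$reconstruction$chains,
                              burn_in = config$reconstruction$burn_in,
                              keep = config$reconstruction$keep,
                              seed = seed + 7L)
    write_prior_samples(ps, samples_path)
    utils::write.table(summarize_prior_moments(ps), summary_path,
                       sep = "\t", row.names = FALSE, quote = FALSE)
    message("reconstruct: wrote ", nrow(ps$samples), " sampled priors to ",
            samples_path)
  }

  manifest <- list(
    package = "timepriors",
    version = as.character(utils::packageVersion("timepriors")),
    date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    seed = seed,
    config = unclass(config)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(config$out_dir)
}
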