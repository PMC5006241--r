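#' Configure an end-to-end pipeline run
#'
#' Bundles the design, the simulation truth, the sampler settings and the
#' output location for a seeded simulate - preprocess - fit - report -
#' recover run. Defaults follow the emulated study throughout: 4 sessions,
#' 15 repetitions per cell, durations 450/650/850 ms, and 3 runs x 2000
#' iterations keeping the latter 1000.
#'
#' @param design A [design_config()].
#' @param truth Optional [generative_params()]; if `NULL` the defaults are
#'   used with random effects drawn under the master seed.
#' @param n_chains,n_iter,n_warmup Sampler settings.
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed; the simulation and fitting substream seeds are
#'   derived from it and recorded in the manifest.
#' @param quiet Suppress progress messages?
#' @return A `flick_pipeline_config`.
#' @export
pipeline_config <- function(design = design_config(),
                            truth = NULL,
                            n_chains = 3, n_iter = 2000, n_warmup = 1000,
                            out_dir = tempfile("flickertime-run-"),
                            seed = 1, quiet = FALSE) {
  stopifnot(inherits(design, "flick_design_config"))
  if (n_chains < 1L) stop("`n_chains` must be >= 1.", call. = FALSE)
  if (n_warmup >= n_iter) {
    stop("`n_warmup` must be smaller than `n_iter`.", call. = FALSE)
  }
  if (!is.null(truth)) validate_params(truth)
  structure(
    list(design = design, truth = truth,
         n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
         n_warmup = as.integer(n_warmup),
         out_dir = out_dir, seed = as.integer(seed), quiet = isTRUE(quiet)),
    class = "flick_pipeline_config"
  )
}

pipeline_log <- function(config, log_path, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  if (!config$quiet) message(line)
  cat(line, "\n", file = log_path, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Simulates an experiment from the configured truth, applies gaze exclusion
#' and side merging, fits the model, summarizes the posterior with the
#' directional comparisons, and scores recovery against the truth. All
#' artifacts are written under `config$out_dir`: `trials.csv`,
#' `truth_params.json`, `exclusion_report.csv`, `posterior.csv`,
#' `summary.csv`, `comparisons.csv`, `recovery.json`, `manifest.json` and
#' `run.log`. The same configuration and seed reproduce every file
#' byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fitted objects and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "flick_pipeline_config"))
  # validate before any file is written
  if (config$n_warmup >= config$n_iter) {
    stop("`n_warmup` must be smaller than `n_iter`.", call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(config$out_dir, c(
    trials = "trials.csv", truth = "truth_params.json",
    exclusion = "exclusion_report.csv", posterior = "posterior.csv",
    summary = "summary.csv", comparisons = "comparisons.csv",
    recovery = "recovery.json", manifest = "manifest.json", log = "run.log"
  ))
  names(paths) <- c("trials", "truth", "exclusion", "posterior", "summary",
                    "comparisons", "recovery", "manifest", "log")
  cat("", file = paths[["log"]])

  set.seed(config$seed)
  sim_seed <- sample.int(.Machine$integer.max, 1)
  fit_seed <- sample.int(.Machine$integer.max, 1)

  pipeline_log(config, paths[["log"]],
               sprintf("simulate: experiment %d, seed %d",
                       config$design$experiment, sim_seed))
  design <- config$design
  design$seed <- sim_seed
  sim <- simulate_experiment(design, config$truth)
  truth <- attr(sim, "truth")
  write_trials(sim, paths[["trials"]])
  write_params(truth, paths[["truth"]])

  pipeline_log(config, paths[["log"]], "preprocess: gaze exclusion + side merge")
  excl <- apply_gaze_exclusion(sim)
  kept <- merge_target_sides(excl$trials)
  readr::write_csv(excl$report, paths[["exclusion"]])

  pipeline_log(config, paths[["log"]],
               sprintf("fit: %d chains x %d iterations (warmup %d), seed %d",
                       config$n_chains, config$n_iter, config$n_warmup, fit_seed))
  fit <- fit_flicker_model(kept, n_chains = config$n_chains,
                           n_iter = config$n_iter, n_warmup = config$n_warmup,
                           seed = fit_seed)
  readr::write_csv(fit$draws, paths[["posterior"]])
  readr::write_csv(fit$summary, paths[["summary"]])
  readr::write_csv(fit$comparisons, paths[["comparisons"]])

  pipeline_log(config, paths[["log"]], "recover: scoring against truth")
  recovery <- recovery_report(truth, fit$summary)
  jsonlite::write_json(
    list(
      parameters = recovery,
      mean_abs_bias_beta_mu = attr(recovery, "mean_abs_bias_beta_mu"),
      coverage_beta_mu = attr(recovery, "coverage_beta_mu")
    ),
    paths[["recovery"]], auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )

  manifest <- list(
    package = "flickertime",
    version = as.character(utils::packageVersion("flickertime")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, sim_seed = sim_seed, fit_seed = fit_seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    artifacts = basename(paths[setdiff(names(paths), c("manifest", "log"))])
  )
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE)
  pipeline_log(config, paths[["log"]], "done")

  invisible(list(trials = sim, truth = truth, exclusion = excl$report,
                 fit = fit, recovery = recovery, paths = paths))
}

#' File-based pipeline stages
#'
#' Thin wrappers that compose the pipeline through CSV/JSON handoff:
#' `stage_simulate()` writes a trial table and its truth sidecar,
#' `stage_preprocess()` reads a trial table and writes the kept trials and
#' exclusion report, `stage_fit()` fits the model to a kept-trials file and
#' writes the posterior draws, `stage_report()` summarizes a posterior file,
#' and `stage_recover()` scores a summary file against a truth sidecar.
#' Running the stages in order with the seeds recorded in a
#' [run_pipeline()] manifest reproduces the monolithic run. A missing
#' upstream file raises an error naming the expected path.
#'
#' @param cfg A [design_config()] (with its seed set) for simulation.
#' @param out_dir Directory to write stage outputs into.
#' @param trials_file,posterior_file,summary_file,truth_file Input paths.
#' @param n_chains,n_iter,n_warmup,seed Sampler settings for `stage_fit()`.
#' @return Each stage invisibly returns the path(s) it wrote.
#' @name pipeline_stages
NULL

require_file <- function(path, what) {
  if (!file.exists(path)) {
    stop(sprintf("Expected %s at '%s' but it does not exist.", what, path),
         call. = FALSE)
  }
  path
}

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_experiment(cfg)
  write_trials(sim, file.path(out_dir, "trials.csv"))
  write_params(attr(sim, "truth"), file.path(out_dir, "truth_params.json"))
  invisible(file.path(out_dir, c("trials.csv", "truth_params.json")))
}

#' @rdname pipeline_stages
#' @export
stage_preprocess <- function(trials_file, out_dir) {
  require_file(trials_file, "a trial table")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trials <- read_trials(trials_file)
  excl <- apply_gaze_exclusion(trials)
  kept <- merge_target_sides(excl$trials)
  write_trials(kept, file.path(out_dir, "kept_trials.csv"))
  readr::write_csv(excl$report, file.path(out_dir, "exclusion_report.csv"))
  invisible(file.path(out_dir, c("kept_trials.csv", "exclusion_report.csv")))
}

#' @rdname pipeline_stages
#' @export
stage_fit <- function(trials_file, out_dir, n_chains = 3, n_iter = 2000,
                      n_warmup = 1000, seed = 1) {
  require_file(trials_file, "a kept-trials table")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fit <- fit_flicker_model(read_trials(trials_file), n_chains = n_chains,
                           n_iter = n_iter, n_warmup = n_warmup, seed = seed)
  readr::write_csv(fit$draws, file.path(out_dir, "posterior.csv"))
  invisible(file.path(out_dir, "posterior.csv"))
}

#' @rdname pipeline_stages
#' @export
stage_report <- function(posterior_file, out_dir) {
  require_file(posterior_file, "a posterior draws table")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  draws <- readr::read_csv(posterior_file, show_col_types = FALSE,
                           progress = FALSE)
  readr::write_csv(summarize_posterior(draws), file.path(out_dir, "summary.csv"))
  readr::write_csv(condition_ratio_tests(draws),
                   file.path(out_dir, "comparisons.csv"))
  invisible(file.path(out_dir, c("summary.csv", "comparisons.csv")))
}

#' @rdname pipeline_stages
#' @export
stage_recover <- function(summary_file, truth_file, out_dir) {
  require_file(summary_file, "a posterior summary table")
  require_file(truth_file, "a truth parameter sidecar")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- readr::read_csv(summary_file, show_col_types = FALSE,
                             progress = FALSE)
  recovery <- recovery_report(read_params(truth_file), summary)
  jsonlite::write_json(
    list(parameters = recovery,
         mean_abs_bias_beta_mu = attr(recovery, "mean_abs_bias_beta_mu"),
         coverage_beta_mu = attr(recovery, "coverage_beta_mu")),
    file.path(out_dir, "recovery.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  invisible(file.path(out_dir, "recovery.json"))
}
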