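#' Generative / model parameters for the location-scale model
#'
#' One parameter object serves both as simulation truth and as the fitted
#' model's parameter layout. The reproduced duration of a trial in condition
#' `c`, target duration `d`, by participant `s` is normal with
#' mean `beta_mu[c] * (gamma_mu[d] + u_mu[s])` and standard deviation
#' `beta_sigma[c] * (gamma_sigma[d] + u_sigma[s])`. The `SS` multipliers are
#' fixed at 1 so that `beta_mu[c]` is directly the dilation ratio of
#' condition `c` relative to the stable-stable baseline.
#'
#' Default effect sizes place the dilation ratios at 1.20 (`FS`), 1.10
#' (`SFi`) and 1.05 (`SFc`), an ordering in which a flickering target dilates
#' most and an ipsilateral flickering distractor more than a contralateral
#' one. Duration effects default to veridical means and a roughly Weberian
#' spread of 20% of the target duration; participant random effects default
#' to draws from `N(0, tau_mu^2)` and `N(0, tau_sigma^2)` with `tau_mu = 60`
#' ms and `tau_sigma = 20` ms.
#'
#' @param participants Character vector of participant ids.
#' @param beta_mu,beta_sigma Named condition multipliers for the mean and SD;
#'   must include `SS = 1`.
#' @param gamma_mu,gamma_sigma Named per-duration effects (ms); names are the
#'   target durations.
#' @param u_mu,u_sigma Named per-participant random effects (ms); if `NULL`
#'   they are drawn from their population distributions using the ambient
#'   RNG.
#' @param tau_mu,tau_sigma Population SDs (ms) of the random effects.
#' @return An object of class `flick_params`.
#' @examples
#' set.seed(1)
#' p <- generative_params(participants = sprintf("P%02d", 1:3))
#' p$beta_mu
#' @export
generative_params <- function(participants = sprintf("P%02d", 1:11),
                              beta_mu = c(SS = 1, FS = 1.20, SFi = 1.10, SFc = 1.05),
                              beta_sigma = c(SS = 1, FS = 1.20, SFi = 1.10, SFc = 1.05),
                              gamma_mu = c(`450` = 450, `650` = 650, `850` = 850),
                              gamma_sigma = c(`450` = 90, `650` = 130, `850` = 170),
                              u_mu = NULL,
                              u_sigma = NULL,
                              tau_mu = 60,
                              tau_sigma = 20) {
  n <- length(participants)
  if (is.null(u_mu)) u_mu <- stats::setNames(stats::rnorm(n, 0, tau_mu), participants)
  if (is.null(u_sigma)) {
    u_sigma <- stats::setNames(stats::rnorm(n, 0, tau_sigma), participants)
  }
  params <- structure(
    list(
      beta_mu = beta_mu, beta_sigma = beta_sigma,
      gamma_mu = gamma_mu, gamma_sigma = gamma_sigma,
      u_mu = u_mu, u_sigma = u_sigma,
      tau_mu = tau_mu, tau_sigma = tau_sigma
    ),
    class = "flick_params"
  )
  validate_params(params)
  params
}

#' @rdname generative_params
#' @param ... Passed to [generative_params()].
#' @export
model_params <- function(...) generative_params(...)

#' Validate a parameter object
#'
#' Checks the structural invariants of [generative_params()]: the `SS`
#' multipliers are exactly 1, all multipliers and `gamma_sigma` and the
#' `tau`s are positive, the random effects are named consistently, and every
#' participant x duration spread `gamma_sigma[d] + u_sigma[s]` is positive.
#'
#' @param params A `flick_params` object.
#' @return `params`, invisibly; errors describe the violated invariant.
#' @export
validate_params <- function(params) {
  stopifnot(inherits(params, "flick_params"))
  for (nm in c("beta_mu", "beta_sigma")) {
    b <- params[[nm]]
    if (!"SS" %in% names(b) || b[["SS"]] != 1) {
      stop(sprintf("`%s[SS]` must be exactly 1 (baseline normalization).", nm),
           call. = FALSE)
    }
    if (any(b <= 0)) stop(sprintf("`%s` must be positive.", nm), call. = FALSE)
  }
  if (any(params$gamma_sigma <= 0)) {
    stop("`gamma_sigma` must be positive.", call. = FALSE)
  }
  if (params$tau_mu <= 0 || params$tau_sigma <= 0) {
    stop("`tau_mu` and `tau_sigma` must be positive.", call. = FALSE)
  }
  if (!identical(names(params$u_mu), names(params$u_sigma))) {
    stop("`u_mu` and `u_sigma` must be named for the same participants.",
         call. = FALSE)
  }
  sd_cells <- outer(params$gamma_sigma, params$u_sigma, `+`)
  if (any(sd_cells <= 0)) {
    bad <- which(sd_cells <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "Nonpositive cell SD: gamma_sigma[%s] + u_sigma[%s] <= 0.",
      names(params$gamma_sigma)[bad[1]], names(params$u_sigma)[bad[2]]
    ), call. = FALSE)
  }
  invisible(params)
}

trial_moments <- function(params, trials) {
  cond <- as.character(trials$condition)
  dur <- as.character(trials$target_duration_ms)
  pid <- trials$participant_id
  missing <- unique(pid[!pid %in% names(params$u_mu)])
  if (length(missing) > 0L) {
    stop("No random effects for participant(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  list(
    mu = unname(params$beta_mu[cond] * (params$gamma_mu[dur] + params$u_mu[pid])),
    sd = unname(params$beta_sigma[cond] * (params$gamma_sigma[dur] + params$u_sigma[pid]))
  )
}

#' Draw reproduced durations from the generative model
#'
#' Draws each trial's reproduced duration from the normal distribution
#' implied by `params` for its condition x duration x participant cell, and
#' redraws any value below 1 ms so reproductions are strictly positive. At
#' realistic parameters the truncation mass is negligible, so the analysis
#' likelihood remains a plain normal.
#'
#' @param params A [generative_params()] object.
#' @param trials Trial tibble (skeleton with or without timing columns).
#' @return `trials` with a `reproduced_ms` column appended.
#' @export
sample_reproduced <- function(params, trials) {
  validate_params(params)
  m <- trial_moments(params, trials)
  if (any(m$sd <= 0)) {
    i <- which(m$sd <= 0)[1]
    stop(sprintf(
      "Nonpositive SD in cell (%s, %s, %s ms).",
      trials$participant_id[i], as.character(trials$condition)[i],
      trials$target_duration_ms[i]
    ), call. = FALSE)
  }
  x <- stats::rnorm(nrow(trials), m$mu, m$sd)
  while (any(bad <- x < 1)) {
    x[bad] <- stats::rnorm(sum(bad), m$mu[bad], m$sd[bad])
  }
  trials$reproduced_ms <- x
  trials
}

#' Simulate maximal gaze deviations
#'
#' A two-component uniform mixture: with probability `gaze_break_prob` the
#' trial's maximal deviation from fixation is drawn uniformly on (2, 6]
#' degrees (a fixation break under the 2 degree criterion), otherwise
#' uniformly on [0, 2) degrees.
#'
#' @param cfg A [design_config()] object (supplies `gaze_break_prob`).
#' @param n Number of trials.
#' @return Numeric vector of deviations in degrees.
#' @export
simulate_gaze <- function(cfg, n) {
  stopifnot(inherits(cfg, "flick_design_config"))
  broke <- stats::runif(n) < cfg$gaze_break_prob
  ifelse(broke, stats::runif(n, 2, 6), stats::runif(n, 0, 2))
}

#' Simulate a complete experiment
#'
#' Runs the full generator: trial skeleton, distractor timing, gaze
#' deviations and reproduced durations, flagging trials whose gaze deviation
#' exceeds 2 degrees. With a seeded configuration the output is reproducible
#' byte for byte.
#'
#' @param cfg A [design_config()] object.
#' @param params Simulation truth ([generative_params()]); if `NULL`,
#'   defaults are used with random effects drawn after seeding, so the truth
#'   is reproducible too.
#' @return A tibble of trials with attributes `truth` (the `flick_params`
#'   used) and `config`.
#' @examples
#' sim <- simulate_experiment(design_config(n_participants = 2, n_sessions = 1,
#'                                          reps_per_cell = 2, seed = 7))
#' dplyr::count(sim, condition)
#' @export
simulate_experiment <- function(cfg, params = NULL) {
  stopifnot(inherits(cfg, "flick_design_config"))
  trials <- build_design(cfg) # seeds the generator if cfg$seed is set
  if (is.null(params)) {
    params <- generative_params(
      participants = participant_ids(cfg$n_participants)
    )
  }
  validate_params(params)
  trials <- assign_distractor_timing(trials, cfg)
  trials$gaze_max_dev_deg <- simulate_gaze(cfg, nrow(trials))
  trials <- sample_reproduced(params, trials)
  trials$excluded <- trials$gaze_max_dev_deg > 2
  attr(trials, "truth") <- params
  attr(trials, "config") <- cfg
  trials
}

#' Read and write trial tables and parameter sidecars
#'
#' Trials travel as tidy CSV (one row per trial, header mandatory, 1-based
#' session and trial indices, milliseconds and degrees as units); parameters
#' travel as flat JSON keyed `beta_mu.FS` etc.
#'
#' @param trials Trial tibble.
#' @param path File path.
#' @return `write_*` return `path` invisibly; `read_trials` a tibble;
#'   `read_params` a `flick_params`.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(as.data.frame(trials), path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("condition" %in% names(trials)) {
    lev <- c("SS", "FS", "SFi", "SFc")
    trials$condition <- factor(trials$condition,
                               levels = union(lev, unique(trials$condition)))
  }
  trials
}

#' @rdname write_trials
#' @param params A `flick_params` object.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  flat <- params_to_vec(params, free_only = FALSE)
  jsonlite::write_json(as.list(flat), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_params <- function(path) {
  flat <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  vec_to_params(flat)
}
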