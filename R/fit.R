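#' Fit the hierarchical location-scale model by MCMC
#'
#' Fits the duration-reproduction model to a (preprocessed) trial table with
#' block-wise adaptive random-walk Metropolis: three independent runs of
#' 2000 iterations by default, discarding the first half of each as warmup
#' and pooling the latter 1000 draws per run into 3000 posterior draws.
#' Positive parameters (condition multipliers, duration SD effects, the
#' `tau`s) are proposed on the log scale; proposal scales adapt during
#' warmup and are frozen thereafter. Initialization is moment-matched:
#' duration effects at the per-duration sample means and SDs, multipliers at
#' 1, random effects at 0.
#'
#' @param trials Trial tibble with `reproduced_ms`, `condition`,
#'   `target_duration_ms`, `participant_id` (typically the kept trials from
#'   [apply_gaze_exclusion()] after [merge_target_sides()]).
#' @param n_chains Number of independent runs.
#' @param n_iter Iterations per run.
#' @param n_warmup Iterations discarded per run (must be `< n_iter`);
#'   adaptation also stops here.
#' @param seed Integer seed; chain seeds are derived from it, so the fit is
#'   fully reproducible.
#' @return A `flick_fit` object: pooled `draws`, per-parameter `summary`,
#'   `comparisons` ([condition_ratio_tests()]), `rhat`, the chains, and the
#'   sampler settings.
#' @examples
#' \donttest{
#' sim <- simulate_experiment(design_config(n_participants = 3, n_sessions = 1,
#'                                          reps_per_cell = 5, seed = 1))
#' fit <- fit_flicker_model(sim, n_chains = 2, n_iter = 400, seed = 1)
#' tidy(fit)
#' }
#' @export
fit_flicker_model <- function(trials, n_chains = 3, n_iter = 2000,
                              n_warmup = floor(n_iter / 2), seed = NULL) {
  if (n_chains < 1L) stop("`n_chains` must be >= 1.", call. = FALSE)
  if (n_warmup >= n_iter) {
    stop("`n_warmup` must be smaller than `n_iter`.", call. = FALSE)
  }
  mk <- make_log_posterior(trials)
  if (!is.null(seed)) set.seed(seed)
  chain_seeds <- sample.int(.Machine$integer.max, n_chains)
  chains <- lapply(chain_seeds, function(s) {
    run_chain(mk$log_post, mk$init, n_iter,
              blocks = mk$blocks, log_scale = mk$log_scale,
              scales = mk$init_scales, directions = mk$directions,
              adapt_until = n_warmup, seed = s)
  })
  draws <- pool_chains(chains, n_warmup)
  structure(
    list(
      draws = draws,
      summary = summarize_posterior(draws),
      comparisons = condition_ratio_tests(draws),
      rhat = if (n_chains >= 2) rhat(chains, n_warmup) else NULL,
      chains = chains,
      n_chains = n_chains, n_iter = n_iter, n_warmup = n_warmup,
      seed = seed, n_trials = nrow(trials)
    ),
    class = "flick_fit"
  )
}

#' @export
print.flick_fit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical location-scale fit: %d trials, %d chains x %d iterations (%d warmup), %d pooled draws\n",
    x$n_trials, x$n_chains, x$n_iter, x$n_warmup, nrow(x$draws)
  ))
  cat("\nDilation ratios vs SS (posterior median [95% CrI]):\n")
  b <- x$summary[startsWith(x$summary$term, "beta_mu."), ]
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  %-12s %5.3f [%5.3f, %5.3f]\n",
                sub("beta_mu\\.", "", b$term[i]),
                b$median[i], b$cri_low[i], b$cri_high[i]))
  }
  cat("\nOne-sided comparisons (Bonferroni over 6):\n")
  print(as.data.frame(x$comparisons), row.names = FALSE)
  invisible(x)
}

#' Tidy a fitted model
#'
#' @param x A `flick_fit`.
#' @param parameters `"all"` or a prefix filter such as `"beta_mu"`.
#' @param ... Unused.
#' @return The per-parameter summary tibble, with an `rhat` column when
#'   several chains were run.
#' @method tidy flick_fit
#' @export
tidy.flick_fit <- function(x, parameters = "all", ...) {
  out <- x$summary
  if (!is.null(x$rhat)) out$rhat <- unname(x$rhat[out$term])
  if (!identical(parameters, "all")) {
    out <- out[startsWith(out$term, parameters), ]
  }
  out
}

#' One-row fit overview
#'
#' @param x A `flick_fit`.
#' @param ... Unused.
#' @return Tibble with draw counts, trial count and the largest R-hat.
#' @method glance flick_fit
#' @export
glance.flick_fit <- function(x, ...) {
  tibble::tibble(
    n_trials = x$n_trials,
    n_chains = x$n_chains,
    n_iter = x$n_iter,
    n_warmup = x$n_warmup,
    n_draws = nrow(x$draws),
    max_rhat = if (is.null(x$rhat)) NA_real_ else max(x$rhat, na.rm = TRUE)
  )
}

#' Plot estimated dilation ratios
#'
#' Posterior medians and 95% credible intervals of the condition mean
#' multipliers (dilation ratios relative to the stable-stable baseline),
#' with the no-dilation line at 1.
#'
#' @param object A `flick_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flick_fit
#' @export
autoplot.flick_fit <- function(object, ...) {
  b <- object$summary[startsWith(object$summary$term, "beta_mu."), ]
  b$condition <- factor(sub("beta_mu\\.", "", b$term),
                        levels = c("FS", "SFi", "SFc"))
  ggplot2::ggplot(b, ggplot2::aes(x = .data$condition, y = .data$median)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$cri_low,
                                          ymax = .data$cri_high)) +
    ggplot2::labs(x = NULL, y = "Reproduced-duration ratio vs SS",
                  title = "Condition dilation ratios") +
    ggplot2::theme_minimal()
}

#' Plot recovery of generating parameters
#'
#' Estimates with 95% credible intervals against the generating values.
#'
#' @param object A `flick_recovery` from [recovery_report()].
#' @param parameters Prefix filter, default the dilation ratios.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flick_recovery
#' @export
autoplot.flick_recovery <- function(object, parameters = "beta_mu", ...) {
  d <- object[startsWith(object$term, parameters), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$truth, y = .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$cri_low,
                                          ymax = .data$cri_high)) +
    ggplot2::labs(x = "Generating value", y = "Posterior median [95% CrI]",
                  title = "Parameter recovery") +
    ggplot2::theme_minimal()
}

#' Plot mean reproduced durations
#'
#' Mean reproduced duration per condition and target duration — the
#' descriptive view of the dilation effect in a trial table.
#'
#' @param trials Trial tibble with `reproduced_ms`.
#' @return A ggplot object.
#' @export
plot_reproduction <- function(trials) {
  d <- trials |>
    dplyr::group_by(.data$condition, .data$target_duration_ms) |>
    dplyr::summarise(mean_reproduced = mean(.data$reproduced_ms),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$target_duration_ms,
                                  y = .data$mean_reproduced,
                                  colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "Target duration (ms)", y = "Mean reproduced (ms)",
                  colour = "Condition") +
    ggplot2::theme_minimal()
}

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
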