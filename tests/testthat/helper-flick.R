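# Shared fixtures: small configurations, fixed-effect-free truths, and a
# lazily computed replicate study reused by the recovery and result-pattern
# acceptance checks.

tiny_cfg <- function(...) {
  design_config(experiment = 1, n_participants = 2, n_sessions = 1,
                reps_per_cell = 2, gaze_break_prob = 0, seed = 42, ...)
}

# parameters with no condition effects and no individual differences
flat_params <- function(participants, gamma_sigma = c(`450` = 90, `650` = 130,
                                                      `850` = 170)) {
  generative_params(
    participants = participants,
    beta_mu = c(SS = 1, FS = 1, SFi = 1, SFc = 1),
    beta_sigma = c(SS = 1, FS = 1, SFi = 1, SFc = 1),
    gamma_sigma = gamma_sigma,
    u_mu = stats::setNames(rep(0, length(participants)), participants),
    u_sigma = stats::setNames(rep(0, length(participants)), participants)
  )
}

simulate_and_fit <- function(cfg, truth = NULL, fit_seed, ...) {
  sim <- simulate_experiment(cfg, truth)
  kept <- merge_target_sides(apply_gaze_exclusion(sim)$trials)
  fit <- fit_flicker_model(kept, seed = fit_seed, ...)
  list(truth = attr(sim, "truth"), fit = fit)
}

# 20 replicate simulation + fit runs at the emulated study's scale
# (10 participants, 4 sessions x 15 reps = 60 trials per condition per
# duration), with the default dilation ratios 1.20 / 1.10 / 1.05.
recovery_replicates <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- purrr::map(1:20, function(i) {
        cfg <- design_config(experiment = 1, n_participants = 10,
                             seed = 20000 + i)
        run <- simulate_and_fit(cfg, fit_seed = 30000 + i)
        rec <- recovery_report(run$truth, run$fit$summary)
        list(
          recovery = rec,
          comparisons = run$fit$comparisons,
          coverage_beta_mu = attr(rec, "coverage_beta_mu")
        )
      })
    }
    cache
  }
})

# 20 replicates with the ipsi/contra distractor ratios equal (null
# contrast), used to check that the SFi-vs-SFc one-sided p is calibrated.
null_contrast_replicates <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- purrr::map_dbl(1:20, function(i) {
        cfg <- design_config(experiment = 2, n_participants = 10,
                             seed = 40000 + i)
        truth_template <- list(
          beta_mu = c(SS = 1, FS = 1.20, SFi = 1.10, SFc = 1.10),
          beta_sigma = c(SS = 1, FS = 1.20, SFi = 1.10, SFc = 1.10)
        )
        set.seed(50000 + i)
        truth <- generative_params(
          participants = sprintf("P%02d", 1:cfg$n_participants),
          beta_mu = truth_template$beta_mu,
          beta_sigma = truth_template$beta_sigma
        )
        run <- simulate_and_fit(cfg, truth, fit_seed = 60000 + i)
        run$fit$comparisons$raw_p[run$fit$comparisons$label == "SFi_gt_SFc"]
      })
    }
    cache
  }
})
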