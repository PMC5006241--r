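unit_params <- function(pids = "P01", gsd = 100) {
  generative_params(
    participants = pids,
    beta_mu = c(SS = 1, FS = 1, SFi = 1, SFc = 1),
    beta_sigma = c(SS = 1, FS = 1, SFi = 1, SFc = 1),
    gamma_sigma = stats::setNames(rep(gsd, 3), c(450, 650, 850)),
    u_mu = stats::setNames(rep(0, length(pids)), pids),
    u_sigma = stats::setNames(rep(0, length(pids)), pids)
  )
}

one_trial <- function(x, condition = "SS", duration = 650, pid = "P01") {
  tibble::tibble(
    participant_id = pid,
    condition = factor(condition, levels = c("SS", "FS", "SFi", "SFc")),
    target_duration_ms = duration,
    reproduced_ms = x
  )
}

test_that("the log-likelihood at a cell mode is the normal density constant", {
  p <- unit_params()
  expect_equal(log_likelihood(p, one_trial(650)), -log(100 * sqrt(2 * pi)))
})

test_that("the log-likelihood is additive and order-invariant", {
  p <- unit_params()
  t1 <- one_trial(600)
  t2 <- one_trial(710, condition = "FS", duration = 850)
  both <- dplyr::bind_rows(t1, t2)
  expect_equal(log_likelihood(p, both),
               log_likelihood(p, t1) + log_likelihood(p, t2))
  expect_equal(log_likelihood(p, both[2:1, ]), log_likelihood(p, both))
})

test_that("the baseline normalization and cell-SD positivity are enforced", {
  p <- unit_params()
  p$beta_mu["SS"] <- 1.01
  expect_error(log_likelihood(p, one_trial(650)), "exactly 1")

  q <- unit_params()
  q$u_sigma["P01"] <- -150
  expect_error(log_likelihood(q, one_trial(650)), "Nonpositive")
})

test_that("the log-prior matches the longhand sum of its component densities", {
  p <- generative_params(
    participants = c("P01", "P02"),
    gamma_sigma = c(`450` = 100, `650` = 100, `850` = 100),
    u_mu = c(P01 = 0, P02 = 0), u_sigma = c(P01 = 0, P02 = 0),
    tau_mu = 60, tau_sigma = 20
  )
  hand <- sum(dnorm(c(1.2, 1.1, 1.05, 1.2, 1.1, 1.05), 1, 0.5, log = TRUE)) -
    6 * pnorm(0, 1, 0.5, lower.tail = FALSE, log.p = TRUE) +
    sum(dnorm(c(450, 650, 850), c(450, 650, 850), 300, log = TRUE)) +
    sum(dnorm(rep(100, 3), 0, 300, log = TRUE) + log(2)) +
    sum(dnorm(rep(0, 2), 0, 60, log = TRUE)) +
    sum(dnorm(rep(0, 2), 0, 20, log = TRUE)) +
    sum(dcauchy(c(60, 20), 0, 100, log = TRUE) + log(2))
  expect_equal(log_prior(p), hand)
})

test_that("the log-prior encodes support violations as -Inf", {
  p <- unit_params()
  p$beta_mu["FS"] <- -0.1
  expect_identical(log_prior(p), -Inf)
  q <- unit_params()
  q$tau_mu <- -1
  expect_identical(log_prior(q), -Inf)
})

test_that("doubling the participants adds exactly the extra random-effect terms", {
  p1 <- unit_params("P01")
  p2 <- unit_params(c("P01", "P02"))
  extra <- dnorm(0, 0, p1$tau_mu, log = TRUE) + dnorm(0, 0, p1$tau_sigma, log = TRUE)
  expect_equal(log_prior(p2), log_prior(p1) + extra)
})

test_that("the log-posterior is the prior-likelihood sum and propagates -Inf", {
  p <- unit_params()
  trials <- one_trial(640)
  expect_equal(log_posterior(p, trials),
               log_prior(p) + log_likelihood(p, trials))
  bad <- unit_params()
  bad$tau_sigma <- -5
  expect_identical(log_posterior(bad, trials), -Inf)
  # a too-negative u_sigma is a support violation, not an error, here
  bad2 <- unit_params()
  bad2$u_sigma["P01"] <- -150
  expect_identical(log_posterior(bad2, trials), -Inf)
})

test_that("rescaling data and location/scale effects shifts the log-likelihood by -n log k", {
  set.seed(20)
  p <- generative_params(participants = c("P01", "P02"))
  trials <- simulate_experiment(design_config(n_participants = 2,
                                              n_sessions = 1,
                                              reps_per_cell = 2, seed = 21),
                                p)
  k <- 2.5
  p2 <- p
  p2$gamma_mu <- p$gamma_mu * k
  p2$u_mu <- p$u_mu * k
  p2$gamma_sigma <- p$gamma_sigma * k
  p2$u_sigma <- p$u_sigma * k
  t2 <- trials
  t2$reproduced_ms <- trials$reproduced_ms * k
  n <- nrow(trials)
  expect_equal(log_likelihood(p2, t2), log_likelihood(p, trials) - n * log(k))
})

test_that("the flat-vector representation round-trips", {
  set.seed(22)
  p <- generative_params(participants = sprintf("P%02d", 1:3))
  v <- params_to_vec(p, free_only = FALSE)
  p2 <- vec_to_params(v)
  expect_equal(params_to_vec(p2, free_only = FALSE), v)
  expect_equal(p2$beta_mu[["SS"]], 1)
})

test_that("the sufficient-statistic posterior equals the trial-wise computation", {
  set.seed(23)
  truth <- generative_params(participants = sprintf("P%02d", 1:3))
  trials <- simulate_experiment(design_config(n_participants = 3,
                                              n_sessions = 1,
                                              reps_per_cell = 3, seed = 24),
                                truth)
  mk <- flickertime:::make_log_posterior(trials)
  for (i in 1:5) {
    theta <- mk$init
    theta[mk$log_scale] <- theta[mk$log_scale] *
      exp(rnorm(sum(mk$log_scale), 0, 0.05))
    theta[!mk$log_scale] <- theta[!mk$log_scale] +
      rnorm(sum(!mk$log_scale), 0, 10)
    params <- vec_to_params(theta)
    expect_equal(mk$log_post(theta), log_posterior(params, trials),
                 tolerance = 1e-8)
  }
})
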