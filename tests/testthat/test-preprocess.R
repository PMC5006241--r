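gaze_trials <- function(dev, pid = "P01") {
  tibble::tibble(
    participant_id = rep(pid, length.out = length(dev)),
    condition = factor(rep("SS", length(dev)), levels = c("SS", "FS", "SFi", "SFc")),
    gaze_max_dev_deg = dev
  )
}

test_that("gaze exclusion is strict at the 2-degree boundary", {
  res <- apply_gaze_exclusion(gaze_trials(c(0.5, 2.0, 2.5)))
  expect_equal(res$trials$gaze_max_dev_deg, c(0.5, 2.0)) # exactly 2 is kept
  expect_equal(res$report$n_excluded, 1L)
  expect_equal(res$report$n_total, 3L)
})

test_that("gaze exclusion handles empty input and missing columns", {
  res <- apply_gaze_exclusion(gaze_trials(numeric(0)))
  expect_equal(nrow(res$trials), 0)
  expect_equal(nrow(res$report), 0)
  expect_error(apply_gaze_exclusion(tibble::tibble(x = 1)), "gaze_max_dev_deg")
})

test_that("side merging collapses 8 raw cells to the 4 analysis conditions", {
  raw <- tibble::tibble(
    condition = c(paste0(c("SS", "FS", "SFi", "SFc"), "_L"),
                  paste0(c("SS", "FS", "SFi", "SFc"), "_R"))
  )
  merged <- merge_target_sides(raw)
  expect_equal(nrow(merged), 8)
  expect_equal(dplyr::n_distinct(merged$condition), 4)
  expect_equal(levels(merged$condition), c("SS", "FS", "SFi", "SFc"))

  # already-merged labels pass through unchanged
  plain <- tibble::tibble(condition = c("SFi", "SFi", "SS"))
  expect_equal(as.character(merge_target_sides(plain)$condition),
               plain$condition)
  expect_error(merge_target_sides(tibble::tibble(condition = "XX")),
               "Unrecognized")
})

test_that("exclusion and merging commute", {
  sim <- simulate_experiment(design_config(n_participants = 2, n_sessions = 1,
                                           reps_per_cell = 4,
                                           gaze_break_prob = 0.3, seed = 10))
  a <- merge_target_sides(apply_gaze_exclusion(sim)$trials)
  b <- apply_gaze_exclusion(merge_target_sides(sim))$trials
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("perfect linear coupling gives r = 1 with a vanishing p", {
  t <- tibble::tibble(
    participant_id = "P01",
    target_duration_ms = 650,
    distractor_onset_ms = -seq(1, 10),
    distractor_offset_ms = seq(2, 20, by = 2)
  )
  t$reproduced_ms <- t$target_duration_ms - t$distractor_onset_ms +
    t$distractor_offset_ms
  ct <- distractor_correlations(t)
  expect_equal(ct$pearson_r, 1)
  expect_lt(ct$p_value, 1e-6)
  expect_true(ct$defined)
})

test_that("degenerate correlation cells are flagged undefined, not errors", {
  t <- tibble::tibble(
    participant_id = "P01", target_duration_ms = 650,
    distractor_onset_ms = rnorm(5), distractor_offset_ms = rnorm(5),
    reproduced_ms = rep(700, 5) # zero variance in the response
  )
  ct <- distractor_correlations(t)
  expect_false(ct$defined)
  expect_true(is.na(ct$pearson_r))

  t2 <- t[1:2, ]
  t2$reproduced_ms <- c(1, 2) # n < 3
  expect_false(distractor_correlations(t2)$defined)
})

test_that("the correlation matches the longhand covariance formula on a 5-point fixture", {
  x <- c(600, 640, 655, 700, 720) # distractor durations
  y <- c(610, 700, 650, 780, 690) # reproduced durations
  t <- tibble::tibble(
    participant_id = "P01", target_duration_ms = 650,
    distractor_onset_ms = 650 - x, # offset 0 => duration = 650 - onset
    distractor_offset_ms = 0,
    reproduced_ms = y
  )
  ct <- distractor_correlations(t)
  # longhand: covariance over product of standard deviations
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ct$pearson_r, r_hand, tolerance = 1e-12)
  # two-sided p from the t transform with n - 2 df
  tstat <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(ct$p_value, 2 * pt(abs(tstat), df = 3, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("the correlation table has one row per participant x duration", {
  cfg <- design_config(experiment = 2, n_participants = 3, n_sessions = 1,
                       reps_per_cell = 3, seed = 11)
  sim <- simulate_experiment(cfg)
  ct <- distractor_correlations(sim)
  expect_equal(nrow(ct), 3 * 3)
  expect_true(all(ct$defined))
  expect_true(all(abs(ct$pearson_r) <= 1))
})

test_that("with no jitter-response coupling about 5% of correlation p-values fall below 0.05", {
  pvals <- purrr::map(1:30, function(i) {
    cfg <- design_config(experiment = 2, n_participants = 4, n_sessions = 1,
                         reps_per_cell = 5, seed = 700 + i)
    truth <- flat_params(sprintf("P%02d", 1:4))
    sim <- simulate_experiment(cfg, truth)
    distractor_correlations(sim)$p_value
  })
  pvals <- unlist(pvals)
  frac <- mean(pvals < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / length(pvals)))
})
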