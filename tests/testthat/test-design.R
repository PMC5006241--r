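test_that("each session contains every condition x duration cell exactly reps_per_cell times", {
  cfg <- design_config(experiment = 1, n_participants = 2, n_sessions = 2,
                       reps_per_cell = 3, seed = 1)
  d <- build_design(cfg)
  counts <- dplyr::count(d, participant_id, session, condition,
                         target_duration_ms)
  expect_equal(nrow(counts), 2 * 2 * 4 * 3)
  expect_true(all(counts$n == 3))
  expect_true(all(counts$n >= 0))

  expect_equal(nrow(build_design(design_config(n_participants = 1,
                                               reps_per_cell = 0, seed = 1))), 0)
})

test_that("target side is constant within session and counterbalanced across participants", {
  cfg <- design_config(experiment = 1, n_participants = 4, n_sessions = 4,
                       side_sequence = "LRRL", seed = 3)
  d <- build_design(cfg)
  side_by_session <- d |>
    dplyr::distinct(participant_id, session, target_side) |>
    dplyr::arrange(participant_id, session)
  # one side per participant x session
  expect_equal(nrow(side_by_session), 4 * 4)
  seqs <- side_by_session |>
    dplyr::group_by(participant_id) |>
    dplyr::summarise(s = paste(target_side, collapse = ""), .groups = "drop")
  expect_equal(seqs$s, c("LRRL", "RLLR", "LRRL", "RLLR"))
})

test_that("distractor laterality respects the condition definitions", {
  d <- build_design(design_config(n_participants = 2, n_sessions = 4, seed = 5))
  sfi <- d[d$condition == "SFi", ]
  sfc <- d[d$condition == "SFc", ]
  expect_true(all(sfi$distractor_side == sfi$target_side))
  expect_true(all(sfc$distractor_side != sfc$target_side))
})

test_that("stable-distractor sub-cells balance ipsi and contra over an even session count", {
  d <- build_design(design_config(n_participants = 1, n_sessions = 4,
                                  reps_per_cell = 15, seed = 7))
  bal <- attr(d, "side_balance") |>
    tidyr::pivot_wider(names_from = laterality, values_from = n)
  expect_true(all(bal$ipsi == bal$contra))
  expect_true(all(bal$ipsi == 30))
})

test_that("a seeded design regenerates identically", {
  cfg <- design_config(n_participants = 2, n_sessions = 2, seed = 99)
  expect_identical(build_design(cfg), build_design(cfg))
})

test_that("experiment-1 distractor timing falls in the configured lead and tail ranges", {
  cfg <- design_config(experiment = 1, n_participants = 1, n_sessions = 1,
                       seed = 2)
  d <- assign_distractor_timing(build_design(cfg), cfg)
  expect_true(all(d$distractor_onset_ms >= -2500 & d$distractor_onset_ms <= -2000))
  expect_true(all(d$distractor_offset_ms >= 1000 & d$distractor_offset_ms <= 1500))
})

test_that("experiment-2 asynchronies stay within the jitter bound and are centred", {
  cfg <- design_config(experiment = 2, n_participants = 1, n_sessions = 1,
                       seed = 4)
  d <- build_design(cfg)
  d450 <- d[rep(which(d$target_duration_ms == 450), length.out = 2000), ]
  t450 <- assign_distractor_timing(d450, cfg)
  expect_true(all(abs(t450$distractor_onset_ms) <= 135))
  expect_true(all(abs(t450$distractor_offset_ms) <= 135))

  # degenerate jitter
  cfg0 <- design_config(experiment = 2, n_participants = 1, n_sessions = 1,
                        jitter_frac = 0, seed = 4)
  t0 <- assign_distractor_timing(build_design(cfg0), cfg0)
  expect_true(all(t0$distractor_onset_ms == 0))
  expect_true(all(t0$distractor_offset_ms == 0))

  # Monte-Carlo mean of the uniform onset asynchrony at 650 ms:
  # uniform(-195, 195) has mean 0 and sd 390 / sqrt(12)
  d650 <- d[rep(which(d$target_duration_ms == 650), length.out = 1e4), ]
  set.seed(8)
  t650 <- assign_distractor_timing(d650, cfg)
  se <- (390 / sqrt(12)) / sqrt(1e4)
  expect_lt(abs(mean(t650$distractor_onset_ms)), 3 * se)
})

test_that("stimulus geometry yields 8 degrees edge-to-edge for both layouts", {
  g <- stimulus_geometry()
  expect_equal(g$center_distance_deg, c(14, 14))
  expect_equal(g$edge_distance_deg, c(8, 8))
  g0 <- stimulus_geometry(radius_deg = 0)
  expect_equal(g0$edge_distance_deg, g0$center_distance_deg)
})

test_that("invalid configurations are rejected", {
  expect_error(design_config(jitter_frac = 1), "jitter_frac")
  expect_error(design_config(gaze_break_prob = 1.2), "gaze_break_prob")
  expect_error(design_config(target_durations_ms = c(450, -1)), "positive")
  expect_error(design_config(experiment = 3), "experiment")
  expect_error(design_config(reps_per_cell = -1), "reps_per_cell")
})
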