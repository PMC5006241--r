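#' Configure a duration-reproduction experiment design
#'
#' Builds the design configuration for a synthetic two-stimulus duration
#' reproduction experiment with four conditions (`SS`, `FS`, `SFi`, `SFc`:
#' Stable/Flickering target crossed with stable or flickering ipsi- or
#' contralateral distractor). Defaults follow the two study designs the
#' package emulates: four sessions, 15 repetitions per condition x target
#' duration cell per session (180 trials per session), target durations of
#' 450, 650 and 850 ms, and L-R-R-L / R-L-L-R target-side sequences
#' counterbalanced across participants.
#'
#' In experiment 1 the distractor brackets the target: it appears
#' `exp1_lead_range_ms` before target onset and disappears
#' `exp1_tail_range_ms` after target offset. In experiment 2 the distractor
#' duration approximately matches the target and its onset and offset
#' asynchronies are jittered uniformly within `jitter_frac` of the target
#' duration.
#'
#' @param experiment Experiment variant, `1` (long distractor) or `2`
#'   (jittered, duration-matched distractor).
#' @param n_participants Number of participants (default 11 for experiment 1,
#'   10 for experiment 2, matching the emulated studies).
#' @param n_sessions Number of sessions per participant.
#' @param reps_per_cell Repetitions of every condition x duration cell per
#'   session.
#' @param conditions Condition labels, in their canonical order.
#' @param target_durations_ms Target durations in milliseconds.
#' @param jitter_frac Experiment-2 onset/offset asynchrony bound as a
#'   fraction of the target duration (`0.30` = +/-30%).
#' @param exp1_lead_range_ms Experiment-1 range (ms) of distractor onset lead
#'   before target onset.
#' @param exp1_tail_range_ms Experiment-1 range (ms) of distractor tail after
#'   target offset.
#' @param side_sequence Target-side session sequence for the first
#'   participant; subsequent participants alternate between `"LRRL"` and
#'   `"RLLR"` so the sequence is counterbalanced.
#' @param gaze_break_prob Per-trial probability that the simulated maximal
#'   gaze deviation exceeds the 2 degree fixation criterion.
#' @param seed Integer seed for the generator, or `NULL` to use the ambient
#'   RNG state.
#'
#' @return An object of class `flick_design_config` (a named list).
#' @examples
#' cfg <- design_config(experiment = 1, n_participants = 2, seed = 1)
#' @export
design_config <- function(experiment = 1,
                          n_participants = if (experiment == 1) 11L else 10L,
                          n_sessions = 4L,
                          reps_per_cell = 15L,
                          conditions = c("SS", "FS", "SFi", "SFc"),
                          target_durations_ms = c(450, 650, 850),
                          jitter_frac = 0.30,
                          exp1_lead_range_ms = c(2000, 2500),
                          exp1_tail_range_ms = c(1000, 1500),
                          side_sequence = c("LRRL", "RLLR"),
                          gaze_break_prob = 0.05,
                          seed = NULL) {
  experiment <- as.integer(experiment)
  side_sequence <- match.arg(side_sequence)
  if (!experiment %in% c(1L, 2L)) {
    stop("`experiment` must be 1 or 2.", call. = FALSE)
  }
  if (n_participants < 1L) stop("`n_participants` must be >= 1.", call. = FALSE)
  if (n_sessions < 1L) stop("`n_sessions` must be >= 1.", call. = FALSE)
  if (reps_per_cell < 0L) stop("`reps_per_cell` must be >= 0.", call. = FALSE)
  if (jitter_frac < 0 || jitter_frac >= 1) {
    stop("`jitter_frac` must lie in [0, 1).", call. = FALSE)
  }
  if (gaze_break_prob < 0 || gaze_break_prob > 1) {
    stop("`gaze_break_prob` must lie in [0, 1].", call. = FALSE)
  }
  if (any(target_durations_ms <= 0)) {
    stop("`target_durations_ms` must all be positive.", call. = FALSE)
  }
  if (length(exp1_lead_range_ms) != 2L || diff(exp1_lead_range_ms) < 0 ||
      length(exp1_tail_range_ms) != 2L || diff(exp1_tail_range_ms) < 0) {
    stop("Experiment-1 timing ranges must be nondecreasing length-2 vectors.",
         call. = FALSE)
  }
  structure(
    list(
      experiment = experiment,
      n_participants = as.integer(n_participants),
      n_sessions = as.integer(n_sessions),
      reps_per_cell = as.integer(reps_per_cell),
      conditions = conditions,
      target_durations_ms = as.numeric(target_durations_ms),
      jitter_frac = jitter_frac,
      exp1_lead_range_ms = as.numeric(exp1_lead_range_ms),
      exp1_tail_range_ms = as.numeric(exp1_tail_range_ms),
      side_sequence = side_sequence,
      gaze_break_prob = gaze_break_prob,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "flick_design_config"
  )
}

other_sequence <- function(s) if (s == "LRRL") "RLLR" else "LRRL"

participant_ids <- function(n) sprintf("P%02d", seq_len(n))

#' Build the trial skeleton of an experiment
#'
#' Lays out every trial of the configured design, without responses or
#' distractor timing: one row per trial with participant, session,
#' within-session trial index, condition, target side, distractor side and
#' target duration. The target side is constant within a session and follows
#' the counterbalanced side sequence. `SFi` trials place the distractor on
#' the target's side, `SFc` on the opposite side; `SS` and `FS` trials split
#' their stable distractor between ipsi- and contralateral placements as
#' evenly as possible, with any odd remainder alternating across sessions so
#' that an even number of sessions is exactly balanced. The realized
#' sub-cell counts are recorded in the `side_balance` attribute. Trial order
#' within a session is shuffled with the seeded generator.
#'
#' @param cfg A [design_config()] object.
#' @return A tibble of trial skeletons with attribute `side_balance`.
#' @examples
#' nrow(build_design(design_config(n_participants = 1, n_sessions = 1, seed = 1)))
#' @export
build_design <- function(cfg) {
  stopifnot(inherits(cfg, "flick_design_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sides <- c(L = "L", R = "R")

  one_session <- function(pid, session, target_side) {
    cells <- tidyr::expand_grid(
      condition = cfg$conditions,
      target_duration_ms = cfg$target_durations_ms
    )
    rows <- purrr::pmap_dfr(cells, function(condition, target_duration_ms) {
      reps <- cfg$reps_per_cell
      if (reps == 0L) {
        return(tibble::tibble(
          condition = character(), target_duration_ms = numeric(),
          distractor_side = character()
        ))
      }
      dside <- switch(condition,
        SFi = rep(target_side, reps),
        SFc = rep(setdiff(sides, target_side), reps),
        {
          # stable distractor: balance ipsi/contra, remainder alternates by session
          n_ipsi <- if (session %% 2L == 1L) ceiling(reps / 2) else floor(reps / 2)
          lat <- c(rep("ipsi", n_ipsi), rep("contra", reps - n_ipsi))
          ifelse(lat == "ipsi", target_side, setdiff(sides, target_side))
        }
      )
      tibble::tibble(
        condition = rep(condition, reps),
        target_duration_ms = rep(target_duration_ms, reps),
        distractor_side = dside
      )
    })
    if (nrow(rows) > 0L) rows <- rows[sample.int(nrow(rows)), ]
    tibble::tibble(
      experiment = cfg$experiment,
      participant_id = pid,
      session = session,
      trial_index = seq_len(nrow(rows)),
      condition = factor(rows$condition, levels = cfg$conditions),
      target_side = target_side,
      distractor_side = rows$distractor_side,
      target_duration_ms = rows$target_duration_ms
    )
  }

  trials <- purrr::map_dfr(seq_len(cfg$n_participants), function(p) {
    seq_p <- if (p %% 2L == 1L) cfg$side_sequence else other_sequence(cfg$side_sequence)
    seq_sides <- strsplit(seq_p, "")[[1]]
    purrr::map_dfr(seq_len(cfg$n_sessions), function(s) {
      one_session(participant_ids(cfg$n_participants)[p], s,
                  seq_sides[((s - 1L) %% length(seq_sides)) + 1L])
    })
  })

  balance <- trials |>
    dplyr::filter(.data$condition %in% c("SS", "FS")) |>
    dplyr::count(.data$condition, .data$target_duration_ms,
                 laterality = ifelse(.data$distractor_side == .data$target_side,
                                     "ipsi", "contra"))
  attr(trials, "side_balance") <- balance
  trials
}

#' Assign distractor timing to trials
#'
#' Fills `distractor_onset_ms` and `distractor_offset_ms`, both signed
#' asynchronies relative to target onset and offset respectively. Experiment
#' 1 draws the onset lead uniformly from `exp1_lead_range_ms` (so the onset
#' asynchrony is negative) and the tail uniformly from `exp1_tail_range_ms`.
#' Experiment 2 draws both asynchronies independently and uniformly on
#' `+/- jitter_frac * target_duration_ms`. The experiment-2 distractor
#' duration is `target_duration_ms - onset + offset`.
#'
#' @param trials Trial tibble with `condition` and `target_duration_ms`.
#' @param cfg The [design_config()] used to build the trials.
#' @return `trials` with timing columns set.
#' @export
assign_distractor_timing <- function(trials, cfg) {
  stopifnot(inherits(cfg, "flick_design_config"))
  n <- nrow(trials)
  if (cfg$experiment == 1L) {
    trials$distractor_onset_ms <-
      -stats::runif(n, cfg$exp1_lead_range_ms[1], cfg$exp1_lead_range_ms[2])
    trials$distractor_offset_ms <-
      stats::runif(n, cfg$exp1_tail_range_ms[1], cfg$exp1_tail_range_ms[2])
  } else {
    bound <- cfg$jitter_frac * trials$target_duration_ms
    trials$distractor_onset_ms <- stats::runif(n, -bound, bound)
    trials$distractor_offset_ms <- stats::runif(n, -bound, bound)
  }
  trials
}

#' Target-distractor display geometry
#'
#' Computes the centre-to-centre and edge-to-edge distance between the target
#' disk (centre 7 degrees lateral and 7 degrees above fixation) and the
#' distractor disk. The ipsilateral distractor sits 14 degrees below the
#' target centre; the contralateral distractor sits 14 degrees toward the
#' opposite side, mirrored across the vertical meridian. Both disks have a
#' 3 degree radius by default, so the edge-to-edge distance is 8 degrees for
#' either layout.
#'
#' @param layout `"ipsi"`, `"contra"`, or both.
#' @param radius_deg Disk radius in degrees (applies to target and
#'   distractor).
#' @return A tibble with one row per layout: centre coordinates of both
#'   disks, `center_distance_deg`, and `edge_distance_deg`.
#' @examples
#' stimulus_geometry()
#' @export
stimulus_geometry <- function(layout = c("ipsi", "contra"), radius_deg = 3) {
  layout <- match.arg(layout, several.ok = TRUE)
  target <- c(x = 7, y = 7) # right-target case; left is a mirror image
  purrr::map_dfr(layout, function(l) {
    d <- if (l == "ipsi") c(x = 7, y = 7 - 14) else c(x = 7 - 14, y = 7)
    cd <- sqrt(sum((target - d)^2))
    tibble::tibble(
      layout = l,
      target_x_deg = target[["x"]], target_y_deg = target[["y"]],
      distractor_x_deg = d[["x"]], distractor_y_deg = d[["y"]],
      center_distance_deg = cd,
      edge_distance_deg = cd - 2 * radius_deg
    )
  })
}
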