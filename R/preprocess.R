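#' Exclude trials with broken fixation
#'
#' Drops trials whose maximal gaze deviation exceeds the threshold. The
#' criterion is strict: a deviation of exactly `threshold_deg` is kept,
#' because only eyes moved *more than* 2 degrees from fixation break the
#' criterion.
#'
#' @param trials Trial tibble with a `gaze_max_dev_deg` column.
#' @param threshold_deg Exclusion threshold in degrees.
#' @return A list with `trials` (the kept rows) and `report` (per-participant
#'   `n_total`, `n_excluded`, `prop_excluded`).
#' @examples
#' t <- tibble::tibble(participant_id = "P01", gaze_max_dev_deg = c(1, 2, 2.5))
#' apply_gaze_exclusion(t)$report
#' @export
apply_gaze_exclusion <- function(trials, threshold_deg = 2) {
  if (!"gaze_max_dev_deg" %in% names(trials)) {
    stop("`trials` must contain `gaze_max_dev_deg`.", call. = FALSE)
  }
  kept <- dplyr::filter(trials, .data$gaze_max_dev_deg <= threshold_deg)
  if (nrow(trials) > 0L) {
    report <- trials |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(
        n_total = dplyr::n(),
        n_excluded = sum(.data$gaze_max_dev_deg > threshold_deg),
        prop_excluded = .data$n_excluded / .data$n_total,
        .groups = "drop"
      )
  } else {
    report <- tibble::tibble(
      participant_id = character(), n_total = integer(),
      n_excluded = integer(), prop_excluded = numeric()
    )
  }
  list(trials = kept, report = report)
}

#' Collapse target sides into one analysis cell per condition
#'
#' Left- and right-target trials of the same condition are analysed
#' together; after merging, exactly the four condition levels `SS`, `FS`,
#' `SFi`, `SFc` remain. Condition labels carrying a side suffix (e.g.
#' `"SS_L"`, `"FS.R"`) are stripped to their base condition; row count and
#' order are unchanged.
#'
#' @param trials Trial tibble with a `condition` column.
#' @return `trials` with `condition` as a factor over the four merged
#'   levels.
#' @export
merge_target_sides <- function(trials) {
  lev <- c("SS", "FS", "SFi", "SFc")
  base <- sub("[._](L|R)$", "", as.character(trials$condition))
  unknown <- setdiff(unique(base), lev)
  if (length(unknown) > 0L) {
    stop("Unrecognized condition label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  trials$condition <- factor(base, levels = lev)
  trials
}

#' Distractor-duration correlation diagnostic
#'
#' For each participant and target duration, the Pearson correlation between
#' the realized distractor duration and the reproduced duration, with the
#' two-sided p-value from the t transform on n - 2 degrees of freedom. In
#' the jittered-distractor experiment this checks that participants
#' reproduced the target, not the distractor: strong correlations would
#' indicate distractor-based timing. The distractor duration is derived as
#' `target_duration_ms - distractor_onset_ms + distractor_offset_ms`. Cells
#' with fewer than 3 trials or zero variance in either variable are flagged
#' `defined = FALSE` rather than raising.
#'
#' @param trials Trial tibble with timing columns and `reproduced_ms`.
#' @return A tibble with one row per participant x duration:
#'   `participant_id`, `target_duration_ms`, `n_trials`, `pearson_r`,
#'   `p_value`, `defined`.
#' @export
distractor_correlations <- function(trials) {
  need <- c("distractor_onset_ms", "distractor_offset_ms", "reproduced_ms")
  missing <- setdiff(need, names(trials))
  if (length(missing) > 0L) {
    stop("`trials` must contain: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  trials |>
    dplyr::mutate(distractor_duration_ms = .data$target_duration_ms -
                    .data$distractor_onset_ms + .data$distractor_offset_ms) |>
    dplyr::group_by(.data$participant_id, .data$target_duration_ms) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      defined = .data$n_trials >= 3 &&
        stats::sd(.data$distractor_duration_ms) > 0 &&
        stats::sd(.data$reproduced_ms) > 0,
      pearson_r = if (.data$defined[1]) {
        stats::cor(.data$distractor_duration_ms, .data$reproduced_ms)
      } else {
        NA_real_
      },
      p_value = if (.data$defined[1]) {
        stats::cor.test(.data$distractor_duration_ms, .data$reproduced_ms,
                        method = "pearson")$p.value
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::select("participant_id", "target_duration_ms", "n_trials",
                  "pearson_r", "p_value", "defined")
}
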