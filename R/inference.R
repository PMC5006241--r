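draw_columns <- function(draws) {
  setdiff(names(draws), c("chain", "iteration"))
}

#' Percentile summaries of pooled posterior draws
#'
#' Per-parameter posterior median (50th percentile) and equal-tailed 95%
#' credible interval (2.5th and 97.5th percentiles), using the
#' linear-interpolation quantile rule (type 7), recorded in the
#' `quantile_rule` attribute.
#'
#' @param draws Pooled draws from [pool_chains()] (tibble with `chain`,
#'   `iteration` and one column per parameter).
#' @return Tibble with columns `term`, `median`, `cri_low`, `cri_high`.
#' @export
summarize_posterior <- function(draws) {
  pars <- draw_columns(draws)
  if (nrow(draws) == 0L || length(pars) == 0L) {
    stop("`draws` must contain at least one draw of at least one parameter.",
         call. = FALSE)
  }
  out <- purrr::map_dfr(pars, function(p) {
    q <- stats::quantile(draws[[p]], c(0.025, 0.5, 0.975), type = 7, names = FALSE)
    tibble::tibble(term = p, median = q[2], cri_low = q[1], cri_high = q[3])
  })
  attr(out, "quantile_rule") <- "empirical percentiles, linear interpolation (type 7)"
  out
}

ratio_comparisons <- tibble::tribble(
  ~label,        ~lhs,   ~rhs,
  "FS_gt_1",     "FS",   "1",
  "SFi_gt_1",    "SFi",  "1",
  "SFc_gt_1",    "SFc",  "1",
  "FS_gt_SFi",   "FS",   "SFi",
  "FS_gt_SFc",   "FS",   "SFc",
  "SFi_gt_SFc",  "SFi",  "SFc"
)

#' One-sided posterior comparisons of the dilation ratios
#'
#' The six directional comparisons among the condition mean multipliers:
#' each dilation ratio against 1 (`FS_gt_1`, `SFi_gt_1`, `SFc_gt_1`) and the
#' three pairwise orderings (`FS_gt_SFi`, `FS_gt_SFc`, `SFi_gt_SFc`). The
#' raw one-sided posterior p is the fraction of pooled draws violating the
#' stated direction; the corrected p is Bonferroni over the 6-comparison
#' family, `min(1, 6 * raw)`.
#'
#' @param draws Pooled draws containing `beta_mu.FS`, `beta_mu.SFi`,
#'   `beta_mu.SFc`.
#' @return Tibble with `label`, `raw_p`, `corrected_p`, `family_size`.
#' @export
condition_ratio_tests <- function(draws) {
  need <- paste0("beta_mu.", c("FS", "SFi", "SFc"))
  missing <- setdiff(need, names(draws))
  if (length(missing) > 0L) {
    stop("Missing condition-ratio draws: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fam <- nrow(ratio_comparisons)
  purrr::pmap_dfr(ratio_comparisons, function(label, lhs, rhs) {
    l <- draws[[paste0("beta_mu.", lhs)]]
    r <- if (rhs == "1") 1 else draws[[paste0("beta_mu.", rhs)]]
    raw <- mean(l <= r)
    tibble::tibble(
      label = label,
      raw_p = raw,
      corrected_p = min(1, fam * raw),
      family_size = fam
    )
  })
}

#' Compare estimates with simulation truth
#'
#' Matches each summarized parameter with its generating value, reporting
#' bias (`estimate - truth`) and whether the 95% credible interval covers
#' the truth. The aggregate attributes summarize the dilation ratios, the
#' quantities the analysis is about: `mean_abs_bias_beta_mu` and
#' `coverage_beta_mu` (fraction of free `beta_mu` parameters covered).
#'
#' @param truth A `flick_params` object used to generate the data.
#' @param summary A [summarize_posterior()] table.
#' @return A tibble (class `flick_recovery`) with columns `term`, `truth`,
#'   `estimate`, `bias`, `cri_low`, `cri_high`, `covered`, and attributes
#'   `mean_abs_bias_beta_mu` and `coverage_beta_mu`.
#' @export
recovery_report <- function(truth, summary) {
  tv <- params_to_vec(truth, free_only = FALSE)
  missing <- setdiff(summary$term, names(tv))
  if (length(missing) > 0L) {
    stop("No generating value for parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- summary |>
    dplyr::mutate(
      truth = unname(tv[.data$term]),
      estimate = .data$median,
      bias = .data$estimate - .data$truth,
      covered = .data$cri_low <= .data$truth & .data$truth <= .data$cri_high
    ) |>
    dplyr::select("term", "truth", "estimate", "bias",
                  "cri_low", "cri_high", "covered")
  beta <- out[startsWith(out$term, "beta_mu."), ]
  attr(out, "mean_abs_bias_beta_mu") <- mean(abs(beta$bias))
  attr(out, "coverage_beta_mu") <- mean(beta$covered)
  class(out) <- c("flick_recovery", class(out))
  out
}
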