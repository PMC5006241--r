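#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

# --- flat-vector <-> structured parameter conversion -------------------------

#' Flatten parameters to a named vector
#'
#' Serializes a `flick_params` object to a flat named numeric vector with
#' names like `beta_mu.FS`, `gamma_mu.650`, `u_mu.P03`, `tau_mu`. With
#' `free_only = TRUE` the fixed `SS` multipliers (identically 1) are
#' dropped; this is the parameterization the sampler works in.
#'
#' @param params A `flick_params` object.
#' @param free_only Drop the fixed baseline multipliers?
#' @return Named numeric vector.
#' @export
params_to_vec <- function(params, free_only = TRUE) {
  keep <- function(b) if (free_only) b[names(b) != "SS"] else b
  pre <- function(prefix, v) stats::setNames(unname(v), paste0(prefix, ".", names(v)))
  c(
    pre("beta_mu", keep(params$beta_mu)),
    pre("beta_sigma", keep(params$beta_sigma)),
    pre("gamma_mu", params$gamma_mu),
    pre("gamma_sigma", params$gamma_sigma),
    pre("u_mu", params$u_mu),
    pre("u_sigma", params$u_sigma),
    tau_mu = unname(params$tau_mu),
    tau_sigma = unname(params$tau_sigma)
  )
}

#' @rdname params_to_vec
#' @param flat Named numeric vector as produced by `params_to_vec()`.
#' @export
vec_to_params <- function(flat) {
  grab <- function(prefix) {
    nm <- names(flat)[startsWith(names(flat), paste0(prefix, "."))]
    stats::setNames(unname(flat[nm]), sub(paste0("^", prefix, "\\."), "", nm))
  }
  add_ss <- function(b) {
    if (!"SS" %in% names(b)) b <- c(SS = 1, b)
    b[c("SS", setdiff(names(b), "SS"))]
  }
  structure(
    list(
      beta_mu = add_ss(grab("beta_mu")),
      beta_sigma = add_ss(grab("beta_sigma")),
      gamma_mu = grab("gamma_mu"),
      gamma_sigma = grab("gamma_sigma"),
      u_mu = grab("u_mu"),
      u_sigma = grab("u_sigma"),
      tau_mu = unname(flat[["tau_mu"]]),
      tau_sigma = unname(flat[["tau_sigma"]])
    ),
    class = "flick_params"
  )
}

# --- likelihood, prior, posterior --------------------------------------------

#' Log-likelihood of the location-scale model
#'
#' Sum over trials of the normal log-density with cell mean
#' `beta_mu[c] * (gamma_mu[d] + u_mu[s])` and cell SD
#' `beta_sigma[c] * (gamma_sigma[d] + u_sigma[s])`. The `SS` multipliers must
#' equal 1 and every observed cell SD must be positive; violations raise an
#' error naming the offending cell.
#'
#' @param params A `flick_params` object.
#' @param trials Trial tibble with `reproduced_ms`, `condition`,
#'   `target_duration_ms` and `participant_id`.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(params, trials) {
  validate_params(params)
  if (!"reproduced_ms" %in% names(trials)) {
    stop("`trials` must contain `reproduced_ms`.", call. = FALSE)
  }
  m <- trial_moments(params, trials)
  if (any(m$sd <= 0)) {
    i <- which(m$sd <= 0)[1]
    stop(sprintf(
      "Nonpositive cell SD for (%s, %s, %s ms).",
      trials$participant_id[i], as.character(trials$condition)[i],
      trials$target_duration_ms[i]
    ), call. = FALSE)
  }
  sum(stats::dnorm(trials$reproduced_ms, m$mu, m$sd, log = TRUE))
}

#' Log-prior of the location-scale model
#'
#' Weakly-informative priors on the millisecond scale: each free condition
#' multiplier has a normal(1, 0.5^2) prior truncated to the positive line;
#' `gamma_mu[d]` is normal centred at the nominal duration `d` with SD 300
#' ms; `gamma_sigma[d]` is half-normal(0, 300^2); participant effects are
#' normal(0, `tau_mu`^2) and normal(0, `tau_sigma`^2); the `tau`s are
#' half-Cauchy(0, 100). Outside any support the value is `-Inf`.
#'
#' @param params A `flick_params` object.
#' @return Scalar log-prior density (possibly `-Inf`).
#' @export
log_prior <- function(params) {
  b_free <- c(params$beta_mu[names(params$beta_mu) != "SS"],
              params$beta_sigma[names(params$beta_sigma) != "SS"])
  if (any(b_free <= 0) || any(params$gamma_sigma <= 0) ||
      params$tau_mu <= 0 || params$tau_sigma <= 0) {
    return(-Inf)
  }
  durs <- as.numeric(names(params$gamma_mu))
  # log normalizing constant of N(1, 0.5^2) truncated to (0, Inf)
  trunc_const <- stats::pnorm(0, 1, 0.5, lower.tail = FALSE, log.p = TRUE)
  sum(stats::dnorm(b_free, 1, 0.5, log = TRUE)) - length(b_free) * trunc_const +
    sum(stats::dnorm(params$gamma_mu, durs, 300, log = TRUE)) +
    sum(stats::dnorm(params$gamma_sigma, 0, 300, log = TRUE) + log(2)) +
    sum(stats::dnorm(params$u_mu, 0, params$tau_mu, log = TRUE)) +
    sum(stats::dnorm(params$u_sigma, 0, params$tau_sigma, log = TRUE)) +
    sum(stats::dcauchy(c(params$tau_mu, params$tau_sigma), 0, 100, log = TRUE) + log(2))
}

#' Log-posterior of the location-scale model
#'
#' `log_likelihood + log_prior`. Support violations — including a
#' nonpositive cell SD arising from a too-negative `u_sigma` — are encoded
#' as `-Inf` rather than errors, so the value can be used directly as a
#' Metropolis target.
#'
#' @inheritParams log_likelihood
#' @return Scalar log-posterior (possibly `-Inf`).
#' @export
log_posterior <- function(params, trials) {
  lp <- log_prior(params)
  if (!is.finite(lp)) return(-Inf)
  m <- trial_moments(params, trials)
  if (any(m$sd <= 0)) return(-Inf)
  lp + sum(stats::dnorm(trials$reproduced_ms, m$mu, m$sd, log = TRUE))
}

# --- fast machinery for fitting ----------------------------------------------

# Per-cell sufficient statistics (n, sum, sum of squares) over
# participant x condition x duration cells. The normal likelihood depends on
# the data only through these, so a posterior evaluation costs O(#cells)
# instead of O(#trials).
flick_cell_stats <- function(trials) {
  conds <- c("SS", "FS", "SFi", "SFc")
  stopifnot(all(as.character(trials$condition) %in% conds))
  durs <- sort(unique(trials$target_duration_ms))
  pids <- sort(unique(trials$participant_id))
  cells <- trials |>
    dplyr::group_by(.data$participant_id, .data$condition, .data$target_duration_ms) |>
    dplyr::summarise(
      n = dplyr::n(),
      s1 = sum(.data$reproduced_ms),
      s2 = sum(.data$reproduced_ms^2),
      .groups = "drop"
    )
  list(
    conds = conds, durs = durs, pids = pids,
    ci = match(as.character(cells$condition), conds),
    di = match(cells$target_duration_ms, durs),
    si = match(cells$participant_id, pids),
    n = cells$n, s1 = cells$s1, s2 = cells$s2,
    n_trials = nrow(trials)
  )
}

# Builds everything the sampler needs for a dataset: a fast log-posterior on
# the flat free-parameter vector, a moment-matched initial value, the block
# structure, and the log-scale mask for positive parameters.
make_log_posterior <- function(trials) {
  cs <- flick_cell_stats(trials)
  nd <- length(cs$durs)
  ns <- length(cs$pids)
  free_conds <- cs$conds[-1]

  nm <- c(
    paste0("beta_mu.", free_conds), paste0("beta_sigma.", free_conds),
    paste0("gamma_mu.", cs$durs), paste0("gamma_sigma.", cs$durs),
    paste0("u_mu.", cs$pids), paste0("u_sigma.", cs$pids),
    "tau_mu", "tau_sigma"
  )
  i_bmu <- 1:3
  i_bsg <- 4:6
  i_gmu <- 6 + seq_len(nd)
  i_gsg <- 6 + nd + seq_len(nd)
  i_umu <- 6 + 2 * nd + seq_len(ns)
  i_usg <- 6 + 2 * nd + ns + seq_len(ns)
  i_tau <- 6 + 2 * nd + 2 * ns + 1:2
  positive <- c(i_bmu, i_bsg, i_gsg, i_tau)

  trunc_const <- stats::pnorm(0, 1, 0.5, lower.tail = FALSE, log.p = TRUE)
  durs <- cs$durs
  half_log2pi <- 0.5 * log(2 * pi)

  log_post <- function(theta) {
    if (any(theta[positive] <= 0)) return(-Inf)
    bmu <- c(1, theta[i_bmu])
    bsg <- c(1, theta[i_bsg])
    gmu <- theta[i_gmu]
    gsg <- theta[i_gsg]
    umu <- theta[i_umu]
    usg <- theta[i_usg]
    tau_mu <- theta[i_tau[1]]
    tau_sg <- theta[i_tau[2]]

    sdc <- bsg[cs$ci] * (gsg[cs$di] + usg[cs$si])
    if (any(sdc <= 0)) return(-Inf)
    muc <- bmu[cs$ci] * (gmu[cs$di] + umu[cs$si])
    ll <- sum(-cs$n * (log(sdc) + half_log2pi) -
                (cs$s2 - 2 * muc * cs$s1 + cs$n * muc^2) / (2 * sdc^2))

    b_free <- theta[c(i_bmu, i_bsg)]
    lp <- sum(stats::dnorm(b_free, 1, 0.5, log = TRUE)) - 6 * trunc_const +
      sum(stats::dnorm(gmu, durs, 300, log = TRUE)) +
      sum(stats::dnorm(gsg, 0, 300, log = TRUE) + log(2)) +
      sum(stats::dnorm(umu, 0, tau_mu, log = TRUE)) +
      sum(stats::dnorm(usg, 0, tau_sg, log = TRUE)) +
      sum(stats::dcauchy(c(tau_mu, tau_sg), 0, 100, log = TRUE) + log(2))
    ll + lp
  }

  # moment-matched start: duration means/SDs, multipliers at 1, u at 0
  by_dur <- trials |>
    dplyr::group_by(.data$target_duration_ms) |>
    dplyr::summarise(m = mean(.data$reproduced_ms),
                     s = stats::sd(.data$reproduced_ms), .groups = "drop") |>
    dplyr::arrange(.data$target_duration_ms)
  part_means <- trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(m = mean(.data$reproduced_ms), .groups = "drop")
  tau_mu0 <- max(10, stats::sd(part_means$m), na.rm = TRUE)
  init <- stats::setNames(c(
    rep(1, 6),
    by_dur$m,
    pmax(by_dur$s, 10),
    rep(0, ns), rep(0, ns),
    tau_mu0, 20
  ), nm)

  blocks <- list(
    beta_mu = i_bmu, beta_sigma = i_bsg,
    gamma_mu = i_gmu, gamma_sigma = i_gsg,
    u_mu = i_umu, u_sigma = i_usg,
    tau = i_tau
  )
  log_scale <- stats::setNames(rep(FALSE, length(nm)), nm)
  log_scale[positive] <- TRUE

  # joint translation moves along the additively confounded ridges
  # (gamma_mu + delta, u_mu - delta) and (gamma_sigma + delta, u_sigma - delta)
  dir_mu <- numeric(length(nm))
  dir_mu[i_gmu] <- 1
  dir_mu[i_umu] <- -1
  dir_sg <- numeric(length(nm))
  dir_sg[i_gsg] <- 1
  dir_sg[i_usg] <- -1

  list(
    log_post = log_post, init = init, blocks = blocks, log_scale = log_scale,
    par_names = nm, cell_stats = cs,
    directions = list(mu_ridge = dir_mu, sigma_ridge = dir_sg),
    init_scales = c(beta_mu = 0.01, beta_sigma = 0.02, gamma_mu = 5,
                    gamma_sigma = 0.05, u_mu = 8, u_sigma = 8, tau = 0.25,
                    mu_ridge = 20, sigma_ridge = 10)
  )
}
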