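#' Run one adaptive random-walk Metropolis chain
#'
#' Block-wise Gaussian random-walk Metropolis on an arbitrary log-density.
#' Each block is updated in turn with an isotropic Gaussian proposal whose
#' scale is adapted in batches during the first `adapt_until` iterations
#' toward `target_accept` acceptance (and frozen thereafter, keeping the
#' post-adaptation kernel valid). Parameters flagged in `log_scale` are
#' proposed multiplicatively on the log scale, with the Jacobian term
#' included in the acceptance ratio, so positivity is respected by
#' construction.
#'
#' @param log_post Function of the flat parameter vector returning the log
#'   target density (possibly `-Inf`).
#' @param init Named numeric starting vector; `log_post(init)` must be
#'   finite.
#' @param n_iter Number of iterations (every iteration is stored).
#' @param blocks List of integer index vectors partitioning the parameters;
#'   default a single block.
#' @param log_scale Logical vector marking parameters proposed on the log
#'   scale; default none.
#' @param scales Initial proposal scale per block (recycled over blocks then
#'   directions).
#' @param directions Optional list of length-p numeric vectors; each defines
#'   an additional one-dimensional translation move `theta + z * v` with
#'   `z ~ N(0, scale^2)`, adapted like a block. Useful for ridges created by
#'   additively confounded parameter pairs, which isotropic block moves
#'   traverse slowly.
#' @param adapt_until Final iteration of scale adaptation; default half the
#'   run.
#' @param target_accept Target acceptance rate during adaptation.
#' @param adapt_batch Iterations per adaptation batch.
#' @param seed Optional integer seed; a fixed seed makes the chain
#'   bitwise reproducible.
#' @return A `flick_chain`: list with `draws` (`n_iter` x p matrix),
#'   `log_post` trace, per-block acceptance counts and post-adaptation
#'   rates, final `scales`, `n_iter`, `adapt_until` and `seed`.
#' @examples
#' ch <- run_chain(function(x) dnorm(x, log = TRUE), c(x = 0), 500, seed = 1)
#' mean(ch$draws)
#' @export
run_chain <- function(log_post, init, n_iter,
                      blocks = NULL, log_scale = NULL, scales = 0.5,
                      directions = NULL,
                      adapt_until = floor(n_iter / 2), target_accept = 0.3,
                      adapt_batch = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- length(init)
  if (is.null(blocks)) blocks <- list(seq_len(p))
  if (is.null(log_scale)) log_scale <- rep(FALSE, p)
  n_blocks <- length(blocks)
  nb <- n_blocks + length(directions)
  scales <- rep_len(scales, nb)

  cur <- init
  lpc <- log_post(cur)
  if (!is.finite(lpc)) {
    stop("`log_post(init)` must be finite.", call. = FALSE)
  }

  draws <- matrix(NA_real_, n_iter, p, dimnames = list(NULL, names(init)))
  lp_trace <- numeric(n_iter)
  acc_total <- integer(nb)
  acc_post <- integer(nb) # acceptances after adaptation froze
  acc_batch <- integer(nb)
  batch_no <- 0L

  for (it in seq_len(n_iter)) {
    for (b in seq_len(nb)) {
      jac <- 0
      if (b <= n_blocks) {
        idx <- blocks[[b]]
        z <- stats::rnorm(length(idx), 0, scales[b])
        prop <- cur
        lsb <- log_scale[idx]
        if (any(lsb)) {
          i2 <- idx[lsb]
          prop[i2] <- cur[i2] * exp(z[lsb])
          jac <- sum(z[lsb]) # log |d prop / d cur| on the log-proposal coords
        }
        if (any(!lsb)) {
          i2 <- idx[!lsb]
          prop[i2] <- cur[i2] + z[!lsb]
        }
      } else {
        v <- directions[[b - n_blocks]]
        prop <- cur + stats::rnorm(1, 0, scales[b]) * v
      }
      lpp <- log_post(prop)
      if (is.finite(lpp) && log(stats::runif(1)) < (lpp - lpc + jac)) {
        cur <- prop
        lpc <- lpp
        acc_total[b] <- acc_total[b] + 1L
        acc_batch[b] <- acc_batch[b] + 1L
        if (it > adapt_until) acc_post[b] <- acc_post[b] + 1L
      }
    }
    if (it <= adapt_until && it %% adapt_batch == 0L) {
      batch_no <- batch_no + 1L
      gain <- min(0.5, 2 / sqrt(batch_no))
      rate <- acc_batch / adapt_batch
      scales <- scales * exp(gain * (rate - target_accept))
      scales <- pmin(pmax(scales, 1e-8), 1e4)
      acc_batch[] <- 0L
    }
    draws[it, ] <- cur
    lp_trace[it] <- lpc
  }

  n_post <- n_iter - adapt_until
  structure(
    list(
      draws = draws,
      log_post = lp_trace,
      accept = acc_total,
      accept_rate_post = if (n_post > 0) acc_post / n_post else rep(NA_real_, nb),
      scales = scales,
      blocks = blocks,
      directions = directions,
      n_iter = n_iter,
      adapt_until = adapt_until,
      seed = seed
    ),
    class = "flick_chain"
  )
}

chain_draws <- function(chain) {
  if (inherits(chain, "flick_chain")) chain$draws else as.matrix(chain)
}

#' Pool post-warmup draws from several chains
#'
#' Discards the first `n_warmup` iterations of every chain and concatenates
#' the remainder, retaining chain and iteration labels. The default scheme of
#' the package — three runs of 2000 iterations keeping the latter 1000 —
#' pools to exactly 3000 draws.
#'
#' @param chains List of `flick_chain` objects (or draw matrices).
#' @param n_warmup Iterations to discard from the start of each chain.
#' @return A tibble with columns `chain`, `iteration` (original index) and
#'   one column per parameter.
#' @export
pool_chains <- function(chains, n_warmup) {
  stopifnot(length(chains) >= 1L)
  mats <- lapply(chains, chain_draws)
  if (any(vapply(mats, nrow, 1L) <= n_warmup)) {
    stop("`n_warmup` must be smaller than every chain length.", call. = FALSE)
  }
  purrr::imap_dfr(mats, function(m, i) {
    keep <- (n_warmup + 1L):nrow(m)
    dplyr::bind_cols(
      tibble::tibble(chain = as.integer(i), iteration = keep),
      tibble::as_tibble(m[keep, , drop = FALSE])
    )
  })
}

#' Split-chain potential scale reduction factor
#'
#' Gelman-Rubin R-hat computed after splitting each chain's retained segment
#' in half, so within-chain trend shows up as between-chain variance.
#' Parameters whose within-chain variance is zero are returned as `NA`.
#'
#' @param chains List of at least two `flick_chain` objects (or draw
#'   matrices).
#' @param n_warmup Iterations to discard before splitting.
#' @return Named numeric vector of R-hat values, one per parameter.
#' @export
rhat <- function(chains, n_warmup = 0) {
  if (length(chains) < 2L) {
    stop("R-hat needs at least two chains.", call. = FALSE)
  }
  mats <- lapply(chains, chain_draws)
  if (any(vapply(mats, nrow, 1L) <= n_warmup)) {
    stop("`n_warmup` must be smaller than every chain length.", call. = FALSE)
  }
  halves <- list()
  for (m in mats) {
    kept <- m[(n_warmup + 1L):nrow(m), , drop = FALSE]
    n2 <- floor(nrow(kept) / 2)
    halves <- c(halves, list(kept[seq_len(n2), , drop = FALSE],
                             kept[(n2 + 1L):(2L * n2), , drop = FALSE]))
  }
  n <- nrow(halves[[1]])
  if (n < 2L) stop("Too few retained iterations to split.", call. = FALSE)
  p <- ncol(halves[[1]])
  out <- stats::setNames(rep(NA_real_, p), colnames(halves[[1]]))
  means <- vapply(halves, colMeans, numeric(p))
  vars <- vapply(halves, function(h) apply(h, 2, stats::var), numeric(p))
  if (p == 1L) {
    means <- matrix(means, nrow = 1)
    vars <- matrix(vars, nrow = 1)
  }
  W <- rowMeans(vars)
  B <- n * apply(means, 1, stats::var)
  ok <- W > 0
  var_plus <- ((n - 1) / n) * W[ok] + B[ok] / n
  out[ok] <- sqrt(var_plus / W[ok])
  out
}
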