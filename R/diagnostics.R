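#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) two-variance shrink factor: with m chains of length n,
#' within-chain variance W and between-chain variance B = n * var(chain
#' means), the PSRF is sqrt(((n - 1)/n * W + B/n) / W). Values below 1.1 are
#' the conventional convergence criterion.
#'
#' @param chains a [chain_set()] or list of equal-length numeric chains.
#' @return the shrink factor (a scalar).
#' @export
gelman_rubin <- function(chains) {
  ch <- .as_chain_list(chains)
  m <- length(ch)
  if (m < 2L) stop("gelman_rubin requires at least 2 chains")
  n <- length(ch[[1L]])
  if (n < 2L) stop("each chain must hold at least 2 draws")
  W <- mean(vapply(ch, stats::var, numeric(1)))
  B_over_n <- stats::var(vapply(ch, mean, numeric(1)))
  if (W == 0) return(if (B_over_n == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

# chain-length-averaged autocorrelation function, lags 0..lag_max
.avg_autocorr <- function(ch, lag_max) {
  acfs <- lapply(ch, function(x)
    as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                          demean = TRUE)$acf))
  Reduce(`+`, acfs) / length(acfs)
}

#' Effective sample size of MCMC draws
#'
#' Initial-positive-sequence (Geyer) estimator: per-chain autocorrelations
#' are averaged across chains and summed over consecutive lag pairs while
#' the pair sums remain positive; ESS = (m * n) / (1 + 2 * sum(rho)). A
#' constant chain has undefined autocorrelation and returns 0 with a
#' warning. The estimate is capped at the pooled number of draws.
#'
#' @param chains a [chain_set()], list of chains, or numeric vector.
#' @return effective sample size (a scalar >= 0).
#' @export
effective_sample_size <- function(chains) {
  ch <- .as_chain_list(chains)
  n <- length(ch[[1L]])
  m <- length(ch)
  if (m * n < 10L) stop("pooled chain length must be at least 10")
  if (all(vapply(ch, function(x) stats::var(x) == 0, logical(1)))) {
    warning("constant chain: autocorrelation undefined, returning ESS = 0")
    return(0)
  }
  lag_max <- min(n - 1L, max(100L, floor(10 * log10(n))), 2000L)
  rho <- .avg_autocorr(ch, lag_max)[-1L]   # drop lag 0
  # Geyer initial positive sequence over lag pairs (1,2), (3,4), ...
  n_pairs <- floor(length(rho) / 2)
  s <- 0
  if (n_pairs >= 1L) {
    for (j in seq_len(n_pairs)) {
      g <- rho[2L * j - 1L] + rho[2L * j]
      if (g <= 0) break
      s <- s + g
    }
  }
  ess <- (m * n) / (1 + 2 * s)
  min(ess, m * n)
}

#' Monte Carlo standard error
#'
#' Pooled posterior standard deviation divided by the square root of the
#' effective sample size.
#'
#' @inheritParams effective_sample_size
#' @return MCSE (a scalar).
#' @export
mcse <- function(chains) {
  draws <- pool_draws(.as_chain_list(chains))
  ess <- suppressWarnings(effective_sample_size(chains))
  if (ess == 0) stop("MCSE undefined: effective sample size is 0")
  stats::sd(draws) / sqrt(ess)
}

#' Lag-1 autocorrelation, averaged across chains
#'
#' @inheritParams effective_sample_size
#' @return lag-1 autocorrelation in [-1, 1] (NA for constant chains).
#' @export
lag1_autocorr <- function(chains) {
  ch <- .as_chain_list(chains)
  r <- vapply(ch, function(x) {
    if (stats::var(x) == 0) return(NA_real_)
    as.numeric(stats::acf(x, lag.max = 1L, plot = FALSE)$acf[2L])
  }, numeric(1))
  mean(r)
}

#' Convergence diagnostics for a chain set
#'
#' @param chains a [chain_set()] or list of chains.
#' @return one-row data frame with columns `psrf`, `ess`, `mcse`,
#'   `lag1_autocorr`. `psrf` is NA for a single chain.
#' @export
diagnose <- function(chains) {
  ch <- .as_chain_list(chains)
  psrf <- if (length(ch) >= 2L) gelman_rubin(ch) else NA_real_
  ess <- suppressWarnings(effective_sample_size(ch))
  mc <- if (ess > 0) stats::sd(pool_draws(ch)) / sqrt(ess) else NA_real_
  data.frame(psrf = psrf, ess = ess, mcse = mc,
             lag1_autocorr = lag1_autocorr(ch))
}
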