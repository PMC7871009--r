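#' Posterior predictive check
#'
#' Draws parameter values from the fitted chains, simulates replicated
#' datasets of the observed size, computes discrepancy statistics on each
#' replicate and on the observed data, and reports for each statistic the
#' tail probability P(T_rep >= T_obs). Probabilities near 0 or 1 flag
#' misfit in that statistic.
#'
#' Default statistics: mean, sd and max for count fits; mean, max and the
#' fraction of fragments larger than twice the dataset mean for area fits.
#'
#' @param fit a `"count_fit"` or `"area_fit"`.
#' @param ... passed to methods.
#' @return object of class `"ppc_report"`.
#' @export
ppc <- function(fit, ...) UseMethod("ppc")

.run_ppc <- function(obs, reps_fn, statistics, n_rep, seed) {
  if (n_rep < 1L) stop("'n_rep' must be a positive integer")
  if (n_rep < 100L)
    warning("n_rep < 100: tail probabilities will be coarse")
  if (!is.null(seed)) set.seed(seed)
  t_obs <- vapply(statistics, function(f) f(obs), numeric(1))
  t_rep <- matrix(NA_real_, n_rep, length(statistics),
                  dimnames = list(NULL, names(statistics)))
  for (r in seq_len(n_rep)) {
    y <- reps_fn()
    t_rep[r, ] <- vapply(statistics, function(f) f(y), numeric(1))
  }
  p_tail <- colMeans(sweep(t_rep, 2L, t_obs, `>=`))
  structure(list(observed = t_obs, replicated = t_rep, p_tail = p_tail,
                 n_rep = n_rep), class = "ppc_report")
}

#' @rdname ppc
#' @param statistics named list of functions mapping a dataset to a scalar.
#' @param n_rep number of replicated datasets (warn below 100).
#' @param seed seed for the replicate draws.
#' @export
ppc.count_fit <- function(fit, statistics = NULL, n_rep = 1000L,
                          seed = NULL, ...) {
  if (is.null(statistics))
    statistics <- list(mean = mean, sd = stats::sd, max = max)
  lam <- pool_draws(fit$chains)
  n <- fit$data$n
  reps_fn <- function() stats::rpois(n, lam[sample.int(length(lam), 1L)])
  .run_ppc(fit$data$counts, reps_fn, statistics, n_rep, seed)
}

#' @rdname ppc
#' @export
ppc.area_fit <- function(fit, statistics = NULL, n_rep = 1000L,
                         seed = NULL, ...) {
  if (is.null(statistics))
    statistics <- list(mean = mean, max = max,
                       frac_large = function(y) mean(y > 2 * mean(y)))
  p1 <- pool_draws(fit$chains[[1L]])
  p2 <- pool_draws(fit$chains[[2L]])
  n <- fit$data$n
  reps_fn <- if (fit$distribution == "gamma") {
    function() { i <- sample.int(length(p1), 1L)
                 stats::rgamma(n, shape = p1[i], rate = p2[i]) }
  } else {
    function() { i <- sample.int(length(p1), 1L)
                 stats::rweibull(n, shape = p1[i], scale = p2[i]) }
  }
  .run_ppc(fit$data$areas, reps_fn, statistics, n_rep, seed)
}

#' @export
print.ppc_report <- function(x, ...) {
  cat(sprintf("Posterior predictive check (%d replicates)\n", x$n_rep))
  for (s in names(x$observed))
    cat(sprintf("  %-12s T_obs = %.4g, P(T_rep >= T_obs) = %.3f%s\n",
                s, x$observed[s], x$p_tail[s],
                if (x$p_tail[s] < 0.01 || x$p_tail[s] > 0.99)
                  "  ** extreme" else ""))
  invisible(x)
}
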