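#' Highest-density interval from posterior samples
#'
#' Narrowest-window estimator: the returned interval is the narrowest
#' contiguous window of the sorted draws containing `ceiling(mass * n)` of
#' them. Ties are broken in favour of the lowest starting index.
#'
#' @param samples numeric vector of at least 10 posterior draws.
#' @param mass probability mass in (0, 1); default 0.95.
#' @return named numeric `c(lower, upper)`.
#' @export
hdi_from_samples <- function(samples, mass = 0.95) {
  samples <- as.numeric(samples)
  n <- length(samples)
  if (n < 10L)
    stop("'samples' must hold at least 10 draws (got ", n, ")")
  if (!is.finite(mass) || mass <= 0 || mass >= 1)
    stop("'mass' must lie strictly between 0 and 1")
  x <- sort(samples)
  k <- ceiling(mass * n)
  if (k >= n) return(c(lower = x[1L], upper = x[n]))
  widths <- x[k:n] - x[1L:(n - k + 1L)]
  i <- which.min(widths)            # which.min returns the first minimum
  c(lower = x[i], upper = x[i + k - 1L])
}

#' Analytic highest-density interval of a unimodal distribution
#'
#' Minimizes the interval width `q(t + mass) - q(t)` over `t` in
#' `[0, 1 - mass]` by one-dimensional numerical optimization. For a
#' continuous unimodal density the optimum has equal density at both
#' endpoints (or sits at the support boundary, as for the exponential).
#'
#' @param quantile_fn vectorized quantile function of the distribution.
#' @param mass probability mass in (0, 1); default 0.95.
#' @param tol optimization tolerance on `t`.
#' @return named numeric `c(lower, upper)`.
#' @export
hdi_analytic <- function(quantile_fn, mass = 0.95, tol = 1e-10) {
  if (!is.function(quantile_fn)) stop("'quantile_fn' must be a function")
  if (!is.finite(mass) || mass <= 0 || mass >= 1)
    stop("'mass' must lie strictly between 0 and 1")
  # probe strictly inside the search range: boundary quantiles may be
  # infinite (e.g. q(1) for the Gamma) without harming the minimization
  probe <- (1 - mass) * c(0.25, 0.5, 0.75)
  qs <- vapply(probe, function(t) quantile_fn(t + mass) - quantile_fn(t),
               numeric(1))
  if (!all(is.finite(qs)))
    stop("quantile function returned non-finite values inside the search range")
  opt <- stats::optimize(function(t) quantile_fn(t + mass) - quantile_fn(t),
                         interval = c(0, 1 - mass), tol = tol)
  t0 <- opt$minimum
  c(lower = quantile_fn(t0), upper = quantile_fn(t0 + mass))
}

#' Posterior summary (mean and HDI) of a set of draws
#'
#' @param samples numeric draws or a [chain_set()].
#' @param mass HDI probability mass.
#' @return list with `mean`, `hdi_low`, `hdi_high`, `mass`.
#' @export
posterior_summary <- function(samples, mass = 0.95) {
  draws <- pool_draws(samples)
  h <- hdi_from_samples(draws, mass)
  list(mean = mean(draws), hdi_low = unname(h[1]), hdi_high = unname(h[2]),
       mass = mass)
}
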