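#' Multi-chain MCMC draw container
#'
#' Bundles post-burn-in draws of a single scalar parameter from one or more
#' chains, together with the number of discarded adaptation/burn-in
#' iterations and the master seed that produced them. All diagnostic
#' functions ([gelman_rubin()], [effective_sample_size()], [mcse()]) accept
#' this container.
#'
#' @param chains list of numeric vectors, one per chain; all the same length.
#' @param parameter name of the parameter the draws target.
#' @param n_adapt_burn number of discarded adaptation + burn-in iterations.
#' @param seed master seed used to generate the chains (per-chain seeds are
#'   derived from it by fixed offsets).
#' @return an object of class `"chain_set"`.
#' @export
chain_set <- function(chains, parameter = "parameter", n_adapt_burn = 0L,
                      seed = NA_integer_) {
  if (is.numeric(chains)) chains <- list(chains)
  if (!is.list(chains) || length(chains) < 1L)
    stop("'chains' must be a non-empty list of numeric vectors")
  lens <- vapply(chains, length, integer(1))
  if (any(lens < 2L))
    stop("each chain must hold at least 2 draws")
  if (length(unique(lens)) != 1L)
    stop("all chains must have the same length")
  if (!all(vapply(chains, function(x) all(is.finite(x)), logical(1))))
    stop("chain draws must be finite")
  structure(
    list(parameter = parameter, chains = lapply(chains, as.numeric),
         n_adapt_burn = as.integer(n_adapt_burn), seed = seed),
    class = "chain_set")
}

#' @export
print.chain_set <- function(x, ...) {
  cat(sprintf("<chain_set> %s: %d chain(s) x %d draws (burn-in %d discarded)\n",
              x$parameter, length(x$chains), length(x$chains[[1]]),
              x$n_adapt_burn))
  invisible(x)
}

#' Pool the draws of a chain set into one vector
#'
#' @param x a [chain_set()] or a list of numeric vectors.
#' @return numeric vector of concatenated draws.
#' @export
pool_draws <- function(x) {
  if (inherits(x, "chain_set")) x <- x$chains
  unlist(x, use.names = FALSE)
}

.as_chain_list <- function(x) {
  if (inherits(x, "chain_set")) return(x$chains)
  if (is.numeric(x)) return(list(x))
  if (is.list(x)) return(x)
  stop("expected a chain_set, a list of numeric vectors, or a numeric vector")
}

#' Sampler configuration
#'
#' Defaults reproduce the study protocol: three chains, 10,000 iterations of
#' adaptation and burn-in (discarded), then 50,000 retained iterations for
#' the count model or 100,000 for the area models.
#'
#' @param n_chains number of chains.
#' @param n_adapt_burn discarded adaptation + burn-in iterations per chain.
#' @param n_iter retained iterations per chain.
#' @param seed master seed; chain `k` uses `seed + k - 1`.
#' @param proposal_scale initial random-walk proposal standard deviation on
#'   the log-parameter scale (area models only; adapted during burn-in).
#' @return list of class `"sampler_config"`.
#' @export
sampler_config <- function(n_chains = 3L, n_adapt_burn = 10000L,
                           n_iter = 50000L, seed = 1L,
                           proposal_scale = 0.25) {
  if (n_chains < 1L || n_adapt_burn < 1L || n_iter < 1L)
    stop("all sampler counts must be positive")
  if (proposal_scale <= 0) stop("'proposal_scale' must be positive")
  structure(list(n_chains = as.integer(n_chains),
                 n_adapt_burn = as.integer(n_adapt_burn),
                 n_iter = as.integer(n_iter),
                 seed = as.integer(seed),
                 proposal_scale = proposal_scale),
            class = "sampler_config")
}

#' Vague Gamma prior configuration
#'
#' Shape-rate parameterization throughout. The default Gamma(0.001, 0.001)
#' is the vague prior placed on the Poisson rate and on both Gamma
#' likelihood parameters.
#'
#' @param shape0,rate0 positive prior shape and rate.
#' @return list of class `"prior_config"`.
#' @export
prior_config <- function(shape0 = 0.001, rate0 = 0.001) {
  if (shape0 <= 0 || rate0 <= 0) stop("prior shape and rate must be positive")
  structure(list(shape0 = shape0, rate0 = rate0), class = "prior_config")
}
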