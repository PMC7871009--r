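#' Two-component Gamma mixture for parent/child fragment populations
#'
#' Impact tends to leave one or two large "parent" fragments and many small
#' "child" fragments, so the area distribution can be subtly bimodal. This
#' fits y ~ w * Gamma(alpha1, beta1) + (1 - w) * Gamma(alpha2, beta2) by
#' data augmentation: latent component labels are resampled each sweep, the
#' weight w gets a uniform prior (so w | z ~ Beta(1 + n1, 1 + n2)), and each
#' component's shape and rate take vague Gamma priors updated by random-walk
#' Metropolis on the log scale. Components are relabeled every sweep so that
#' component 1 is the larger-mean (parent) component; w is its weight.
#'
#' On data with no real second mode the weight is barely identified: its
#' posterior stays diffuse (HDI spanning most of (0, 1)) and the ordered
#' components collapse onto overlapping means. This is expected behaviour,
#' not an error; inspect the `w` HDI and the mu1/mu2 separation before
#' interpreting the weight.
#'
#' @param areas positive fragment areas; at least 10 observations (fewer do
#'   not carry enough information to separate two components).
#' @param prior a [prior_config()] shared by all four shape/rate parameters.
#' @param config a [sampler_config()].
#' @param mass HDI probability mass.
#' @return object of class `"area_mixture_fit"` with chains for `w`,
#'   `alpha1`, `beta1`, `alpha2`, `beta2`, `mu1`, `mu2`, plus summaries.
#' @export
fit_area_mixture <- function(areas, prior = prior_config(),
                             config = sampler_config(n_iter = 100000L),
                             mass = 0.95) {
  areas <- as.numeric(areas)
  if (length(areas) < 10L)
    stop("at least 10 fragment areas are required to fit the mixture")
  if (any(!is.finite(areas) | areas <= 0)) stop("areas must be positive")
  n <- length(areas)
  s0 <- prior$shape0; r0 <- prior$rate0

  comp_lp <- function(la, lb, y) {
    a <- exp(la); b <- exp(lb)
    length(y) * (a * lb - lgamma(a)) + (a - 1) * sum(log(y)) - b * sum(y) +
      (s0 - 1) * (la + lb) - r0 * (a + b) + la + lb
  }

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    # initialize by a median split: component 1 = larger areas (parents)
    z <- areas > stats::median(areas)
    if (!any(z)) z[which.max(areas)] <- TRUE
    mom <- function(y) {
      if (length(y) < 2L || stats::var(y) == 0) return(c(2, 2 / mean(y)))
      a <- max(mean(y)^2 / stats::var(y), 1e-2); c(a, a / mean(y))
    }
    p1 <- log(mom(areas[z])); p2 <- log(mom(areas[!z]))
    w <- mean(z)
    sc <- rep(config$proposal_scale, 4L)
    acc <- integer(4L)
    total <- config$n_adapt_burn + config$n_iter
    keep <- matrix(NA_real_, config$n_iter, 5L)
    for (i in seq_len(total)) {
      # 1. latent labels
      l1 <- log(w) + stats::dgamma(areas, exp(p1[1]), exp(p1[2]), log = TRUE)
      l2 <- log1p(-w) + stats::dgamma(areas, exp(p2[1]), exp(p2[2]), log = TRUE)
      pr1 <- 1 / (1 + exp(l2 - l1))
      z <- stats::runif(n) < pr1
      n1 <- sum(z)
      # 2. weight (uniform prior)
      w <- stats::rbeta(1L, 1 + n1, 1 + n - n1)
      w <- min(max(w, 1e-12), 1 - 1e-12)
      # 3. component parameters (skip a component that is momentarily empty:
      #    the vague prior alone would send its shape unbounded)
      for (cidx in 1:2) {
        y <- if (cidx == 1L) areas[z] else areas[!z]
        if (length(y) < 2L) next
        par <- if (cidx == 1L) p1 else p2
        cur_lp <- comp_lp(par[1], par[2], y)
        for (p in 1:2) {
          j <- 2L * (cidx - 1L) + p
          prop <- par
          prop[p] <- par[p] + stats::rnorm(1L, 0, sc[j])
          prop_lp <- comp_lp(prop[1], prop[2], y)
          if (is.finite(prop_lp) && log(stats::runif(1L)) < prop_lp - cur_lp) {
            par <- prop; cur_lp <- prop_lp; acc[j] <- acc[j] + 1L
          }
        }
        if (cidx == 1L) p1 <- par else p2 <- par
      }
      # 4. identifiability: component 1 is the larger-mean component
      mu1 <- exp(p1[1] - p1[2]); mu2 <- exp(p2[1] - p2[2])
      if (mu1 < mu2) {
        tmp <- p1; p1 <- p2; p2 <- tmp
        w <- 1 - w
      }
      if (i <= config$n_adapt_burn && i %% 50L == 0L) {
        rate <- acc / 50
        sc <- ifelse(rate < 0.2, sc * 0.7, ifelse(rate > 0.5, sc * 1.4, sc))
        acc <- integer(4L)
      }
      if (i > config$n_adapt_burn)
        keep[i - config$n_adapt_burn, ] <- c(w, exp(p1), exp(p2))
    }
    keep
  }

  runs <- lapply(seq_len(config$n_chains),
                 function(k) run_chain(config$seed + k - 1L))
  par_names <- c("w", "alpha1", "beta1", "alpha2", "beta2")
  chain_list <- stats::setNames(lapply(seq_along(par_names), function(j)
    chain_set(lapply(runs, function(m) m[, j]), par_names[j],
              config$n_adapt_burn, config$seed)), par_names)
  chain_list$mu1 <- chain_set(lapply(runs, function(m) m[, 2] / m[, 3]),
                              "mu1", config$n_adapt_burn, config$seed)
  chain_list$mu2 <- chain_set(lapply(runs, function(m) m[, 4] / m[, 5]),
                              "mu2", config$n_adapt_burn, config$seed)
  summaries <- do.call(rbind, lapply(names(chain_list), function(p) {
    s <- posterior_summary(chain_list[[p]], mass)
    data.frame(parameter = p, mean = s$mean, hdi_low = s$hdi_low,
               hdi_high = s$hdi_high)
  }))
  structure(
    list(data = list(areas = areas, n = n), prior = prior, config = config,
         chains = chain_list, summaries = summaries, mass = mass),
    class = "area_mixture_fit")
}

#' @export
print.area_mixture_fit <- function(x, ...) {
  cat(sprintf("Two-component Gamma mixture fit (n = %d fragments)\n",
              x$data$n))
  s <- x$summaries
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-6s mean %.4g, HDI (%.4g, %.4g)\n", s$parameter[i],
                s$mean[i], s$hdi_low[i], s$hdi_high[i]))
  cat("  component 1 = parent (larger-mean) component; w is its weight\n")
  invisible(x)
}

#' @export
coef.area_mixture_fit <- function(object, ...) {
  stats::setNames(object$summaries$mean, object$summaries$parameter)
}
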