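# independent oracles used across test files

# exhaustive narrowest-window HDI: plain loop over all candidate windows
brute_hdi <- function(samples, mass = 0.95) {
  x <- sort(samples)
  n <- length(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  best_i <- 1L
  best_w <- Inf
  for (i in 1:(n - k + 1)) {
    w <- x[i + k - 1] - x[i]
    if (w < best_w - 0) { best_w <- w; best_i <- i }
  }
  c(x[best_i], x[best_i + k - 1])
}

# textbook two-variance PSRF computed from first principles
brute_psrf <- function(chains) {
  m <- length(chains); n <- length(chains[[1]])
  means <- sapply(chains, mean)
  W <- mean(sapply(chains, var))
  B <- n * var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# AR(1) chain with known integrated autocorrelation time
ar1_chain <- function(n, phi, seed) {
  set.seed(seed)
  as.numeric(stats::arima.sim(list(ar = phi), n))
}

# quick sampler settings for tests that only need a correct, well-mixed
# posterior, not the full study protocol
quick_cfg <- function(seed = 1L, n_iter = 4000L, n_chains = 2L,
                      n_adapt_burn = 1000L)
  sampler_config(n_chains = n_chains, n_adapt_burn = n_adapt_burn,
                 n_iter = n_iter, seed = seed)

# small balanced structural-trait table generator
make_structure_table <- function(varieties = c("A", "B"),
                                 stages = c("GS65", "GS77"),
                                 n_rep = 5, effect = 10, sd = 3,
                                 seed = 1) {
  set.seed(seed)
  d <- expand.grid(variety = varieties, growth_stage = stages,
                   rep = seq_len(n_rep), stringsAsFactors = FALSE)
  d$region <- "mid"
  d$trait <- "thickness_min_um"
  d$value <- 100 + effect * (d$variety == varieties[2]) + rnorm(nrow(d), 0, sd)
  d$ear_id <- seq_len(nrow(d))
  d
}
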