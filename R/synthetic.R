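#' Simulate recorded fragment counts
#'
#' Poisson(lambda) draws with zeros recoded to 1, mirroring the assay
#' convention that an intact lemma is recorded as a single fragment.
#'
#' @param lambda positive Poisson rate (mean fragments per lemma).
#' @param n number of lemmas.
#' @param seed optional seed.
#' @return integer vector of length n, all values >= 1.
#' @export
simulate_counts <- function(lambda, n, seed = NULL) {
  if (!is.finite(lambda) || lambda <= 0) stop("'lambda' must be positive")
  if (n < 1L) stop("'n' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  y <- stats::rpois(n, lambda)
  y[y == 0L] <- 1L
  y
}

#' Simulate i.i.d. Gamma fragment areas
#'
#' @param alpha,beta positive shape and rate.
#' @param n number of fragments.
#' @param seed optional seed.
#' @return numeric vector of positive areas (pixels).
#' @export
simulate_areas <- function(alpha, beta, n, seed = NULL) {
  if (alpha <= 0 || beta <= 0) stop("'alpha' and 'beta' must be positive")
  if (!is.null(seed)) set.seed(seed)
  stats::rgamma(n, shape = alpha, rate = beta)
}

#' Simulate sequential breakage of a lemma
#'
#' Area-conserving fragmentation: starting from a single fragment equal to
#' the whole lemma area, each event selects an existing fragment with
#' probability proportional to its area and splits it at a Beta(a, b)
#' fraction. This reproduces the parent/child structure seen in impact
#' assays: one or two large first-formed fragments and many small late
#' fragments. The total area is conserved exactly and the final fragment
#' count is `n_events + 1`.
#'
#' @param total_area positive lemma area (pixels).
#' @param n_events number of breakage events (>= 0).
#' @param split_a,split_b Beta split-fraction parameters (default 1, 1 =
#'   uniform splits).
#' @param seed optional seed.
#' @return numeric vector of `n_events + 1` fragment areas summing exactly
#'   to `total_area`.
#' @export
simulate_breakage <- function(total_area, n_events, split_a = 1, split_b = 1,
                              seed = NULL) {
  if (total_area <= 0) stop("'total_area' must be positive")
  if (n_events < 0L) stop("'n_events' must be >= 0")
  if (split_a <= 0 || split_b <= 0) stop("Beta split parameters must be positive")
  if (!is.null(seed)) set.seed(seed)
  frags <- total_area
  for (e in seq_len(n_events)) {
    i <- sample.int(length(frags), 1L, prob = frags)
    f <- stats::rbeta(1L, split_a, split_b)
    piece <- f * frags[i]
    rest <- frags[i] - piece     # exact complement: the sum telescopes
    frags[i] <- piece
    frags <- c(frags, rest)
  }
  frags
}

#' Default study design: four varieties at two growth stages
#'
#' Group-level generative parameters matching the published estimates for
#' the four-variety impact assay: lambda is the mean fragment count per
#' lemma and mu the mean fragment area in pixels (order 10^6); the Gamma
#' shape is alpha = 2 (right-skewed, CV ~ 0.7) with beta = alpha / mu.
#'
#' @return data frame with columns `variety`, `growth_stage`, `lambda`,
#'   `alpha`, `beta`, `n_lemmas`.
#' @export
default_study_groups <- function() {
  g <- data.frame(
    variety = rep(c("Poker", "Propino", "GoldenPromise", "Henni"), 2),
    growth_stage = rep(c("GS65", "GS77"), each = 4),
    lambda = c(7.3, 10.0, 1.9, 3.5, 6.0, 4.6, 2.6, 1.2),
    mu = c(0.98, 0.65, 3.52, 1.85, 1.13, 1.53, 2.45, 5.45) * 1e6,
    n_lemmas = 10L)
  g$alpha <- 2
  g$beta <- g$alpha / g$mu
  g[c("variety", "growth_stage", "lambda", "alpha", "beta", "n_lemmas")]
}

#' Study-level generator configuration
#'
#' @param groups data frame as returned by [default_study_groups()].
#' @param mode `"gamma_iid"` (areas drawn i.i.d. from each group's Gamma) or
#'   `"breakage"` (areas from [simulate_breakage()] with `count - 1` events
#'   on a whole lemma).
#' @param lemma_area_px whole-lemma area in pixels used in breakage mode.
#' @param split_a,split_b Beta split-fraction parameters for breakage mode.
#' @param seed master seed.
#' @return list of class `"study_config"`.
#' @export
study_config <- function(groups = default_study_groups(),
                         mode = c("gamma_iid", "breakage"),
                         lemma_area_px = 6e6, split_a = 1, split_b = 1,
                         seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(all(c("variety", "growth_stage", "lambda", "alpha", "beta",
                  "n_lemmas") %in% names(groups)))
  if (any(groups$lambda <= 0) || any(groups$alpha <= 0) ||
      any(groups$beta <= 0) || any(groups$n_lemmas < 1L))
    stop("group parameters must be positive and n_lemmas >= 1")
  if (lemma_area_px <= 0) stop("'lemma_area_px' must be positive")
  structure(list(groups = groups, mode = mode,
                 lemma_area_px = lemma_area_px,
                 split_a = split_a, split_b = split_b,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Generate a synthetic impact-assay study
#'
#' For each group (variety x growth stage) and lemma, draws a recorded
#' fragment count via [simulate_counts()] and then fragment areas either
#' i.i.d. from the group Gamma or by sequential breakage of a whole lemma.
#' Output tables use the standard CSV schemas consumed by the fitting
#' pipeline. Fully reproducible from the master seed.
#'
#' @param config a [study_config()].
#' @return list with data frames `counts` (variety, growth_stage, ear_id,
#'   lemma_id, fragment_count) and `areas` (variety, growth_stage, lemma_id,
#'   fragment_area_px).
#' @export
generate_study <- function(config = study_config()) {
  if (!inherits(config, "study_config")) stop("'config' must be a study_config")
  set.seed(config$seed)
  counts_rows <- list(); areas_rows <- list()
  g <- config$groups
  for (i in seq_len(nrow(g))) {
    n <- g$n_lemmas[i]
    cnt <- simulate_counts(g$lambda[i], n)
    counts_rows[[i]] <- data.frame(
      variety = g$variety[i], growth_stage = g$growth_stage[i],
      ear_id = seq_len(n), lemma_id = seq_len(n), fragment_count = cnt)
    per_lemma <- lapply(seq_len(n), function(j) {
      if (config$mode == "gamma_iid")
        simulate_areas(g$alpha[i], g$beta[i], cnt[j])
      else
        simulate_breakage(config$lemma_area_px, cnt[j] - 1L,
                          config$split_a, config$split_b)
    })
    areas_rows[[i]] <- data.frame(
      variety = g$variety[i], growth_stage = g$growth_stage[i],
      lemma_id = rep(seq_len(n), vapply(per_lemma, length, integer(1))),
      fragment_area_px = unlist(per_lemma))
  }
  list(counts = do.call(rbind, counts_rows),
       areas = do.call(rbind, areas_rows))
}

#' Render fragment areas as a binary mask
#'
#' Places non-touching connected blobs on an all-background canvas, one per
#' requested area, whose pixel counts equal the requested (rounded) areas
#' exactly. Blobs are grown from a random seed pixel by repeatedly annexing
#' a random 4-neighbour of the current blob, which keeps every blob
#' connected under both 4- and 8-connectivity. A 2-pixel exclusion margin
#' around each placed blob guarantees separation.
#'
#' @param areas vector of target pixel counts (may be empty).
#' @param canvas_shape integer c(rows, cols) of the canvas.
#' @param seed optional seed.
#' @param max_tries placement attempts per blob before giving up.
#' @return logical matrix (TRUE = foreground).
#' @export
render_fragment_image <- function(areas, canvas_shape = c(512L, 512L),
                                  seed = NULL, max_tries = 200L) {
  nr <- canvas_shape[1]; nc <- canvas_shape[2]
  areas <- as.integer(round(areas))
  img <- matrix(FALSE, nr, nc)
  if (length(areas) == 0L) return(img)
  if (any(areas < 1L)) stop("areas must be >= 1 pixel")
  # margin accounting: each blob excludes roughly its area plus a boundary rim
  if (sum(areas) + 25L * length(areas) > nr * nc)
    stop(sprintf(
      "canvas too small: %d x %d cannot hold %d blob pixels plus margins; need at least %d pixels",
      nr, nc, sum(areas), sum(areas) + 25L * length(areas)))
  if (!is.null(seed)) set.seed(seed)
  forbidden <- matrix(FALSE, nr, nc)
  for (a in sort(areas, decreasing = TRUE)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      blob <- .grow_blob(a, nr, nc, forbidden)
      if (!is.null(blob)) {
        img[blob] <- TRUE
        forbidden <- forbidden | .dilate_mask(blob, nr, nc, radius = 2L)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf(
        "canvas too small: could not place a %d-pixel blob on %d x %d after %d attempts",
        a, nr, nc, max_tries))
  }
  img
}

# grow a 4-connected blob of exactly `a` pixels avoiding `forbidden`;
# returns linear indices or NULL if growth stalls
.grow_blob <- function(a, nr, nc, forbidden) {
  free <- which(!forbidden)
  if (length(free) == 0L) return(NULL)
  start <- free[sample.int(length(free), 1L)]
  in_blob <- integer(0)
  blob_mask <- rep(FALSE, nr * nc)
  frontier <- start
  while (length(in_blob) < a) {
    if (length(frontier) == 0L) return(NULL)
    pick <- sample.int(length(frontier), 1L)
    cell <- frontier[pick]
    frontier <- frontier[-pick]
    if (blob_mask[cell] || forbidden[cell]) next
    blob_mask[cell] <- TRUE
    in_blob <- c(in_blob, cell)
    r <- (cell - 1L) %% nr + 1L
    cc <- (cell - 1L) %/% nr + 1L
    if (r > 1L) frontier <- c(frontier, cell - 1L)
    if (r < nr) frontier <- c(frontier, cell + 1L)
    if (cc > 1L) frontier <- c(frontier, cell - nr)
    if (cc < nc) frontier <- c(frontier, cell + nr)
  }
  in_blob
}

# chebyshev dilation of a set of linear indices by `radius`
.dilate_mask <- function(idx, nr, nc, radius = 2L) {
  m <- matrix(FALSE, nr, nc)
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  for (dr in -radius:radius) for (dc in -radius:radius) {
    rr <- r + dr; ccc <- cc + dc
    ok <- rr >= 1L & rr <= nr & ccc >= 1L & ccc <= nc
    m[cbind(rr[ok], ccc[ok])] <- TRUE
  }
  m
}
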