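#' Two-way ANOVA on a structural trait
#'
#' Fixed-effects variety x growth-stage ANOVA with interaction on one trait
#' within one lemma region. The design must be complete (every variety x
#' growth-stage cell present with >= 2 replicates). Unbalanced designs
#' error by default; `type2 = TRUE` switches to Type-II sums of squares via
#' \pkg{car}.
#'
#' @param table data frame with columns `variety`, `growth_stage`, `region`,
#'   `trait`, `value` (and optionally `ear_id`).
#' @param trait trait name to analyse.
#' @param region region name (`"central"`, `"mid"` or `"lateral"`).
#' @param type2 allow unbalanced designs via Type-II sums of squares.
#' @return data frame with columns `term`, `df`, `F`, `p`.
#' @export
anova_two_way <- function(table, trait, region, type2 = FALSE) {
  d <- .subset_structure(table, trait, region)
  tab <- base::table(d$variety, d$growth_stage)
  if (any(tab == 0L)) {
    miss <- which(tab == 0L, arr.ind = TRUE)
    stop("empty design cell(s): ",
         paste(rownames(tab)[miss[, 1]], colnames(tab)[miss[, 2]],
               sep = " x ", collapse = "; "))
  }
  if (any(tab < 2L)) stop("each variety x growth-stage cell needs >= 2 replicates")
  balanced <- length(unique(as.vector(tab))) == 1L
  d$variety <- factor(d$variety); d$growth_stage <- factor(d$growth_stage)
  if (!balanced && !type2)
    stop("unbalanced design: set type2 = TRUE for Type-II sums of squares")
  if (balanced) {
    fit <- stats::aov(value ~ variety * growth_stage, data = d)
    s <- summary(fit)[[1L]]
    terms <- trimws(rownames(s))
    keep <- terms != "Residuals"
    ss <- s[keep, "Sum Sq"]
    out <- data.frame(term = terms[keep], df = s[keep, "Df"],
                      F = s[keep, "F value"], p = s[keep, "Pr(>F)"])
  } else {
    if (!requireNamespace("car", quietly = TRUE))
      stop("Type-II ANOVA requires the 'car' package")
    fit <- stats::lm(value ~ variety * growth_stage, data = d)
    a <- car::Anova(fit, type = 2)
    keep <- rownames(a) != "Residuals"
    ss <- a[keep, "Sum Sq"]
    out <- data.frame(term = rownames(a)[keep], df = a[keep, "Df"],
                      F = a[keep, "F value"], p = a[keep, "Pr(>F)"])
  }
  # a term whose sum of squares is numerically zero carries no signal:
  # report F = 0 rather than the 0/0 noise of an all-constant response
  zero <- ss <= 1e-12 * sum(d$value^2)
  out$F[zero] <- 0; out$p[zero] <- 1
  rownames(out) <- NULL
  out
}

.subset_structure <- function(table, trait, region) {
  req <- c("variety", "growth_stage", "region", "trait", "value")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols))
    stop("structure table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  d <- table[table$trait == trait & table$region == region, , drop = FALSE]
  if (nrow(d) == 0L)
    stop("no rows for trait '", trait, "' in region '", region, "'")
  if (any(d$value <= 0)) stop("trait values must be positive")
  d
}

#' Tukey HSD over variety x growth-stage cells
#'
#' Studentized-range simultaneous confidence intervals for all pairwise
#' differences between the cell means of the variety x growth-stage
#' crossing, for one trait within one region.
#'
#' @inheritParams anova_two_way
#' @param alpha family-wise error rate (default 0.05 for 95% intervals).
#' @return data frame with `pair`, `diff`, `ci_low`, `ci_high`, `p_adj`,
#'   `significant`.
#' @export
tukey_hsd_cells <- function(table, trait, region, alpha = 0.05) {
  d <- .subset_structure(table, trait, region)
  d$cell <- factor(paste(d$variety, d$growth_stage, sep = ":"))
  if (nlevels(d$cell) < 2L) stop("need at least 2 cells to compare")
  fit <- stats::aov(value ~ cell, data = d)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$cell
  out <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                    ci_low = tk[, "lwr"], ci_high = tk[, "upr"],
                    p_adj = tk[, "p adj"])
  out$significant <- out$ci_low > 0 | out$ci_high < 0
  rownames(out) <- NULL
  out
}

#' Compact letter display from a pairwise significance relation
#'
#' Insertion-absorption algorithm: two groups share a letter if and only if
#' they are not significantly different. Letters are assigned in group
#' order.
#'
#' @param sig logical matrix, symmetric, `sig[i, j]` TRUE when groups i and
#'   j differ significantly; dimnames give the group names.
#' @return named character vector of letter strings, one per group.
#' @export
compact_letters <- function(sig) {
  if (!is.matrix(sig) || nrow(sig) != ncol(sig))
    stop("'sig' must be a square matrix")
  if (!isTRUE(all(sig == t(sig)))) stop("'sig' must be symmetric")
  groups <- rownames(sig)
  if (is.null(groups)) groups <- as.character(seq_len(nrow(sig)))
  sets <- list(groups)                     # start: everyone shares a letter
  pairs <- which(upper.tri(sig) & sig, arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    gi <- groups[pairs[k, 1]]; gj <- groups[pairs[k, 2]]
    new_sets <- list()
    for (S in sets) {
      if (gi %in% S && gj %in% S) {
        new_sets <- c(new_sets, list(setdiff(S, gi)), list(setdiff(S, gj)))
      } else new_sets <- c(new_sets, list(S))
    }
    # absorption: drop sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) for (b in seq_along(new_sets)) {
      if (a != b && keep[a] && keep[b] &&
          all(new_sets[[a]] %in% new_sets[[b]]) &&
          !(all(new_sets[[b]] %in% new_sets[[a]]) && a < b))
        keep[a] <- FALSE
    }
    sets <- unique(new_sets[keep])
  }
  # order letters by the first group they contain
  first <- vapply(sets, function(S) min(match(S, groups)), numeric(1))
  sets <- sets[order(first)]
  letters_out <- stats::setNames(rep("", length(groups)), groups)
  for (j in seq_along(sets)) {
    lt <- letters[j]
    for (g in sets[[j]]) letters_out[g] <- paste0(letters_out[g], lt)
  }
  letters_out
}

#' Descriptive normal-theory confidence interval of a group mean
#'
#' Mean +/- z * standard error, the descriptive interval used for trait
#' summaries (z = 1.96 for 95%).
#'
#' @param values numeric vector, n >= 2.
#' @param conf confidence level.
#' @return named numeric `c(mean, ci_low, ci_high)`.
#' @export
group_ci_normal <- function(values, conf = 0.95) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  m <- mean(values)
  se <- stats::sd(values) / sqrt(n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(mean = m, ci_low = m - z * se, ci_high = m + z * se)
}

#' Ratio of group means with a bootstrap confidence interval
#'
#' Point estimate mean(numerator)/mean(denominator) with a percentile
#' bootstrap interval (groups resampled independently).
#'
#' @param numerator,denominator numeric vectors, each n >= 3.
#' @param n_boot bootstrap resamples.
#' @param conf confidence level.
#' @param seed optional seed.
#' @return list with `ratio`, `ci_low`, `ci_high`, `n_boot`.
#' @export
ratio_of_means_ci <- function(numerator, denominator, n_boot = 5000L,
                              conf = 0.95, seed = NULL) {
  if (length(numerator) < 3L || length(denominator) < 3L)
    stop("both groups need at least 3 values")
  if (mean(denominator) == 0) stop("denominator group mean is zero")
  if (!is.null(seed)) set.seed(seed)
  ratio <- mean(numerator) / mean(denominator)
  boot <- replicate(n_boot, {
    mean(sample(numerator, replace = TRUE)) /
      mean(sample(denominator, replace = TRUE))
  })
  qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  list(ratio = ratio, ci_low = qs[1], ci_high = qs[2], n_boot = n_boot)
}
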