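test_that("two-way ANOVA matches a hand-computed sums-of-squares oracle", {
  # 2 x 2 balanced design, 3 replicates per cell
  d <- expand.grid(variety = c("A", "B"), growth_stage = c("S1", "S2"),
                   rep = 1:3, stringsAsFactors = FALSE)
  d$region <- "mid"; d$trait <- "thickness_min_um"; d$ear_id <- seq_len(nrow(d))
  d$value <- c(10, 14, 11, 15, 12, 16, 13, 19, 11, 15, 12, 18)
  out <- anova_two_way(d, "thickness_min_um", "mid")

  # direct SS decomposition
  y <- d$value
  gm <- mean(y)
  mA <- tapply(y, d$variety, mean)
  mB <- tapply(y, d$growth_stage, mean)
  mAB <- tapply(y, interaction(d$variety, d$growth_stage), mean)
  ss_a <- 6 * sum((mA - gm)^2)
  ss_b <- 6 * sum((mB - gm)^2)
  cell <- interaction(d$variety, d$growth_stage)
  ss_ab <- 3 * sum((mAB - gm)^2) - ss_a - ss_b
  ss_err <- sum((y - mAB[cell])^2)
  ms_err <- ss_err / 8
  expect_equal(out$F[out$term == "variety"], (ss_a / 1) / ms_err,
               tolerance = 1e-8)
  expect_equal(out$F[out$term == "growth_stage"], (ss_b / 1) / ms_err,
               tolerance = 1e-8)
  expect_equal(out$F[out$term == "variety:growth_stage"],
               (ss_ab / 1) / ms_err, tolerance = 1e-8)
  # SS identity for the balanced case
  ss_tot <- sum((y - gm)^2)
  expect_equal(ss_a + ss_b + ss_ab + ss_err, ss_tot, tolerance = 1e-8)
})

test_that("degenerate and unbalanced designs are handled explicitly", {
  d <- make_structure_table(effect = 0, sd = 1)
  d$value <- 100                     # all identical
  out <- anova_two_way(d, "thickness_min_um", "mid")
  expect_true(all(out$F == 0))
  # missing cell named in the error
  d2 <- make_structure_table()
  d2 <- d2[!(d2$variety == "B" & d2$growth_stage == "GS77"), ]
  expect_error(anova_two_way(d2, "thickness_min_um", "mid"), "B x GS77")
  # unbalanced: error by default, Type-II fallback runs
  d3 <- make_structure_table()
  d3 <- d3[-1, ]
  expect_error(anova_two_way(d3, "thickness_min_um", "mid"), "unbalanced")
  if (requireNamespace("car", quietly = TRUE)) {
    out3 <- anova_two_way(d3, "thickness_min_um", "mid", type2 = TRUE)
    expect_true(all(is.finite(out3$F)))
  }
})

test_that("Tukey intervals match the studentized-range oracle", {
  # 3 groups x 4 replicates; oracle: q * s / sqrt(n) half-width
  set.seed(5)
  d <- data.frame(variety = rep(c("A", "B", "C"), each = 4),
                  growth_stage = "GS65", region = "mid",
                  trait = "thickness_min_um",
                  value = c(10, 12, 11, 13, 15, 17, 16, 18, 24, 26, 25, 27))
  d$ear_id <- seq_len(nrow(d))
  out <- tukey_hsd_cells(d, "thickness_min_um", "mid")
  fit <- aov(value ~ factor(variety), data = d)
  mse <- sum(residuals(fit)^2) / fit$df.residual
  hw <- qtukey(0.95, 3, 9) * sqrt(mse / 4)
  means <- tapply(d$value, d$variety, mean)
  ba <- out[out$pair == "B:GS65-A:GS65", ]
  expect_equal(ba$diff, unname(means["B"] - means["A"]), tolerance = 1e-8)
  expect_equal(ba$ci_low, unname(means["B"] - means["A"]) - hw,
               tolerance = 1e-8)
  expect_equal(ba$ci_high, unname(means["B"] - means["A"]) + hw,
               tolerance = 1e-8)
  # significance flags consistent with the interval excluding zero
  expect_identical(out$significant, out$ci_low > 0 | out$ci_high < 0)
})

test_that("identical groups yield all-covering Tukey intervals", {
  d <- make_structure_table(effect = 0, sd = 1, seed = 3)
  out <- tukey_hsd_cells(d, "thickness_min_um", "mid")
  expect_true(all(out$ci_low < 0 & out$ci_high > 0))
})

test_that("Tukey intervals are wider than unadjusted t intervals", {
  d <- make_structure_table(varieties = c("A", "B", "C"), effect = 5,
                            sd = 4, seed = 9)
  out <- tukey_hsd_cells(d, "thickness_min_um", "mid")
  sub <- d[d$growth_stage == "GS65" & d$variety %in% c("A", "B"), ]
  tt <- t.test(value ~ variety, data = sub, var.equal = TRUE)
  tukey_w <- with(out[out$pair == "B:GS65-A:GS65", ], ci_high - ci_low)
  expect_gt(tukey_w, diff(tt$conf.int))
})

test_that("compact letters encode the significance relation", {
  sig3 <- function(pairs) {
    m <- matrix(FALSE, 3, 3, dimnames = list(c("A", "B", "C"),
                                             c("A", "B", "C")))
    for (p in pairs) { m[p[1], p[2]] <- TRUE; m[p[2], p[1]] <- TRUE }
    m
  }
  # all different
  lt <- compact_letters(sig3(list(c("A","B"), c("A","C"), c("B","C"))))
  expect_equal(unname(lt), c("a", "b", "c"))
  # none different
  lt <- compact_letters(sig3(list()))
  expect_equal(unname(lt), c("a", "a", "a"))
  # chain: A~B, B~C, A!=C
  lt <- compact_letters(sig3(list(c("A", "C"))))
  expect_equal(unname(lt), c("a", "ab", "b"))
  # round-trip: sharing a letter <=> not significantly different
  share <- function(lt) outer(lt, lt, Vectorize(function(x, y)
    length(intersect(strsplit(x, "")[[1]], strsplit(y, "")[[1]])) > 0))
  for (pairs in list(list(c("A","C")), list(), list(c("A","B"), c("A","C")))) {
    m <- sig3(pairs)
    lt <- compact_letters(m)
    sh <- share(lt)
    diag(sh) <- TRUE
    expect_identical(unname(!sh), unname(m))
  }
})

test_that("descriptive z-interval follows mean +/- 1.96 se", {
  ci <- group_ci_normal(c(1, 2, 3, 4))
  expect_equal(unname(ci["mean"]), 2.5)
  expect_equal(unname(ci["ci_high"] - ci["mean"]),
               qnorm(0.975) * sd(c(1, 2, 3, 4)) / 2, tolerance = 1e-10)
  expect_equal(unname(ci["ci_high"] - ci["mean"]), 1.96 * 1.2910 / 2,
               tolerance = 1e-3)
  ci0 <- group_ci_normal(rep(7, 5))
  expect_equal(unname(ci0["ci_high"] - ci0["ci_low"]), 0)
  # width scales as 1/sqrt(n): unit-sd samples of quadrupling size
  set.seed(10)
  widths <- vapply(c(10, 40, 160), function(n) {
    v <- as.numeric(scale(rnorm(n)))   # mean 0, sd exactly 1
    ci <- group_ci_normal(v)
    unname(ci["ci_high"] - ci["ci_low"])
  }, numeric(1))
  expect_equal(widths[1] / widths[2], 2, tolerance = 1e-10)
  expect_equal(widths[2] / widths[3], 2, tolerance = 1e-10)
})

test_that("bootstrap ratio of means recovers a known thickness ratio", {
  r <- ratio_of_means_ci(rep(50, 5), rep(50, 5), n_boot = 500, seed = 1)
  expect_equal(r$ratio, 1)
  expect_lte(r$ci_low, 1); expect_gte(r$ci_high, 1)
  covered <- ratio_in <- logical(50)
  for (s in 1:50) {
    set.seed(2000 + s)
    high <- rnorm(30, 61, 10)
    low <- rnorm(30, 100, 10)
    r <- ratio_of_means_ci(high, low, n_boot = 1000, seed = s)
    ratio_in[s] <- r$ratio > 0.55 && r$ratio < 0.67
    covered[s] <- r$ci_low <= 0.61 && r$ci_high >= 0.61
  }
  expect_gte(mean(ratio_in), 0.9)
  expect_gte(mean(covered), 0.9)
  r1 <- ratio_of_means_ci(1:10, 2:11, seed = 4, n_boot = 200)
  r2 <- ratio_of_means_ci(1:10, 2:11, seed = 4, n_boot = 200)
  expect_identical(r1, r2)
  expect_error(ratio_of_means_ci(1:5, rep(0, 5), seed = 1), "zero")
})
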