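test_that("stage profiles give per-stage mean, SEM and n", {
  rec <- data.frame(div = c(3, 3, 3, 14, 28), value = c(1, 2, 3, 5, 7))
  prof <- stage_profiles(rec)
  expect_equal(prof$mean, c(2, 5, 7))
  expect_equal(prof$sem[1], sd(c(1, 2, 3)) / sqrt(3))
  expect_true(is.na(prof$sem[2]))           # single value: SEM flagged
  expect_equal(prof$n, c(3L, 1L, 1L))
})

test_that("stage profiles equal the brute-force groupby on simulated tables", {
  set.seed(13)
  rec <- data.frame(div = sample(c(3, 6, 10, 14, 17, 21, 28), 210, TRUE),
                    value = rnorm(210))
  prof <- stage_profiles(rec)
  or <- oracle_groupby(rec$div, rec$value)
  expect_equal(prof$mean, or$mean, tolerance = 1e-12)
  expect_equal(prof$sem, or$sem, tolerance = 1e-12)
})

test_that("growth rates are forward differences on the DIV grid", {
  prof <- stage_profiles(data.frame(div = c(10, 20), value = c(100, 200)))
  expect_equal(growth_rates(prof)$rate, 10)
  flatp <- stage_profiles(data.frame(div = c(3, 14, 28), value = c(5, 5, 5)))
  expect_equal(growth_rates(flatp)$rate, c(0, 0))
  expect_error(growth_rates(stage_profiles(data.frame(div = 3, value = 1))),
               "2 stages")
})

test_that("a logistic profile has a bell-shaped rate with one interior maximum", {
  div <- c(3, 6, 10, 14, 17, 21, 28)
  len <- 1600 / (1 + exp(-(div - 12) / 4))
  prof <- stage_profiles(data.frame(div = div, value = len))
  r <- growth_rates(prof)$rate
  imax <- which.max(r)
  expect_gt(imax, 1); expect_lt(imax, length(r))
  expect_true(all(diff(r[1:imax]) > 0))
  expect_true(all(diff(r[imax:length(r)]) < 0))
  # trapezoid of the rates recovers the profile differences exactly
  dd <- diff(prof$div)
  expect_equal(cumsum(r * dd), cumsum(diff(prof$mean)), tolerance = 1e-12)
})

test_that("profile correlation returns exact OLS and handles degeneracy", {
  x <- stage_profiles(data.frame(div = c(3, 14, 28), value = c(1, 2, 4)))
  y <- stage_profiles(data.frame(div = c(3, 14, 28), value = c(3, 5, 9)))
  fit <- profile_correlation(x, y)
  expect_equal(fit$slope, 2); expect_equal(fit$intercept, 1)
  expect_equal(fit$r_squared, 1)
  set.seed(14)
  y2 <- stage_profiles(data.frame(div = c(3, 14, 28), value = c(9, 3, 5)))
  fit2 <- profile_correlation(x, y2)
  # closed-form R^2
  r <- cor(x$mean, y2$mean)
  expect_equal(fit2$r_squared, r^2, tolerance = 1e-12)
  expect_true(fit2$r_squared >= 0 && fit2$r_squared <= 1)
  ycst <- stage_profiles(data.frame(div = c(3, 14, 28), value = c(2, 2, 2)))
  fit3 <- profile_correlation(x, ycst)
  expect_true(fit3$degenerate)
  expect_equal(fit3$r_squared, 0)
  expect_error(profile_correlation(x, stage_profiles(
    data.frame(div = c(3, 14, 21), value = 1:3))), "grids")
})

test_that("R^2 is invariant to affine rescaling of both profiles", {
  set.seed(15)
  x <- stage_profiles(data.frame(div = c(3, 6, 14, 28), value = rnorm(4)))
  y <- stage_profiles(data.frame(div = c(3, 6, 14, 28), value = rnorm(4)))
  r0 <- profile_correlation(x, y)$r_squared
  x2 <- x; x2$mean <- 3 * x2$mean - 7
  y2 <- y; y2$mean <- -2 * y2$mean + 1
  expect_equal(profile_correlation(x2, y2)$r_squared, r0, tolerance = 1e-12)
})

test_that("two-group comparison equals the textbook pooled-t oracle", {
  gc <- group_compare(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  or <- oracle_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(gc$statistic, or$t, tolerance = 1e-12)
  expect_equal(gc$p_value, or$p, tolerance = 1e-12)
  expect_equal(gc$df, 4)
  same <- group_compare(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$stars, "n.s.")
})

test_that("ANOVA with Bonferroni flags nothing for equal-mean groups", {
  set.seed(16)
  g <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  g <- lapply(g, function(v) v - mean(v))    # exactly equal means
  gc <- group_compare(g)
  expect_equal(gc$test, "anova_bonferroni")
  expect_true(all(gc$pairwise$p_adj >= gc$pairwise$p_raw))
  expect_true(all(gc$pairwise$p_adj <= 1))
  expect_equal(gc$pairwise$p_adj,
               pmin(1, gc$pairwise$p_raw * 3), tolerance = 1e-12)
  expect_true(all(gc$pairwise$stars == "n.s."))
})

test_that("star coding follows the significance criteria", {
  expect_equal(p_stars(c(0.04, 0.009, 0.0009, 0.2)),
               c("*", "**", "***", "n.s."))
})

test_that("full synthetic two-condition run recovers the profile-correlation signs", {
  # healthy maturation: frequency falls while length and amplitude grow
  pr <- build_stage_presets(); mp <- build_morph_presets()
  divs <- c(3, 10, 17, 28)
  freq <- vapply(divs, function(d) {
    get_preset(pr, paste0("DIV", d), "healthy")$event_rate_mHz
  }, numeric(1))
  amp <- vapply(divs, function(d) {
    get_preset(pr, paste0("DIV", d), "healthy")$amplitude_mean
  }, numeric(1))
  len <- vapply(divs, function(d) {
    get_preset(mp, paste0("DIV", d), "healthy")$total_length_mean
  }, numeric(1))
  pf <- stage_profiles(data.frame(div = divs, value = freq))
  pa <- stage_profiles(data.frame(div = divs, value = amp))
  pl <- stage_profiles(data.frame(div = divs, value = len))
  expect_lt(profile_correlation(pl, pf)$slope, 0)
  expect_gt(profile_correlation(pl, pa)$slope, 0)
})
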