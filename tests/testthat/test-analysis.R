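# Statistical readouts: segment ANOVA, paired comparisons, breakpoint
# detection, MAP regression -- all checked against hand-computed oracles.

test_that("segment ANOVA equals the textbook variance-ratio on a 9-point toy", {
  # three segments, three samples each, at hand-picked values
  prof <- gradient_profile(c(0, 1, 2, 4, 5, 6, 8, 9, 10),
                           c(2, 3, 4, 50, 52, 54, 90, 91, 95))
  res <- segment_summary(prof)
  # brute-force one-way ANOVA
  g <- list(c(2, 3, 4), c(50, 52, 54), c(90, 91, 95))
  grand <- mean(unlist(g))
  ss_b <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, numeric(1)))
  ss_w <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  F_oracle <- (ss_b / 2) / (ss_w / 6)
  expect_equal(res$statistic, F_oracle, tolerance = 1e-12)
  expect_equal(res$p_value, pf(F_oracle, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$groups$mean, vapply(g, mean, numeric(1)))
  expect_equal(res$groups$sd, vapply(g, sd, numeric(1)))
})

test_that("identical samples across segments give F = 0 and p = 1", {
  prof <- gradient_profile(c(0, 1, 2, 4, 5, 6, 8, 9, 10), rep(42, 9))
  res <- segment_summary(prof)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("segment summaries name an empty segment in their error", {
  prof <- gradient_profile(c(0, 1, 8, 9, 10), c(2, 3, 90, 91, 95))
  expect_error(segment_summary(prof), "watershed")
})

test_that("paired arc t-test equals the brute-force formula on a 4-pair toy", {
  # distances inside the perfused/watershed windows so all pairs are kept
  pm <- gradient_profile(c(4, 5, 8, 9), c(80, 82, 99, 101))
  pa <- gradient_profile(c(4, 5, 8, 9), c(70, 75, 85, 88))
  res <- compare_arcs(pm, pa)
  d <- c(80, 82, 99, 101) - c(70, 75, 85, 88)
  t_oracle <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(res$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_oracle), df = 3), tolerance = 1e-12)
  expect_true(res$paired)
  expect_equal(res$groups$mean, c(mean(pm$rpu), mean(pa$rpu)))
})

test_that("identical arc profiles give zero difference and p = 1", {
  p <- gradient_profile(c(4, 5, 8, 9, 10), c(80, 82, 99, 101, 100))
  res <- compare_arcs(p, p)
  expect_equal(res$estimate, 0)
  expect_equal(res$p_value, 1)
})

test_that("arc comparison needs at least 3 matched in-window points", {
  a <- gradient_profile(c(4, 8), c(1, 2))
  b <- gradient_profile(c(4, 8), c(2, 3))
  expect_error(compare_arcs(a, b), "matched")
  # matched distances only in the excluded gaps also fail
  a2 <- gradient_profile(c(2.5, 3, 6.5, 7), 1:4)
  expect_error(compare_arcs(a2, a2), "matched")
})

test_that("breakpoint search recovers a noiseless two-piece profile exactly", {
  d <- seq(2, 8, by = 0.5)
  y <- ifelse(d <= 4, 5 + 20 * (d - 2), 45 + 3 * (d - 4)) # break at 4.0
  onset <- detect_decline_onset(gradient_profile(d, y))
  expect_equal(as.numeric(onset), 4.0)
  sl <- attr(onset, "slopes")
  expect_equal(unname(sl["proximal"]), 20, tolerance = 1e-9)
  expect_equal(unname(sl["distal"]), 3, tolerance = 1e-9)
})

test_that("a linear profile yields no onset under the slope-ratio guard", {
  d <- seq(0, 10, by = 0.5)
  onset <- detect_decline_onset(gradient_profile(d, 5 + 9 * d))
  expect_true(is.na(onset))
  expect_error(detect_decline_onset(gradient_profile(c(1, 2, 3, 4), 1:4)),
               "6 samples")
})

test_that("onset search can be restricted to the declining span", {
  d <- seq(0, 10, by = 0.5)
  y <- ifelse(d <= 2, 2, ifelse(d <= 5, 2 + 27 * (d - 2),
       ifelse(d <= 8, 83 + 5 * (d - 5), 98)))
  onset <- detect_decline_onset(gradient_profile(d, y), span = c(2, 8))
  expect_equal(as.numeric(onset), 5.0)
})

test_that("MAP regression matches hand-computed OLS and R^2 on a toy table", {
  toy <- data.frame(map_mmHg = c(65, 55, 45, 35, 25),
                    rpu = c(95, 81, 60, 38, 22))
  res <- map_rpu_regression(toy)
  # brute-force OLS
  mx <- mean(toy$map_mmHg); my <- mean(toy$rpu)
  slope <- sum((toy$map_mmHg - mx) * (toy$rpu - my)) / sum((toy$map_mmHg - mx)^2)
  r2 <- cor(toy$map_mmHg, toy$rpu)^2
  expect_equal(res$slope, slope, tolerance = 1e-12)
  expect_equal(res$intercept, my - slope * mx, tolerance = 1e-12)
  expect_equal(res$r_squared, r2, tolerance = 1e-12)
})

test_that("collinear points give R^2 = 1 with the slope recovered exactly", {
  toy <- data.frame(map_mmHg = c(60, 50, 40), rpu = 7 + 1.5 * c(60, 50, 40))
  res <- map_rpu_regression(toy)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  expect_equal(res$slope, 1.5, tolerance = 1e-12)
  expect_error(map_rpu_regression(data.frame(map_mmHg = rep(50, 4), rpu = 1:4)),
               "variance")
})

test_that("anastomosis comparison reduces to arithmetic on the point sets", {
  am <- seq(82.2, 25.8, length.out = 10)
  m <- seq(61.5, 14.5, length.out = 10)
  res <- compare_anastomoses(am, m)
  expect_equal(res$groups$mean, c(mean(am), mean(m)))
  d <- am - m
  expect_equal(res$statistic, mean(d) / (sd(d) / sqrt(10)), tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)
  expect_error(compare_anastomoses(am, m[1:9]), "length")
  same <- compare_anastomoses(am, am)
  expect_equal(same$estimate, 0)
})

test_that("ANOVA p-values fall monotonically as segment separation grows", {
  set.seed(8)
  noise <- rnorm(15, 0, 3)
  p_at <- function(sep) {
    d <- c(0, 0.5, 1, 1.5, 2, 4, 4.5, 5, 5.5, 6, 8, 8.5, 9, 9.5, 10)
    mu <- rep(c(0, sep / 2, sep), each = 5)
    segment_summary(gradient_profile(d, mu + noise))$p_value
  }
  ps <- vapply(c(5, 15, 45), p_at, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("profiles validate ordering and matched lengths", {
  expect_error(gradient_profile(c(1, 1, 2), 1:3), "increasing")
  expect_error(gradient_profile(1:3, 1:2), "matching")
})
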