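test_that("sliding-window rates are exact on affine OD series", {
  times <- seq(0, 190, by = 10)
  flat <- growth_curve(times, rep(0.5, length(times)))
  expect_equal(sliding_window_rates(flat)$rate, rep(0, 11))

  # +0.01 OD per 10-minute step = 0.06 OD/h, in every window
  lin <- growth_curve(times, 0.1 + 0.01 * seq_along(times))
  r <- sliding_window_rates(lin)
  expect_equal(r$rate, rep(0.06, 11), tolerance = 1e-12)
  expect_equal(nrow(r), length(times) - 10 + 1)
  expect_equal(r$window_start[1], 0)

  # arbitrary affine series: slope recovered at machine precision
  aff <- growth_curve(times, 0.07 + 0.123 * times / 60)
  expect_equal(sliding_window_rates(aff)$rate, rep(0.123, 11), tolerance = 1e-12)
})

test_that("windowed rates match an independent per-window regression oracle", {
  times <- seq(0, 600, by = 10)
  od <- 1 / (1 + exp(-0.01 * (times - 300)))
  cv <- growth_curve(times, od)
  got <- sliding_window_rates(cv, window = 10)
  oracle <- vapply(seq_len(length(times) - 9), function(i) {
    idx <- i:(i + 9)
    unname(stats::coef(stats::lm(od[idx] ~ I(times[idx] / 60)))[2])
  }, numeric(1))
  expect_equal(got$rate, oracle, tolerance = 1e-12)
})

test_that("window preconditions and bad inputs raise explicit errors", {
  expect_error(growth_curve(c(0, 10, 5), c(1, 2, 3)), "strictly increasing")
  expect_error(growth_curve(c(0, 10), c(0.1, -0.2)), "non-negative")
  short <- growth_curve(seq(0, 40, 10), rep(0.2, 5))
  expect_error(sliding_window_rates(short, window = 10), "requires at least 10")
  expect_error(sliding_window_rates(short, window = 1), "at least 2")
})

test_that("windows containing missing readings are skipped, not imputed", {
  times <- seq(0, 300, by = 10)
  od <- 0.1 + 0.001 * times
  od[15] <- NA
  cv <- growth_curve(times, od)
  expect_message(r <- sliding_window_rates(cv), "skipped 10 window")
  expect_equal(nrow(r), (length(times) - 9) - 10)
  expect_true(all(is.finite(r$rate)))
})

test_that("maximal rate picks the steepest phase, earliest window on ties", {
  times <- seq(0, 990, by = 10)
  # flat, then linear rise at 0.3 OD/h, then flat
  od <- c(rep(0.1, 30), 0.1 + 0.05 * seq_len(40), rep(2.1, 30))
  cv <- growth_curve(times, od)
  fv <- max_growth_rate(cv)
  expect_equal(fv$rate, 0.05 * 6, tolerance = 1e-9)  # 0.05/10min = 0.3/h

  # dyadic increments at whole-hour sampling make every window slope exactly
  # 0.25, so the tie is exact and the earliest window must win
  tie <- growth_curve(seq(0, 19) * 60, 1 + 0.25 * seq(0, 19))
  fv2 <- max_growth_rate(tie, window = 4)
  expect_equal(fv2$rate, 0.25)
  expect_equal(fv2$window_start, 0)

  # appending a shallower post-plateau tail never changes the maximum
  times2 <- seq(0, 1190, by = 10)
  od2 <- c(od, 2.1 + 0.001 * seq_len(20))
  expect_equal(max_growth_rate(growth_curve(times2, od2))$rate, fv$rate)
})

test_that("noiseless logistic maxima track the analytic peak slope rK/4 and noisy maxima stay rank-faithful", {
  g0 <- gen_growth_curves(n_wells = 30, rate_range = c(0.05, 0.4), noise_sd = 0,
                          duration_min = 4320, seed = 101)
  est0 <- vapply(g0$curves, function(cv) max_growth_rate(cv)$rate, numeric(1))
  expect_true(all(abs(est0 - g0$truth$peak_slope) / g0$truth$peak_slope < 0.02))

  g1 <- gen_growth_curves(n_wells = 100, rate_range = c(0.05, 0.4),
                          noise_sd = 0.005, duration_min = 4320, seed = 102)
  est1 <- vapply(g1$curves, function(cv) max_growth_rate(cv)$rate, numeric(1))
  expect_gt(stats::cor(est1, g1$truth$peak_slope), 0.99)
})

test_that("log-OD and endpoint options behave as documented", {
  times <- seq(0, 300, by = 10)
  od <- 0.1 * exp(0.25 * times / 60)  # pure exponential, rate 0.25/h
  cv <- growth_curve(times, od)
  r_log <- sliding_window_rates(cv, log_od = TRUE)
  expect_equal(r_log$rate, rep(0.25, nrow(r_log)), tolerance = 1e-10)
  r_ep <- sliding_window_rates(growth_curve(times, 0.1 + 0.3 * times / 60),
                               method = "endpoint")
  expect_equal(r_ep$rate, rep(0.3, nrow(r_ep)), tolerance = 1e-12)
})

test_that("fitness improvement is the percent ratio change and needs a positive ancestor", {
  expect_equal(fitness_improvement(0.3, 0.3)$improvement_percent, 0)
  expect_equal(fitness_improvement(0.36, 0.3)$improvement_percent, 20)
  expect_equal(fitness_improvement(0.24, 0.3)$improvement_percent, -20)
  expect_error(fitness_improvement(0.3, 0), "positive")
  # strictly increasing in the evolved fitness
  imp <- vapply(seq(0.1, 0.5, 0.05),
                function(fx) fitness_improvement(fx, 0.3)$improvement_percent,
                numeric(1))
  expect_true(all(diff(imp) > 0))
})

test_that("Welch t test matches its closed form and handles degeneracy", {
  a <- c(1.1, 1.4, 0.9, 1.2)
  b <- c(2.0, 2.3, 1.8, 2.2, 2.1)
  got <- welch_t_one_tailed(a, b, alternative = "less")
  # closed-form Welch statistic and Welch-Satterthwaite df
  se2 <- var(a) / length(a) + var(b) / length(b)
  t_exp <- (mean(a) - mean(b)) / sqrt(se2)
  df_exp <- se2^2 / ((var(a) / length(a))^2 / (length(a) - 1) +
                     (var(b) / length(b))^2 / (length(b) - 1))
  expect_equal(got$t, t_exp, tolerance = 1e-12)
  expect_equal(got$df, df_exp, tolerance = 1e-12)
  expect_equal(got$p, stats::pt(t_exp, df_exp), tolerance = 1e-12)

  expect_equal(welch_t_one_tailed(a, a, "less")$p, 0.5)
  jitter <- c(1e-9, -1e-9, 2e-9, -2e-9)
  expect_lt(welch_t_one_tailed(0 + jitter, 1 + jitter, "less")$p, 1e-6)
  expect_error(welch_t_one_tailed(rep(1, 3), rep(2, 3)), "zero variance")
})

test_that("paired t test uses df = n_pairs - 1 and rejects degenerate pairs", {
  set.seed(5)
  x <- rnorm(8, 10, 1)
  y <- x - 1 + rnorm(8, 0, 0.01)  # differences ~ +1
  got <- paired_t_one_tailed(x, y, alternative = "greater")
  expect_equal(got$df, 7)
  expect_gt(got$t, 50)
  expect_lt(got$p, 1e-9)
  expect_error(paired_t_one_tailed(x, x), "zero variance")
  # two-column matrix input is equivalent
  expect_equal(paired_t_one_tailed(cbind(x, y), alternative = "greater"), got)
})

test_that("BH adjustment is the step-up procedure and permutation-stable", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(9)
  p <- runif(25)
  expect_true(all(bh_adjust(p) >= p))
  perm <- sample(25)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
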