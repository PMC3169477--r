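# Hand-computed closed forms are the oracles here: bias 4/3, SD sqrt(13/3),
# t = sqrt(2), r = 0.5 etc. are exact arithmetic on the listed short series.

test_that("bland_altman matches the three-pair hand computation exactly", {
  ba <- bland_altman(c(10, 20, 30), c(12, 19, 33))
  expect_equal(ba$bias, 4 / 3, tolerance = 1e-12)
  expect_equal(ba$sd_diff, sqrt(13 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_low, 4 / 3 - 1.96 * sqrt(13 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_high, 4 / 3 + 1.96 * sqrt(13 / 3), tolerance = 1e-12)
  expect_equal(tidy(ba)$diff, c(2, -1, 3))
  g <- glance(ba)
  expect_equal(g$n, 3L)
})

test_that("bland_altman identity, constant offset and antisymmetry", {
  x <- c(3, 1, 4, 1, 5)
  expect_message(ba0 <- bland_altman(x, x), "zero-variance")
  expect_identical(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  expect_message(ba5 <- bland_altman(x, x + 5), "zero-variance")
  expect_identical(c(ba5$bias, ba5$loa_low, ba5$loa_high), c(5, 5, 5))
  y <- c(2, 2, 5, 0, 7)
  ab <- bland_altman(x, y)
  ba <- bland_altman(y, x)
  expect_equal(ab$bias, -ba$bias, tolerance = 1e-15)
  expect_equal(ab$loa_low, -ba$loa_high, tolerance = 1e-15)
  expect_equal(ab$loa_high, -ba$loa_low, tolerance = 1e-15)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("correlation closed forms and affine invariance", {
  expect_equal(correlation(1:5, 2 * (1:5) + 1)$r, 1, tolerance = 1e-12)
  expect_equal(correlation(1:5, -(1:5))$r, -1, tolerance = 1e-12)
  expect_equal(correlation(c(1, 2, 3), c(1, 3, 2))$r, 0.5, tolerance = 1e-12)
  expect_equal(correlation(c(1, 2, 3), c(1, 3, 2))$r2, 0.25, tolerance = 1e-12)
  x <- c(1.2, 5.3, 2.2, 8.8, 4.1)
  y <- c(0.7, 4.9, 3.0, 7.7, 5.2)
  expect_equal(correlation(2.5 * x + 7, y)$r, correlation(x, y)$r,
               tolerance = 1e-12)
  expect_equal(correlation(x, 0.1 * y - 3)$r, correlation(x, y)$r,
               tolerance = 1e-12)
  expect_error(correlation(rep(1, 4), 1:4), "zero-variance")
})

test_that("paired_t matches the five-pair hand computation and degenerates", {
  x <- rep(0, 5)
  y <- c(2, -1, 3, 0, 1)
  tt <- paired_t(x, y)
  expect_equal(tt$t_stat, sqrt(2), tolerance = 1e-12)
  expect_equal(tt$df, 4)
  expect_false(tt$degenerate)
  expect_warning(t0 <- paired_t(1:4, 1:4), "t = 0")
  expect_identical(c(t0$t_stat, t0$p_value), c(0, 1))
  expect_true(t0$degenerate)
  expect_warning(ti <- paired_t(c(0, 0, 0, 0), c(1, 1, 1, 1)), "infinite")
  expect_identical(c(ti$t_stat, ti$p_value), c(Inf, 0))
})

test_that("observer differences: absolute and relative forms", {
  expect_equal(unlist(observer_differences(c(1, 2), c(1, 2))),
               c(mean_abs_diff = 0, mean_rel_diff = 0))
  od <- observer_differences(c(100, 200), c(110, 180))
  expect_equal(od$mean_abs_diff, 15)
  expect_equal(od$mean_rel_diff, 10)
  od1 <- observer_differences(50, 45)
  expect_equal(c(od1$mean_abs_diff, od1$mean_rel_diff), c(5, 10))
  expect_warning(odz <- observer_differences(c(0, 1), c(1, 1)), "zero")
  expect_equal(odz$mean_abs_diff, 0.5)
  expect_true(is.na(odz$mean_rel_diff))
})

test_that("percent bias vs truth: sign convention and summary", {
  pb <- percent_bias_vs_truth(c(22, 24), c(20, 25))
  expect_equal(pb$pct_bias, c(10, -4))
  bs <- bias_summary(c(22, 24), c(20, 25))
  expect_equal(bs$mean_pct, 3, tolerance = 1e-12)
  expect_equal(bs$sd_pct, sqrt(98), tolerance = 1e-12)  # 7*sqrt(2) ~ 9.90
  expect_equal(percent_bias_vs_truth(0.975 * c(10, 20), c(10, 20))$pct_bias,
               c(-2.5, -2.5), tolerance = 1e-12)
  expect_equal(percent_bias_vs_truth(c(5, 5), c(5, 5))$pct_bias, c(0, 0))
  expect_error(percent_bias_vs_truth(c(1, 2), c(1, 0)), "> 0")
})

test_that("agreement_stats assembles the combined report consistently", {
  x <- c(10, 20, 30, 40)
  y <- c(12, 19, 33, 41)
  g <- agreement_stats(x, y)
  expect_equal(g$bias, mean(y - x), tolerance = 1e-12)
  expect_equal(g$cv, 100 * sd(y - x) / mean(x), tolerance = 1e-12)
  expect_equal(g$r2, cor(x, y)^2, tolerance = 1e-12)
  # report rows survive CSV serialization losslessly
  f <- tempfile(fileext = ".csv")
  readr::write_csv(g, f)
  g2 <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(as.data.frame(g2), as.data.frame(g), tolerance = 1e-12)
})
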