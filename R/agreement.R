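# Agreement statistics for method-vs-truth and observer-vs-observer volume
# tables: Bland-Altman bias and 95% limits of agreement, Pearson correlation,
# paired t test, absolute/relative observer differences and signed percent
# bias versus a known truth. Sign convention throughout: difference =
# method - reference, so negative values mean underestimation.

#' Bland-Altman agreement analysis
#'
#' Differences are `d = y - x`; bias is `mean(d)`, `sd_diff` the sample SD
#' (n - 1 denominator), and the limits of agreement `bias +/- 1.96 * sd_diff`
#' (95% by convention; an exact-t multiplier for small n is available via
#' `exact_t = TRUE`).
#'
#' @param x Reference series.
#' @param y Comparison series (same length, n >= 2).
#' @param exact_t Use `qt(0.975, n - 1)` instead of 1.96 as the LoA
#'   multiplier (default `FALSE`).
#' @return An object of class `agreement_report`; see [tidy()] for the
#'   per-pair (mean, difference) table and [glance()] for the one-row summary.
#' @examples
#' ba <- bland_altman(c(10, 20, 30), c(12, 19, 33))
#' glance(ba)
#' @export
bland_altman <- function(x, y, exact_t = FALSE) {
  check_series(x, y, min_n = 2L)
  d <- y - x
  n <- length(d)
  bias <- mean(d)
  sdd <- sd(d)
  mult <- if (exact_t) stats::qt(0.975, n - 1) else 1.96
  zero_var <- sdd < 1e-12
  if (zero_var) {
    inform("bland_altman: zero-variance differences; limits of agreement collapse to the bias")
  }
  structure(
    list(n = n, bias = bias, sd_diff = sdd,
         loa_low = bias - mult * sdd, loa_high = bias + mult * sdd,
         loa_multiplier = mult, zero_variance = zero_var,
         pairs = tibble(mean = (x + y) / 2, diff = d)),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> n = %d\n  bias %.4g, SD of differences %.4g\n  95%% limits of agreement [%.4g, %.4g]\n",
    x$n, x$bias, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' @rdname bland_altman
#' @param object,... An `agreement_report`; further arguments ignored.
#' @export
tidy.agreement_report <- function(x, ...) x$pairs

#' @rdname bland_altman
#' @export
glance.agreement_report <- function(x, ...) {
  tibble(n = x$n, bias = x$bias, sd_diff = x$sd_diff,
         loa_low = x$loa_low, loa_high = x$loa_high,
         loa_multiplier = x$loa_multiplier)
}

#' @rdname bland_altman
#' @export
autoplot.agreement_report <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "mean of methods", y = "difference (method - reference)")
}

#' Pearson correlation between two series
#'
#' @param x,y Numeric series of equal length (n >= 3), both with non-zero
#'   variance.
#' @return A one-row tibble with `r` and `r2`.
#' @examples
#' correlation(1:5, 2 * (1:5) + 1)
#' @export
correlation <- function(x, y) {
  check_series(x, y, min_n = 3L)
  if (sd(x) < 1e-12 || sd(y) < 1e-12) {
    abort("correlation undefined for a zero-variance series")
  }
  r <- cor(x, y)
  tibble(r = r, r2 = r^2)
}

#' Two-sided paired t test
#'
#' Standard paired t on `d = y - x` with n - 1 degrees of freedom.
#' Zero-variance differences are handled explicitly: `t = 0, p = 1` when the
#' mean difference is also zero, infinite t with `p = 0` otherwise (both
#' flagged in the `degenerate` column).
#'
#' @param x,y Numeric series of equal length (n >= 2).
#' @return A one-row tibble with `t_stat`, `df`, `p_value`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  check_series(x, y, min_n = 2L)
  d <- y - x
  n <- length(d)
  if (sd(d) < 1e-12) {
    if (abs(mean(d)) < 1e-12) {
      warn("paired_t: identical series; t = 0, p = 1 by convention")
      return(tibble(t_stat = 0, df = n - 1, p_value = 1, degenerate = TRUE))
    }
    warn("paired_t: constant non-zero differences; t is infinite")
    return(tibble(t_stat = sign(mean(d)) * Inf, df = n - 1, p_value = 0,
                  degenerate = TRUE))
  }
  tt <- t.test(y, x, paired = TRUE)
  tibble(t_stat = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, degenerate = FALSE)
}

#' Absolute and relative differences between paired observations
#'
#' `mean_abs_diff = mean(|a - b|)`; `mean_rel_diff = 100 * mean(|a - b| / a)`
#' (the first series is the initial measurement).
#'
#' @param a Initial measurement series.
#' @param b Repeat measurement series (same length).
#' @return A one-row tibble with `mean_abs_diff` (input units) and
#'   `mean_rel_diff` (percent; `NA` with a warning when any `a` is zero).
#' @export
observer_differences <- function(a, b) {
  check_series(a, b, min_n = 1L)
  mad_ <- mean(abs(a - b))
  if (any(a == 0)) {
    warn("observer_differences: zero initial measurement; relative difference undefined")
    return(tibble(mean_abs_diff = mad_, mean_rel_diff = NA_real_))
  }
  tibble(mean_abs_diff = mad_, mean_rel_diff = 100 * mean(abs(a - b) / a))
}

#' Signed percent bias versus a known truth
#'
#' `100 * (measured - truth) / truth` per heart, with the mean +/- SD summary
#' used in method-accuracy tables (negative values mean underestimation).
#'
#' @param measured Measured series.
#' @param truth Ground-truth series (same length, all > 0).
#' @return A tibble with one row per pair (`measured`, `truth`, `pct_bias`)
#'   and the summary in attributes `mean_pct` / `sd_pct`; see
#'   [bias_summary()] for the one-row summary form.
#' @export
percent_bias_vs_truth <- function(measured, truth) {
  check_series(measured, truth, min_n = 1L)
  if (any(truth <= 0)) abort("truth values must be > 0")
  pb <- 100 * (measured - truth) / truth
  out <- tibble(measured = measured, truth = truth, pct_bias = pb)
  attr(out, "mean_pct") <- mean(pb)
  attr(out, "sd_pct") <- if (length(pb) > 1) sd(pb) else NA_real_
  out
}

#' @rdname percent_bias_vs_truth
#' @export
bias_summary <- function(measured, truth) {
  pb <- percent_bias_vs_truth(measured, truth)
  tibble(mean_pct = attr(pb, "mean_pct"), sd_pct = attr(pb, "sd_pct"),
         n = nrow(pb))
}

#' Full agreement report between a method and a reference
#'
#' Combines [bland_altman()], [correlation()], [paired_t()] and
#' [observer_differences()] into the one-row summary used for method
#' comparison tables. The coefficient of variation is
#' `100 * SD(differences) / mean(reference)`.
#'
#' @param x Reference series.
#' @param y Method series.
#' @return A one-row tibble: `n`, `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `r`, `r2`, `t_stat`, `p_value`, `mean_abs_diff`, `mean_rel_diff`, `cv`.
#' @export
agreement_stats <- function(x, y) {
  ba <- glance(bland_altman(x, y))
  co <- correlation(x, y)
  tt <- paired_t(x, y)
  od <- observer_differences(x, y)
  tibble(n = ba$n, bias = ba$bias, sd_diff = ba$sd_diff,
         loa_low = ba$loa_low, loa_high = ba$loa_high,
         r = co$r, r2 = co$r2, t_stat = tt$t_stat, p_value = tt$p_value,
         mean_abs_diff = od$mean_abs_diff, mean_rel_diff = od$mean_rel_diff,
         cv = 100 * ba$sd_diff / mean(x))
}

check_series <- function(x, y, min_n = 2L) {
  if (!is.numeric(x) || !is.numeric(y)) abort("series must be numeric")
  if (length(x) != length(y)) abort("series must have equal length")
  if (length(x) < min_n) {
    abort(sprintf("series must have at least %d elements", min_n))
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("series must be finite")
  }
  invisible(TRUE)
}
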