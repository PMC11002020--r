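# Method-agreement statistics: Bland-Altman limits of agreement, Lin's
# concordance correlation coefficient, Pearson correlation.

#' Bland-Altman agreement analysis
#'
#' Computes the paired differences `d = x - y`, their mean (bias), the
#' 95% limits of agreement `bias +/- 1.96 * sd(d)` (sample SD, n - 1
#' denominator), and a two-sided one-sample t-test of the bias against
#' zero.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), e.g. per-muscle
#'   mean T2w from two estimators.
#' @return A `bland_altman` object; `tidy()` returns the statistics as a
#'   one-row tibble (`loa_half_width` matches the "+/- x ms" form in
#'   which limits of agreement are usually quoted).
#' @examples
#' ba <- bland_altman(c(31, 33, 35), c(30, 31, 32))
#' tidy(ba)
#' @export
bland_altman <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3 pairs", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  p <- if (s == 0) as.numeric(bias != 0) else t.test(d)$p.value
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 loa_half_width = 1.96 * s, bias_p_value = p,
                 n = length(d), mean_xy = (x + y) / 2, diff = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.3f, LOA %.3f to %.3f (+/- %.3f), bias p = %.3g\n",
              x$n, x$bias, x$loa_low, x$loa_high, x$loa_half_width,
              x$bias_p_value))
  invisible(x)
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, loa_low = x$loa_low, loa_high = x$loa_high,
                 loa_half_width = x$loa_half_width,
                 bias_p_value = x$bias_p_value, n = x$n)
}

#' Lin's concordance correlation coefficient
#'
#' Agreement with the identity line:
#' `r_c = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`,
#' with population (1/n) moments as in the original definition (the
#' sample/population choice matters at small n, so it is fixed here).
#'
#' @param x,y Numeric vectors, equal length n >= 3, non-degenerate.
#' @return The concordance coefficient in \[-1, 1\].
#' @export
lin_ccc <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need n >= 3 pairs", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  vx <- mean((x - mean(x))^2); vy <- mean((y - mean(y))^2)
  if (vx == 0 || vy == 0) {
    stop("concordance undefined for zero-variance input", call. = FALSE)
  }
  cxy <- mean((x - mean(x)) * (y - mean(y)))
  2 * cxy / (vx + vy + (mean(x) - mean(y))^2)
}

#' Pearson correlation with significance test
#'
#' Standard product-moment correlation and its two-sided t-based p-value,
#' e.g. for checking that estimated T2w carries no residual dependence on
#' the fat fraction.
#'
#' @param x,y Numeric vectors, equal length n >= 3, non-degenerate.
#' @return One-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3 pairs", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("correlation undefined for zero-variance input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y)
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Compare two estimators' ROI values
#'
#' Convenience wrapper producing the full agreement summary used when
#' comparing T2w estimates from two fitting methods: Bland-Altman bias
#' and limits of agreement, Lin's concordance, and Pearson correlation.
#'
#' @param data Data frame holding the paired values.
#' @param a,b Column names (strings) of the two methods' values.
#' @return One-row tibble combining [bland_altman()], [lin_ccc()] and
#'   [pearson_corr()] results.
#' @export
agreement_stats <- function(data, a, b) {
  x <- data[[a]]; y <- data[[b]]
  ba <- tidy(bland_altman(x, y))
  pc <- pearson_corr(x, y)
  dplyr::mutate(ba, r_c = lin_ccc(x, y), pearson_r = pc$r,
                pearson_p = pc$p_value)
}

#' Bland-Altman plot
#'
#' @param object A [bland_altman()] object.
#' @param ... Unused.
#' @return A ggplot: paired means vs differences with bias and limits of
#'   agreement.
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tibble::tibble(m = object$mean_xy, d = object$diff)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$d)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, color = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", color = "firebrick") +
    ggplot2::labs(x = "Mean of methods", y = "Difference",
                  title = sprintf("Bias %.2f, LOA +/- %.2f", object$bias,
                                  object$loa_half_width)) +
    ggplot2::theme_minimal()
}
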