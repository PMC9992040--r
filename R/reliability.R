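#' Bland-Altman agreement analysis of paired measurements
#'
#' Computes the mean difference, the sample SD of the differences, the 95%
#' limits of agreement `mean +/- 1.96 * SD`, the coefficient of repeatability
#' `CoR = 1.96 * SD` (the bound below which 95% of absolute test-retest
#' differences are expected to fall), CoR as a percentage of the mean
#' measured value, and the derived coefficient of variation `CV = CoR / 1.96`
#' (as a percentage). Optionally adds the paired t-test and intraclass
#' correlation for the same pair.
#'
#' @param x,y Paired measurement vectors (scan 1, scan 2), equal length
#'   `n >= 2`, pairwise complete.
#' @param outcome Label for the measured quantity.
#' @param with_icc Also compute the ICC (needs `n >= 3`).
#' @return An object of class `agreement_report`: list with `outcome`,
#'   `n_pairs`, `mean_measurement`, `mean_difference`, `sd_difference`,
#'   `loa_low`, `loa_high`, `cor`, `cor_pct`, `cv_pct`, `t_statistic`,
#'   `p_value`, `icc`, `icc_model`, and the paired data.
#' @export
bland_altman <- function(x, y, outcome = "measurement", with_icc = TRUE) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 2) stop("at least 2 complete pairs required", call. = FALSE)
  d <- x - y
  md <- mean(d)
  sdd <- stats::sd(d)                    # n - 1 denominator
  mm <- mean((x + y) / 2)
  cor_ <- 1.96 * sdd
  cor_pct <- if (mm != 0) 100 * cor_ / mm else NA_real_
  tt <- paired_ttest(x, y)
  icc_val <- NA_real_; icc_model <- NA_character_
  if (with_icc && n >= 3) {
    icc_val <- tryCatch(icc(x, y), error = function(e) NA_real_)
    icc_model <- "two-way mixed, absolute agreement, single measures (ICC(A,1))"
  }
  structure(list(
    outcome = outcome, n_pairs = n,
    mean_measurement = mm, mean_difference = md, sd_difference = sdd,
    loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd,
    cor = cor_, cor_pct = cor_pct,
    cv_pct = if (is.na(cor_pct)) NA_real_ else cv_from_cor(cor_pct),
    t_statistic = tt$t_statistic, p_value = tt$p_value,
    icc = icc_val, icc_model = icc_model,
    data = tibble::tibble(x = x, y = y)
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("<agreement_report> ", x$outcome, " (n = ", x$n_pairs, ")\n", sep = "")
  cat(sprintf("  mean diff %.4g, SD %.4g, LoA [%.4g, %.4g]\n",
              x$mean_difference, x$sd_difference, x$loa_low, x$loa_high))
  cat(sprintf("  CoR %.4g (%s%% of mean %.4g), CV %.4g%%\n", x$cor,
              ifelse(is.na(x$cor_pct), "NA", format(round(x$cor_pct))),
              x$mean_measurement, x$cv_pct))
  if (!is.na(x$icc)) cat(sprintf("  ICC %.3f, paired t = %.3f (p = %.3g)\n",
                                 x$icc, x$t_statistic, x$p_value))
  invisible(x)
}

#' @rdname bland_altman
#' @param x An `agreement_report` (for `tidy`/`glance`).
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.agreement_report <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, n_pairs = x$n_pairs,
    mean_measurement = x$mean_measurement,
    mean_difference = x$mean_difference, sd_difference = x$sd_difference,
    loa_low = x$loa_low, loa_high = x$loa_high,
    cor = x$cor, cor_pct = x$cor_pct, cv_pct = x$cv_pct,
    t_statistic = x$t_statistic, p_value = x$p_value, icc = x$icc
  )
}

#' @rdname bland_altman
#' @exportS3Method generics::tidy
tidy.agreement_report <- function(x, ...) {
  dplyr::mutate(x$data, mean = (.data$x + .data$y) / 2,
                difference = .data$x - .data$y)
}

#' Bland-Altman plot
#' @param object An `agreement_report`.
#' @param ... Unused.
#' @return A ggplot: pairwise means vs differences with the mean difference
#'   (solid) and 95% limits of agreement (dashed).
#' @exportS3Method ggplot2::autoplot
autoplot.agreement_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$mean_difference, linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of pair", y = "Difference",
                  title = paste0("Bland-Altman: ", object$outcome),
                  subtitle = sprintf("CoR = %.3g (%.0f%% of mean)",
                                     object$cor, object$cor_pct)) +
    ggplot2::theme_minimal()
}

#' Construct paired vectors with exact summary moments
#'
#' Builds `n` pairs whose difference has exactly the requested mean and
#' sample SD and whose pairwise means average exactly to `mean_measurement`.
#' Useful for re-deriving Bland-Altman quantities (LoA, CoR, CoR%) from
#' published summary statistics.
#'
#' @param n Number of pairs (>= 2).
#' @param mean_difference,sd_difference Target moments of `x - y`.
#' @param mean_measurement Target mean of `(x + y) / 2`.
#' @return Tibble with columns `x`, `y`.
#' @export
paired_from_stats <- function(n, mean_difference, sd_difference,
                              mean_measurement) {
  stopifnot(n >= 2, sd_difference >= 0)
  z <- seq_len(n) - (n + 1) / 2            # mean 0 by symmetry
  z <- z / stats::sd(z)                    # sample SD exactly 1
  d <- mean_difference + sd_difference * z
  m <- rep(mean_measurement, n)
  tibble::tibble(x = m + d / 2, y = m - d / 2)
}

#' Dice overlap coefficient of two binary masks
#'
#' `DC(A, B) = 2|A intersect B| / (|A| + |B|)`: 1 for identical nonempty
#' masks, 0 for disjoint ones.
#'
#' @param mask_a,mask_b Logical matrices of the same shape, not both empty.
#' @return List of class `dice_result`: `dice`, `size_a`, `size_b`,
#'   `intersection`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b))) {
    stop("masks must have the same shape", call. = FALSE)
  }
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) stop("Dice undefined: both masks are empty", call. = FALSE)
  inter <- sum(a & b)
  structure(list(dice = 2 * inter / (na + nb), size_a = na, size_b = nb,
                 intersection = inter), class = "dice_result")
}

#' @export
print.dice_result <- function(x, ...) {
  cat(sprintf("<dice_result> DC = %.4f (|A| = %d, |B| = %d, |A&B| = %d)\n",
              x$dice, x$size_a, x$size_b, x$intersection))
  invisible(x)
}

#' Intraclass correlation for a test-retest pair
#'
#' Single-measurement ICC from the two-way ANOVA mean squares over subjects
#' (rows) and measurements (columns). The default, absolute agreement
#' (ICC(A,1), the standard test-retest choice), penalizes systematic offsets
#' between measurements:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with `k = 2`.
#' The consistency variant ICC(C,1) omits the column-variance term.
#'
#' @param x,y Paired measurements, equal length `n >= 3`.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return Scalar ICC.
#' @export
icc <- function(x, y, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3) stop("at least 3 complete pairs required", call. = FALSE)
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_m <- rowMeans(dat); col_m <- colMeans(dat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((dat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- switch(type,
    agreement = msr + (k - 1) * mse + (k / n) * (msc - mse),
    consistency = msr + (k - 1) * mse
  )
  if (denom == 0) stop("ICC undefined: zero total variance", call. = FALSE)
  (msr - mse) / denom
}

#' Paired Student's t-test
#'
#' Standard paired t on the differences with two-sided p from the
#' t-distribution on `n - 1` degrees of freedom. Degenerate cases are
#' resolved explicitly: identical vectors give `t = 0, p = 1` by convention;
#' a nonzero mean difference with zero SD gives `t = +/-Inf, p = 0` with a
#' flag.
#'
#' @param x,y Paired vectors, equal length `n >= 2`.
#' @return List: `t_statistic`, `p_value`, `df`, `mean_difference`,
#'   `degenerate` (TRUE when the difference SD is zero).
#' @export
paired_ttest <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 2) stop("at least 2 complete pairs required", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t_statistic = 0, p_value = 1, df = n - 1,
                  mean_difference = 0, degenerate = TRUE))
    }
    return(list(t_statistic = sign(mean(d)) * Inf, p_value = 0, df = n - 1,
                mean_difference = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_difference = unname(tt$estimate),
       degenerate = FALSE)
}

#' Coefficient of variation from the coefficient of repeatability
#'
#' `CV = CoR / 1.96`, both expressed as percentages of the mean measurement.
#'
#' @param cor_pct CoR as a percentage of the mean (>= 0).
#' @return CV percentage.
#' @export
cv_from_cor <- function(cor_pct) {
  stopifnot(all(cor_pct >= 0))
  cor_pct / 1.96
}

#' Two-group sample size for a relative increase in a mean
#'
#' Total subjects needed to detect a `pct_increase` relative difference in a
#' group mean with a two-sample t-test. The default normal approximation uses
#' `n_per_group = ceiling(2 * (z_{1-alpha/2} + z_{power})^2 * (sd/delta)^2)`
#' with `delta = baseline_mean * pct_increase`; `method = "t"` instead
#' solves the exact noncentral-t power equation ([stats::power.t.test()]),
#' which returns slightly larger groups.
#'
#' @param baseline_mean Control-group mean of the outcome.
#' @param sd Common SD of the outcome.
#' @param pct_increase Relative increase to detect (0.5 = 50%).
#' @param power Target power in (0, 1).
#' @param alpha Two-sided significance level in (0, 1).
#' @param method `"normal"` (default) or `"t"`.
#' @return List: `n_total`, `n_per_group`, `delta`, `method`.
#' @export
sample_size_two_group <- function(baseline_mean, sd, pct_increase,
                                  power = 0.8, alpha = 0.05,
                                  method = c("normal", "t")) {
  method <- match.arg(method)
  stopifnot(baseline_mean > 0, sd > 0, pct_increase > 0,
            power > 0, power < 1, alpha > 0, alpha < 1)
  delta <- baseline_mean * pct_increase
  if (delta == 0) stop("effect size is zero", call. = FALSE)
  n_per <- if (method == "normal") {
    ceiling(2 * ((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) *
                   sd / delta)^2)
  } else {
    ceiling(stats::power.t.test(delta = delta, sd = sd, sig.level = alpha,
                                power = power)$n)
  }
  list(n_total = 2L * as.integer(n_per), n_per_group = as.integer(n_per),
       delta = delta, method = method)
}
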