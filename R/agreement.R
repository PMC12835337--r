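# Agreement statistics for validating estimated gait parameters against a
# reference system: Bland-Altman bias and limits of agreement, Pearson
# correlation, two-way mixed-model intraclass correlation (consistency form),
# paired t-test with Cohen's d, mean absolute error and the normal-theory 95%
# confidence interval of the bias. Differences are oriented reference minus
# estimate throughout.

#' Bland-Altman bias and limits of agreement
#'
#' @param ref,est Paired measurements (equal length, at least 3).
#' @return List with `bias` (mean of `ref - est`), `sd_diff` (sample SD,
#'   n - 1), and `loa` (length-2: bias -/+ 1.96 sd).
#' @export
bland_altman <- function(ref, est) {
  if (length(ref) != length(est)) stop("ref and est must have equal length")
  if (length(ref) < 3) stop("need at least 3 pairs")
  d <- ref - est
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  list(bias = bias, sd_diff = sd_diff,
       loa = c(bias - 1.96 * sd_diff, bias + 1.96 * sd_diff))
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length (n >= 3) with non-zero
#'   variance.
#' @return Correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(x, y)
}

#' Intraclass correlation, two-way mixed model, consistency
#'
#' Computes ICC(3,1) for single ratings and ICC(3,k) for the mean of the k
#' ratings from the two-way ANOVA mean squares: with `BMS` the
#' between-subject and `EMS` the residual mean square,
#' `ICC(3,1) = (BMS - EMS) / (BMS + (k - 1) EMS)` and
#' `ICC(3,k) = (BMS - EMS) / BMS`.
#'
#' @param ratings n-by-k numeric matrix (n subjects, k raters/methods), no
#'   missing cells.
#' @param form `"3,1"` or `"3,k"`.
#' @return The requested ICC value.
#' @export
icc <- function(ratings, form = c("3,1", "3,k")) {
  form <- match.arg(form)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3 || k < 2) stop("need at least 3 subjects and 2 raters")
  if (anyNA(ratings)) stop("missing cells are not supported")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  bms <- ss_rows / (n - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  if (form == "3,1") (bms - ems) / (bms + (k - 1) * ems) else (bms - ems) / bms
}

#' Paired t-test and Cohen's d on two error series
#'
#' Tests whether two methods' error series differ systematically: paired t
#' on `err_a - err_b`, with `d = mean(err_a - err_b) / sd(err_a - err_b)`.
#'
#' @param err_a,err_b Paired error series (equal length, n >= 3).
#' @return List with `t`, `p`, `d` and `df`.
#' @export
paired_t_and_cohens_d <- function(err_a, err_b) {
  if (length(err_a) != length(err_b)) stop("series must have equal length")
  if (length(err_a) < 3) stop("need at least 3 pairs")
  d <- err_a - err_b
  if (stats::sd(d) == 0) {
    if (all(d == 0)) return(list(t = 0, p = 1, d = 0, df = length(d) - 1))
    stop("zero variance of paired differences: t undefined")
  }
  tt <- stats::t.test(err_a, err_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       d = mean(d) / stats::sd(d), df = unname(tt$parameter))
}

#' Full agreement report between a reference and an estimate
#'
#' @param ref,est Paired measurements of one gait parameter.
#' @return An object of class `agreement_report`: list with `n`, `bias`,
#'   `sd_diff`, `mae`, `loa_low`, `loa_high`, `ci95` (bias +/- 1.96 SE),
#'   `pearson_r`, `icc_3_1`, `icc_3k`, `t_stat`, `p_value`, `cohens_d` and
#'   `shapiro_p` (normality of the differences, informational only).
#' @export
agreement_report <- function(ref, est) {
  ba <- bland_altman(ref, est)
  n <- length(ref)
  d <- ref - est
  se <- ba$sd_diff / sqrt(n)
  r <- tryCatch(pearson_r(ref, est), error = function(e) NA_real_)
  m <- cbind(ref, est)
  i31 <- tryCatch(icc(m, "3,1"), error = function(e) NA_real_)
  i3k <- tryCatch(icc(m, "3,k"), error = function(e) NA_real_)
  tt <- tryCatch(stats::t.test(ref, est, paired = TRUE),
                 error = function(e) NULL)
  sw <- tryCatch(stats::shapiro.test(d)$p.value, error = function(e) NA_real_)
  structure(list(
    n = n, bias = ba$bias, sd_diff = ba$sd_diff, mae = mean(abs(d)),
    loa_low = ba$loa[1], loa_high = ba$loa[2],
    ci95 = c(ba$bias - 1.96 * se, ba$bias + 1.96 * se),
    pearson_r = r, icc_3_1 = i31, icc_3k = i3k,
    t_stat = if (is.null(tt)) NA_real_ else unname(tt$statistic),
    p_value = if (is.null(tt)) NA_real_ else tt$p.value,
    cohens_d = if (stats::sd(d) > 0) mean(d) / stats::sd(d) else 0,
    shapiro_p = sw
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n=%d\n", x$n))
  cat(sprintf("  bias (ref-est) %.4f +/- %.4f (95%% CI %.4f to %.4f)\n",
              x$bias, x$sd_diff, x$ci95[1], x$ci95[2]))
  cat(sprintf("  MAE %.4f; LoA [%.4f, %.4f]\n", x$mae, x$loa_low, x$loa_high))
  cat(sprintf("  r=%.3f  ICC(3,1)=%.3f  ICC(3,k)=%.3f  t=%.2f (p=%.3g)\n",
              x$pearson_r, x$icc_3_1, x$icc_3k, x$t_stat, x$p_value))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param report An `agreement_report`.
#' @param ref,est The paired measurements used to build it.
#' @param main Plot title.
#' @return Invisibly, the report.
#' @export
plot_bland_altman <- function(report, ref, est, main = "Bland-Altman") {
  means <- (ref + est) / 2
  d <- ref - est
  graphics::plot(means, d, pch = 19, col = "grey30",
                 xlab = "Mean of methods", ylab = "Difference (ref - est)",
                 main = main)
  graphics::abline(h = report$bias, lwd = 2)
  graphics::abline(h = c(report$loa_low, report$loa_high), lty = 2)
  invisible(report)
}
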