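## Reliability and concurrent-validity statistics: absolute-agreement ICC
## with F-based confidence intervals, Bland-Altman bias and limits of
## agreement, Pearson correlation, and the root-mean-square between-method
## coefficient of variation.

#' Absolute-agreement intraclass correlation, ICC(A,1)
#'
#' Two-way random-effects, single-measure, absolute-agreement ICC from the
#' two-way ANOVA mean squares (subjects x sessions), with the F-based 95%
#' confidence interval. A two-way mixed consistency variant, ICC(3,1), is
#' available for sensitivity analyses.
#'
#' @param a,b Paired measurements (one value per subject), equal length,
#'   at least 3 subjects.
#' @param type `"A1"` (absolute agreement, default) or `"C1"` (consistency).
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `icc`, `ci` (length-2 vector), `type` and the mean
#'   squares `msr`, `msc`, `mse`. `icc` is `NA` (with a warning) when the
#'   data carry no variance at all.
#' @export
icc_absolute <- function(a, b, type = c("A1", "C1"), conf_level = 0.95) {
  type <- match.arg(type)
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 3) stop("at least 3 subjects are required", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("non-finite values in input", call. = FALSE)
  x <- cbind(a, b)
  k <- 2
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (sst == 0) {
    warning("zero total variance: ICC undefined")
    return(list(icc = NA_real_, ci = c(NA_real_, NA_real_), type = type,
                msr = msr, msc = msc, mse = mse))
  }
  alpha <- 1 - conf_level
  if (type == "A1") {
    icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
    # F-based interval (McGraw & Wong) with Satterthwaite denominator df
    aa <- k * icc / (n * (1 - icc))
    bb <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (aa * msc + bb * mse)^2 /
      ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    f <- msr / mse
    fl <- f / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  }
  list(icc = icc, ci = c(lo, hi), type = type,
       msr = msr, msc = msc, mse = mse)
}

#' Qualitative ICC category
#'
#' Maps an ICC to poor (< 0.40), fair (0.40 to < 0.60), good (0.60 to
#' < 0.75) or excellent (>= 0.75).
#'
#' @param icc A finite ICC value.
#' @return One of `"poor"`, `"fair"`, `"good"`, `"excellent"`.
#' @export
icc_category <- function(icc) {
  stopifnot(is.finite(icc))
  if (icc < 0.40) "poor"
  else if (icc < 0.60) "fair"
  else if (icc < 0.75) "good"
  else "excellent"
}

#' Bland-Altman agreement analysis
#'
#' Differences are `d = a - b`; bias is their mean, the 95% limits of
#' agreement are `bias +/- 1.96 sd(d)` (sample SD), and the bias is tested
#' against zero with a two-sided paired t-test. Per-subject
#' (mean, difference) pairs are returned for plotting.
#'
#' @param a,b Paired measurements, equal length, n >= 2.
#' @return A list with `bias`, `loa` (low, high), `t_p` (`NA` when the
#'   differences have zero variance), and `points` (data frame with
#'   columns `mean`, `diff`).
#' @export
bland_altman <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  t_p <- if (s == 0) NA_real_ else t.test(a, b, paired = TRUE)$p.value
  list(bias = bias, loa = c(bias - 1.96 * s, bias + 1.96 * s), t_p = t_p,
       points = data.frame(mean = (a + b) / 2, diff = d))
}

#' Bland-Altman plot
#'
#' Scatter of per-subject differences against means with the bias and 95%
#' limits-of-agreement lines.
#'
#' @param a,b Paired measurements.
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
bland_altman_plot <- function(a, b, xlab = "Mean of methods",
                              ylab = "Difference (a - b)") {
  ba <- bland_altman(a, b)
  ggplot2::ggplot(ba$points, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$bias, linetype = "solid") +
    ggplot2::geom_hline(yintercept = ba$loa, linetype = "dashed") +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}

#' Pearson correlation and its square
#'
#' @param a,b Paired measurements, n >= 3, non-zero variance in both.
#' @return A list with `r` and `r2`.
#' @export
pearson_agreement <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (sd(a) == 0 || sd(b) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  r <- cor(a, b)
  list(r = r, r2 = r^2)
}

#' Root-mean-square between-method coefficient of variation
#'
#' Per subject, the CV of the two paired values (two-point sample SD
#' `|a - b| / sqrt(2)` over their mean, x 100); the result is the square
#' root of the mean squared CV across subjects. Subjects whose pair mean is
#' zero are excluded with a warning.
#'
#' @param a,b Paired measurements.
#' @return CV%RMS, in percent.
#' @export
cv_rms <- function(a, b) {
  stopifnot(length(a) == length(b))
  m <- (a + b) / 2
  zero <- m == 0
  if (any(zero)) {
    warning(sprintf("%d subject(s) with zero pair mean excluded", sum(zero)))
    a <- a[!zero]; b <- b[!zero]; m <- m[!zero]
  }
  if (!length(m)) return(NA_real_)
  cv <- abs(a - b) / sqrt(2) / m * 100
  sqrt(mean(cv^2))
}

#' Full agreement battery for one outcome
#'
#' Combines Bland-Altman, Pearson, absolute-agreement ICC with category,
#' and CV%RMS into one result row.
#'
#' @param a,b Paired measurements.
#' @param conf_level Confidence level for the ICC interval.
#' @return A list of class `agreement_result`.
#' @export
agreement_summary <- function(a, b, conf_level = 0.95) {
  ba <- bland_altman(a, b)
  pr <- tryCatch(pearson_agreement(a, b),
                 error = function(e) list(r = NA_real_, r2 = NA_real_))
  ic <- suppressWarnings(icc_absolute(a, b, conf_level = conf_level))
  structure(list(
    n = length(a),
    bias = ba$bias, loa_low = ba$loa[1], loa_high = ba$loa[2], t_p = ba$t_p,
    r = pr$r, r2 = pr$r2,
    icc = ic$icc, icc_ci = ic$ci,
    icc_category = if (is.finite(ic$icc)) icc_category(ic$icc) else NA_character_,
    cv_rms_pct = suppressWarnings(cv_rms(a, b))),
    class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "n = %d  bias = %.4g [LoA %.4g, %.4g]  r2 = %.3f\nICC = %.3f (%.3f-%.3f, %s)  CV%%RMS = %.2f\n",
    x$n, x$bias, x$loa_low, x$loa_high, x$r2,
    x$icc, x$icc_ci[1], x$icc_ci[2], x$icc_category, x$cv_rms_pct))
  invisible(x)
}

#' Per-scale correlation of entropy with a reference variability measure
#'
#' For each coarseness scale, the Pearson correlation (and its p-value)
#' between subjects' entropy at that scale and a per-subject reference
#' (e.g. force-plate stride-duration SD). Missing values are excluded
#' pairwise.
#'
#' @param entropy_by_subject Numeric matrix, subjects in rows, scales in
#'   columns.
#' @param ref_sd Numeric vector, one reference value per subject.
#' @return A data frame with columns `scale`, `r`, `p`.
#' @export
scale_correlations <- function(entropy_by_subject, ref_sd) {
  stopifnot(nrow(entropy_by_subject) == length(ref_sd))
  res <- lapply(seq_len(ncol(entropy_by_subject)), function(s) {
    e <- entropy_by_subject[, s]
    ok <- is.finite(e) & is.finite(ref_sd)
    if (sum(ok) < 3) return(data.frame(scale = s, r = NA_real_, p = NA_real_))
    ct <- cor.test(e[ok], ref_sd[ok])
    data.frame(scale = s, r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, res)
}
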