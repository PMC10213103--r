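#' Two-way mixed-effects intraclass correlation, absolute agreement
#'
#' Computes ICC(A,1) (single measures) or ICC(A,k) (average measures) from
#' the two-way ANOVA decomposition of an n-subject by k-rater matrix:
#' \deqn{ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))}
#' \deqn{ICC(A,k) = (MSR - MSE) / (MSR + (MSC - MSE)/n)}
#' where MSR, MSC and MSE are the rows (subjects), columns (raters) and
#' residual mean squares. Confidence bounds use the F-distribution method of
#' the McGraw-Wong/Koo-Li guideline: a Satterthwaite-approximated F for the
#' single-measures form, with the average-measures bounds obtained from them
#' by the Spearman-Brown step-up. A matrix with all cells identical returns
#' ICC 1 with degenerate interval [1, 1].
#'
#' @param data numeric matrix, n subjects (rows) x k raters (columns),
#'   n >= 2, k >= 2, no missing cells.
#' @param form `"single"` for ICC(A,1) or `"average"` for ICC(A,k).
#' @param conf confidence level (default 0.95).
#' @return An object of class `icc_result`: fields `icc`, `ci_low`,
#'   `ci_high`, `form`, `agreement`, `msr`, `msc`, `mse`, `n`, `k`,
#'   `degenerate`.
#' @examples
#' icc_absolute(matrix(c(1, 3, 5, 7, 2, 4, 6, 8), ncol = 2), "single")
#' @export
icc_absolute <- function(data, form = c("single", "average"), conf = 0.95) {
  form <- match.arg(form)
  data <- as.matrix(data)
  n <- nrow(data); k <- ncol(data)
  if (n < 2L || k < 2L)
    stop("icc_absolute: need at least 2 subjects and 2 raters")
  if (anyNA(data) || !all(is.finite(data)))
    stop("icc_absolute: matrix must be complete and finite")
  grand <- mean(data)
  rmeans <- rowMeans(data)
  cmeans <- colMeans(data)
  msr <- k * sum((rmeans - grand)^2) / (n - 1)
  msc <- n * sum((cmeans - grand)^2) / (k - 1)
  resid <- data - outer(rmeans, rep(1, k)) -
    outer(rep(1, n), cmeans) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  degenerate <- (msr + msc + mse) <= .Machine$double.eps * max(1, grand^2)
  if (degenerate) {
    return(new_icc_result(1, 1, 1, form, msr, msc, mse, n, k,
                          degenerate = TRUE))
  }
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  icck <- (msr - mse) / (msr + (msc - mse) / n)
  alpha <- 1 - conf
  ci1 <- icc_a1_ci(icc1, msr, msc, mse, n, k, alpha)
  if (form == "single") {
    new_icc_result(icc1, ci1[1], ci1[2], form, msr, msc, mse, n, k)
  } else {
    sb <- function(r) {
      r <- pmin(r, 1)
      k * r / (1 + (k - 1) * r)
    }
    new_icc_result(icck, sb(ci1[1]), sb(ci1[2]), form, msr, msc, mse, n, k)
  }
}

# F-based bounds for ICC(A,1) with Satterthwaite degrees of freedom
icc_a1_ci <- function(icc1, msr, msc, mse, n, k, alpha) {
  if (1 - icc1 < 1e-12 || (msc <= 0 && mse <= 0)) {
    # no rater or residual variance: interval collapses at the estimate
    return(c(icc1, icc1))
  }
  a <- k * icc1 / (n * (1 - icc1))
  b <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
  num <- (a * msc + b * mse)^2
  den <- (a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1))
  # clamp the Satterthwaite df: above ~1e6 the F quantile is at its limit,
  # below 1 there is essentially no residual information and the quantile
  # solver destabilises; in both regimes the interval is already extreme
  v <- if (den > 0) num / den else 1e6
  v <- min(max(v, 1), 1e6)
  f1 <- stats::qf(1 - alpha / 2, n - 1, v)
  f2 <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f1 * mse) /
    (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f2 * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f2 * msr)
  c(max(-1, min(lo, icc1)), min(1, max(hi, icc1)))
}

new_icc_result <- function(icc, lo, hi, form, msr, msc, mse, n, k,
                           degenerate = FALSE) {
  structure(list(icc = icc, ci_low = lo, ci_high = hi, form = form,
                 agreement = "absolute", msr = msr, msc = msc, mse = mse,
                 n = n, k = k, degenerate = degenerate),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "ICC(A,%s) = %.4f, 95%% CI [%.4f, %.4f] (n = %d subjects, k = %d raters%s)\n",
    if (x$form == "single") "1" else "k", x$icc, x$ci_low, x$ci_high,
    x$n, x$k, if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Reliability classification of an ICC result
#'
#' Applies the study's reliability index: a feature is `robust` when
#' ICC > 0.8 and the lower 95% confidence bound > 0.7, `reliable` when
#' ICC > 0.8 (but the bound fails), otherwise `not_reliable`. Inequalities
#' are strict, so ICC = 0.8 exactly is not reliable.
#'
#' @param result an [icc_absolute()] result, or a numeric ICC estimate.
#' @param ci_low lower confidence bound (when `result` is numeric).
#' @return One of `"not_reliable"`, `"reliable"`, `"robust"`.
#' @examples
#' classify_reliability(0.85, 0.75)  # robust
#' classify_reliability(0.85, 0.65)  # reliable
#' classify_reliability(0.80, 0.75)  # not_reliable (strict >)
#' @export
classify_reliability <- function(result, ci_low = NULL) {
  if (inherits(result, "icc_result")) {
    icc <- result$icc
    ci_low <- result$ci_low
  } else {
    icc <- result
    if (is.null(ci_low)) stop("classify_reliability: ci_low required")
  }
  if (!is.finite(icc) || !is.finite(ci_low)) return("not_reliable")
  if (icc > 0.8 && ci_low > 0.7) "robust"
  else if (icc > 0.8) "reliable"
  else "not_reliable"
}
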