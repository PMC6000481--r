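#' ICC(3,1): two-way mixed, single-measure, consistency
#'
#' The Shrout-Fleiss ICC(3,1) for an n-subjects x k-sessions ratings matrix:
#' subjects are random, sessions fixed, agreement is in the consistency
#' sense (a constant shift between sessions does not reduce it). With MSR
#' the between-subject and MSE the residual mean square of the two-way
#' ANOVA (subjects x sessions),
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE).}
#' The confidence interval comes from the F ratio \eqn{F = MSR/MSE} with
#' degrees of freedom \eqn{n-1} and \eqn{(n-1)(k-1)}:
#' \eqn{F_L = F / F_{1-\alpha/2}(n-1, (n-1)(k-1))},
#' \eqn{F_U = F \cdot F_{1-\alpha/2}((n-1)(k-1), n-1)}, each mapped through
#' \eqn{(F-1)/(F+k-1)}.
#'
#' Perfect consistency (MSE = 0 with subject variance present) returns
#' ICC 1 with a degenerate [1, 1] interval. A constant matrix has no
#' variance to apportion and is an error.
#'
#' @param m Numeric matrix or data.frame, subjects in rows, sessions in
#'   columns; complete, n >= 2, k >= 2.
#' @param alpha Two-sided level; default 0.05 gives a 95% CI.
#' @return An `icc31` object: list with `icc`, `ciLow`, `ciHigh`, `msr`,
#'   `mse`, `msc` (session mean square), `n`, `k`, `alpha`.
#' @export
#' @examples
#' icc31(rbind(c(1, 2), c(2, 4), c(3, 6)))  # icc 0.8
icc31 <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("ratings matrix must be complete (no missing cells)")
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 subjects and 2 sessions")
  grand <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  tol <- 1e-12 * max(sst, 1)
  if (msr <= tol && mse <= tol)
    stop("constant ratings matrix: ICC undefined (no variance)")
  if (mse <= tol) {
    icc <- 1; ci <- c(1, 1)
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    f <- msr / mse
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fl <- f / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  structure(list(icc = icc, ciLow = ci[1L], ciHigh = ci[2L],
                 msr = msr, mse = mse, msc = msc, n = n, k = k,
                 alpha = alpha),
            class = "icc31")
}

#' @export
print.icc31 <- function(x, ...) {
  cat(sprintf("ICC(3,1) = %.3f, %d%% CI [%.3f, %.3f] (n = %d, k = %d)\n",
              x$icc, round(100 * (1 - x$alpha)), x$ciLow, x$ciHigh,
              x$n, x$k))
  invisible(x)
}

#' Bland-Altman limits of agreement
#'
#' For paired measurements, the difference of each pair is plotted against
#' the pair mean; the limits of agreement are mean difference +/- 1.96 times
#' the sample SD of the differences (the conventional normal quantile, not a
#' t quantile). In `"percent"` mode the differences are expressed as a
#' percentage of the pair mean, which is the natural scale when variability
#' grows with magnitude.
#'
#' @param x1,x2 Numeric vectors of paired measurements (session 1, 2).
#' @param mode `"absolute"` (default) or `"percent"`.
#' @return A `blandAltman` object: list with `meanDiff`, `sdDiff`, `loaLow`,
#'   `loaHigh`, `mode`, and `points` (data.frame of pair means and
#'   differences).
#' @export
blandAltman <- function(x1, x2, mode = c("absolute", "percent")) {
  mode <- match.arg(mode)
  if (length(x1) != length(x2)) stop("x1 and x2 must have equal length")
  if (length(x1) < 2L) stop("need at least 2 pairs")
  means <- (x1 + x2) / 2
  diffs <- x1 - x2
  if (mode == "percent") {
    if (any(means == 0))
      stop("percent mode undefined for a pair with zero mean")
    diffs <- 100 * diffs / means
  }
  md <- mean(diffs); sdd <- stats::sd(diffs)
  structure(list(meanDiff = md, sdDiff = sdd,
                 loaLow = md - 1.96 * sdd, loaHigh = md + 1.96 * sdd,
                 mode = mode,
                 points = data.frame(mean = means, diff = diffs)),
            class = "blandAltman")
}

#' @export
print.blandAltman <- function(x, ...) {
  unit <- if (x$mode == "percent") "% of pair mean" else ""
  cat(sprintf("Bland-Altman (%s): mean diff %.3f%s, LoA [%.3f, %.3f]\n",
              x$mode, x$meanDiff, unit, x$loaLow, x$loaHigh))
  invisible(x)
}

#' Plot a Bland-Altman analysis
#'
#' Scatter of pair differences against pair means with a bold mean-difference
#' line and dotted 95% limits of agreement.
#'
#' @param x A `blandAltman` object.
#' @param xlab,ylab Axis labels; defaults adapt to the mode.
#' @return A ggplot object.
#' @export
plotBlandAltman <- function(x, xlab = "Mean of both measurements",
                            ylab = NULL) {
  stopifnot(inherits(x, "blandAltman"))
  if (is.null(ylab))
    ylab <- if (x$mode == "percent") "Difference (% of mean)" else "Difference"
  ggplot2::ggplot(x$points, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = x$meanDiff, linewidth = 1) +
    ggplot2::geom_hline(yintercept = c(x$loaLow, x$loaHigh),
                        linetype = "dotted") +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_classic()
}

#' Two-sample t test from summary statistics
#'
#' The two-tailed two-sample t test computed from group summaries
#' (n, mean, SD) as printed in a report, for re-analysis when raw data are
#' unavailable. `"pooled"` is the classic Student test
#' (df = n1 + n2 - 2); `"welch"` uses the Welch-Satterthwaite degrees of
#' freedom.
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A `summaryTTest` object: list with `t`, `df`, `p` (two-tailed),
#'   `variant` and the inputs.
#' @export
#' @examples
#' tTestFromSummary(3.38, 2.89, 52, 1.86, 2.16, 51)
tTestFromSummary <- function(m1, s1, n1, m2, s2, n2,
                             variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop("both groups need n >= 2")
  if (s1 < 0 || s2 < 0 || (s1 == 0 && s2 == 0))
    stop("SDs must be non-negative and not both zero")
  v1 <- s1^2; v2 <- s2^2
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  structure(list(t = t, df = df, p = p, variant = variant,
                 m1 = m1, s1 = s1, n1 = n1, m2 = m2, s2 = s2, n2 = n2),
            class = "summaryTTest")
}

#' @export
print.summaryTTest <- function(x, ...) {
  cat(sprintf("Two-sample t test (%s): t = %.3f, df = %.1f, p = %s\n",
              x$variant, x$t, x$df, formatP(x$p)))
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction) on an
#' r x c table of counts; all-zero rows and columns are dropped first.
#'
#' @param counts Matrix of non-negative counts.
#' @return List with `statistic`, `df`, `p`.
#' @export
chiSquareCounts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("need at least a 2 x 2 table after dropping empty rows/columns")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Expected 95% CI width of an ICC estimate
#'
#' The large-sample expected width of the confidence interval of an
#' intraclass correlation estimated from n subjects and k sessions at true
#' value rho:
#' \deqn{w(n) = 2 z_{1-\alpha/2} (1-\rho)(1+(k-1)\rho)
#'   \sqrt{2 / (k (k-1) n)}.}
#'
#' @param n Number of subjects.
#' @param rho Planning ICC, in (0, 1).
#' @param k Sessions per subject (>= 2).
#' @param alpha Two-sided level (default 0.05).
#' @return Expected CI width.
#' @seealso [iccSampleSize()] for the inverse direction.
#' @export
iccCIWidth <- function(n, rho, k = 2, alpha = 0.05) {
  if (any(rho <= 0 | rho >= 1)) stop("rho must lie strictly in (0, 1)")
  if (k < 2) stop("k must be >= 2")
  z <- stats::qnorm(1 - alpha / 2)
  2 * z * (1 - rho) * (1 + (k - 1) * rho) * sqrt(2 / (k * (k - 1) * n))
}

#' Sample size for a target ICC confidence-interval width
#'
#' Smallest number of subjects n (>= 2) whose expected CI width
#' [iccCIWidth()] does not exceed the target, for planning a test-retest
#' reliability study around an anticipated ICC.
#'
#' @inheritParams iccCIWidth
#' @param width Target full CI width (> 0).
#' @return Integer n.
#' @export
#' @examples
#' iccSampleSize(rho = 0.95, k = 2, width = 0.1)  # 15
iccSampleSize <- function(rho, k = 2, width = 0.1, alpha = 0.05) {
  if (length(rho) != 1 || rho <= 0 || rho >= 1)
    stop("rho must lie strictly in (0, 1)")
  if (width <= 0) stop("width must be positive")
  z <- stats::qnorm(1 - alpha / 2)
  # invert w(n) <= width in closed form, then guard the integer boundary
  n <- ceiling(8 * (z * (1 - rho) * (1 + (k - 1) * rho) / width)^2 /
                 (k * (k - 1)))
  n <- max(2L, as.integer(n))
  while (n > 2L && iccCIWidth(n - 1L, rho, k, alpha) <= width) n <- n - 1L
  while (iccCIWidth(n, rho, k, alpha) > width) n <- n + 1L
  n
}

#' Format a p value for reporting
#'
#' Journal convention: two decimals, three decimals below .01, leading zero
#' dropped; values below .001 are reported as "<.001".
#'
#' @param p Numeric p values in (0, 1].
#' @return Character vector, e.g. `".003"`, `".02"`, `".84"`.
#' @export
#' @examples
#' formatP(c(0.0032, 0.0161, 0.837))
formatP <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.001) return("<.001")
    s <- if (pi < 0.01) sprintf("%.3f", pi) else sprintf("%.2f", pi)
    sub("^0", "", s)
  }, character(1))
}
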