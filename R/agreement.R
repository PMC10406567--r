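#' Pearson correlation with standard error of estimate
#'
#' @param x,y equal-length numeric vectors (n >= 3), `x` with nonzero
#'   variance.
#' @return a list with `r` (sample correlation) and `see` (residual standard
#'   deviation of the y-on-x least-squares line, `sqrt(RSS / (n - 2))`, in
#'   the units of `y`).
#' @export
pearson_with_see <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("pearson_with_see: lengths differ")
  if (n < 3L) stop("pearson_with_see: need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("pearson_with_see: zero variance")
  r <- stats::cor(x, y)
  fit <- stats::lm(y ~ x)
  see <- sqrt(sum(stats::resid(fit)^2) / (n - 2))
  list(r = r, see = see)
}

#' Classify correlation strength
#'
#' Cut-offs on `|r|`: `0.3 <= |r| < 0.5` low, `0.6 <= |r| < 0.8` moderate,
#' `|r| >= 0.8` high; values in the gaps (below 0.3 or in 0.5-0.6) are
#' `unclassified`.
#'
#' @param r correlation, `|r| <= 1`.
#' @return one of `"low"`, `"moderate"`, `"high"`, `"unclassified"`.
#' @export
classify_r <- function(r) {
  if (!is.finite(r) || abs(r) > 1) stop("classify_r: |r| must be <= 1")
  a <- abs(r)
  if (a >= 0.8) "high"
  else if (a >= 0.6) "moderate"
  else if (a >= 0.3 && a < 0.5) "low"
  else "unclassified"
}

#' Bland-Altman agreement analysis
#'
#' Differences are `d = x - y`; the limits of agreement are the mean
#' difference plus/minus exactly two sample standard deviations of `d`.
#' Proportional bias is tested by regressing `d` on the pair means
#' `(x + y) / 2`; when the slope's two-sided p-value is below `alpha` the
#' regression-based limits (fitted line at the mean, plus/minus two
#' residual standard deviations) are reported instead.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @param alpha significance level for the proportional-bias slope test.
#' @return a list with `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `proportional_bias`, `prop_slope`, `prop_p`, and (when proportional
#'   bias is detected) regression-based `loa_low`/`loa_high` evaluated at
#'   the mean of `(x + y) / 2` with `resid_sd`.
#' @export
bland_altman <- function(x, y, alpha = 0.05) {
  n <- length(x)
  if (n != length(y)) stop("bland_altman: lengths differ")
  if (n < 3L) stop("bland_altman: need n >= 3")
  d <- x - y
  m <- (x + y) / 2
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  out <- list(bias = bias, sd_diff = sd_diff,
              loa_low = bias - 2 * sd_diff, loa_high = bias + 2 * sd_diff,
              proportional_bias = FALSE, prop_slope = NA_real_,
              prop_p = NA_real_)
  if (stats::sd(m) > 0 && sd_diff > 0) {
    fit <- stats::lm(d ~ m)
    sm <- summary(fit)$coefficients
    out$prop_slope <- sm[2L, 1L]
    out$prop_p <- sm[2L, 4L]
    if (is.finite(out$prop_p) && out$prop_p < alpha) {
      out$proportional_bias <- TRUE
      rsd <- sqrt(sum(stats::resid(fit)^2) / (n - 2))
      center <- unname(stats::predict(fit, data.frame(m = mean(m))))
      out$resid_sd <- rsd
      out$loa_low <- center - 2 * rsd
      out$loa_high <- center + 2 * rsd
    }
  }
  out
}

# shared two-way (participants x conditions) sum-of-squares decomposition
two_way_ss <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 3L || k < 2L) stop("need at least 3 rows and 2 columns")
  if (anyNA(m)) stop("missing values not allowed")
  grand <- mean(m)
  ss_rows <- k * sum((rowMeans(m) - grand)^2)
  ss_cols <- n * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  list(n = n, k = k,
       ms_rows = ss_rows / (n - 1),
       ms_cols = ss_cols / (k - 1),
       ms_err = ss_err / ((n - 1) * (k - 1)))
}

#' Intraclass correlation ICC(3,1) with 95% confidence interval
#'
#' Two-way mixed model, consistency, single measures:
#' `ICC = (MS_rows - MS_err) / (MS_rows + (k - 1) * MS_err)` from the
#' two-way ANOVA decomposition of the participants-by-conditions matrix.
#' The confidence interval is the F-based (Shrout-Fleiss) interval using
#' `F = MS_rows / MS_err` with `n - 1` and `(n - 1)(k - 1)` degrees of
#' freedom.
#'
#' @param m numeric matrix, participants in rows (n >= 3), conditions in
#'   columns (k >= 2), no missing values.
#' @param conf confidence level (default 0.95).
#' @return a list with `icc`, `ci` (length-2 vector), `f`, `df1`, `df2`.
#' @export
icc_3_1 <- function(m, conf = 0.95) {
  ss <- two_way_ss(m)
  k <- ss$k
  if (ss$ms_err <= .Machine$double.eps * abs(ss$ms_rows))
    return(list(icc = 1, ci = c(1, 1), f = Inf,
                df1 = ss$n - 1, df2 = (ss$n - 1) * (k - 1)))
  icc <- (ss$ms_rows - ss$ms_err) / (ss$ms_rows + (k - 1) * ss$ms_err)
  f <- ss$ms_rows / ss$ms_err
  df1 <- ss$n - 1; df2 <- (ss$n - 1) * (k - 1)
  a <- 1 - conf
  fl <- f / stats::qf(1 - a / 2, df1, df2)
  fu <- f * stats::qf(1 - a / 2, df2, df1)
  ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  list(icc = icc, ci = ci, f = f, df1 = df1, df2 = df2)
}

#' Classify ICC strength
#'
#' Below 0.40 poor, 0.40-0.59 fair, 0.60-0.74 good, 0.75-1.00 excellent.
#'
#' @param icc intraclass correlation, at most 1.
#' @return one of `"poor"`, `"fair"`, `"good"`, `"excellent"`.
#' @export
classify_icc <- function(icc) {
  if (!is.finite(icc) || icc > 1) stop("classify_icc: icc must be <= 1")
  if (icc >= 0.75) "excellent"
  else if (icc >= 0.60) "good"
  else if (icc >= 0.40) "fair"
  else "poor"
}

#' Single-factor repeated-measures ANOVA
#'
#' `F = MS_conditions / MS_error` with `k - 1` and `(k - 1)(n - 1)` degrees
#' of freedom, from the same two-way decomposition as [icc_3_1()].
#'
#' @inheritParams icc_3_1
#' @return a list with `f`, `p`, `df1`, `df2`.
#' @export
rm_anova <- function(m) {
  ss <- two_way_ss(m)
  if (ss$ms_err == 0) stop("rm_anova: zero error mean square")
  f <- ss$ms_cols / ss$ms_err
  df1 <- ss$k - 1; df2 <- (ss$k - 1) * (ss$n - 1)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' Paired t-test
#'
#' Thin wrapper over the standard paired statistic with a guard for
#' zero-variance differences.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return a list with `t` and two-sided `p`.
#' @export
paired_t <- function(x, y) {
  n <- length(x)
  if (n != length(y)) stop("paired_t: lengths differ")
  if (n < 3L) stop("paired_t: need n >= 3")
  if (stats::sd(x - y) == 0)
    stop("paired_t: differences have zero variance")
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Cohort agreement report across ramp slopes
#'
#' Assembles the full method-comparison battery for a cohort measured under
#' several ramp slopes.  For each metric (HRVT1/HRVT2 as V-dot-O2 and HR)
#' it produces all pairwise slope comparisons (Pearson r with SEE and
#' classification, Bland-Altman bias and limits of agreement, paired t,
#' Shapiro-Wilk normality of the differences) plus one ICC(3,1) with CI and
#' classification and one repeated-measures ANOVA across all slopes.
#'
#' @param estimates a data frame with columns `participant`, `slope`, and
#'   one column per metric (default metrics `hrvt1_vo2`, `hrvt1_hr`,
#'   `hrvt2_vo2`, `hrvt2_hr`).  Participants missing any slope are
#'   excluded (and listed in the result).
#' @param metrics character vector of metric column names.
#' @return a list of class `agreement_report` with elements `pairwise`
#'   (data frame, one row per metric x slope pair), `overall` (data frame,
#'   one row per metric with ICC and ANOVA), `excluded` (participant ids),
#'   and `n`.
#' @export
cohort_report <- function(estimates,
                          metrics = c("hrvt1_vo2", "hrvt1_hr",
                                      "hrvt2_vo2", "hrvt2_hr")) {
  stopifnot(is.data.frame(estimates),
            all(c("participant", "slope") %in% names(estimates)),
            all(metrics %in% names(estimates)))
  slopes <- sort(unique(estimates$slope))
  if (length(slopes) < 2L) stop("cohort_report: need at least 2 slopes")
  counts <- table(estimates$participant)
  complete <- names(counts)[counts == length(slopes)]
  excluded <- setdiff(unique(as.character(estimates$participant)), complete)
  if (length(excluded))
    message("cohort_report: excluding incomplete participant(s): ",
            paste(excluded, collapse = ", "))
  est <- estimates[estimates$participant %in% complete, , drop = FALSE]
  n <- length(complete)
  if (n < 3L) stop("cohort_report: fewer than 3 complete participants")
  est <- est[order(est$participant, est$slope), , drop = FALSE]

  pairs <- utils::combn(slopes, 2L, simplify = FALSE)
  pw <- list(); ov <- list()
  for (metric in metrics) {
    m <- matrix(est[[metric]], nrow = n, byrow = TRUE,
                dimnames = list(complete, slopes))
    for (pr in pairs) {
      x <- m[, as.character(pr[1L])]; y <- m[, as.character(pr[2L])]
      ps <- pearson_with_see(x, y)
      ba <- bland_altman(x, y)
      tt <- paired_t(x, y)
      sw <- stats::shapiro.test(x - y)
      pw[[length(pw) + 1L]] <- data.frame(
        metric = metric, pair = paste0(pr[1L], "v", pr[2L]),
        r = ps$r, r_class = classify_r(ps$r), see = ps$see,
        bias = ba$bias, sd_diff = ba$sd_diff,
        loa_low = ba$loa_low, loa_high = ba$loa_high,
        proportional_bias = ba$proportional_bias,
        t = tt$t, t_p = tt$p,
        shapiro_p = sw$p.value, diff_nonnormal = sw$p.value < 0.05)
    }
    ic <- icc_3_1(m)
    an <- rm_anova(m)
    ov[[length(ov) + 1L]] <- data.frame(
      metric = metric, icc = ic$icc, icc_lo = ic$ci[1L], icc_hi = ic$ci[2L],
      icc_class = classify_icc(ic$icc), anova_f = an$f, anova_p = an$p)
  }
  structure(list(pairwise = do.call(rbind, pw),
                 overall = do.call(rbind, ov),
                 excluded = excluded, n = n, slopes = slopes),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Cohort agreement report: %d participants, slopes %s\n",
              x$n, paste(x$slopes, collapse = "/")))
  print(x$overall, row.names = FALSE, digits = 3)
  invisible(x)
}
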