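# shared fixtures, all generated in code

# a short protocol for unit tests (full study protocol is the default)
short_protocol <- function(slope = 30)
  ramp_protocol(slope_w_per_min = slope, baseline1_s = 60, moderate_s = 60,
                baseline2_s = 60)

# compact synthetic participant for fast end-to-end tests
quick_spec <- function(seed = 1L, slope = 30, ...)
  synthetic_spec(seed = seed, protocol = short_protocol(slope),
                 hr_rest = 90, hr_max = 185, peak_w = 260, ...)

# build a dfa_trace data frame directly from a vector of a1 values
make_trace <- function(t_center, a1, hr = 150, valid = TRUE, af = 0) {
  out <- data.frame(t_center_s = t_center, a1 = a1,
                    mean_hr_bpm = rep_len(hr, length(t_center)),
                    n_beats = 150L,
                    artifact_fraction = rep_len(af, length(t_center)),
                    valid = rep_len(valid, length(t_center)))
  class(out) <- c("dfa_trace", "data.frame")
  out
}

# independent brute-force DFA alpha-1 (naive loops; oracle code path)
dfa_alpha1_naive <- function(x, n_min = 4L, n_max = 16L) {
  y <- cumsum(x - mean(x))
  ns <- n_min:n_max
  fs <- numeric(length(ns))
  for (k in seq_along(ns)) {
    n <- ns[k]
    nbox <- length(y) %/% n
    ss <- 0
    for (b in seq_len(nbox)) {
      seg <- y[((b - 1) * n + 1):(b * n)]
      t <- seq_len(n)
      fit <- stats::lm.fit(cbind(1, t), seg)
      ss <- ss + sum(fit$residuals^2)
    }
    fs[k] <- sqrt(ss / (nbox * n))
  }
  unname(stats::coef(stats::lm(log10(fs) ~ log10(ns)))[2L])
}

# independent two-way ANOVA decomposition (oracle for ICC / RM-ANOVA)
two_way_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ms_rows <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  ms_cols <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  ss_err <- sum((m - outer(rowMeans(m), rep(1, k)) -
                   outer(rep(1, n), colMeans(m)) + grand)^2)
  list(ms_rows = ms_rows, ms_cols = ms_cols,
       ms_err = ss_err / ((n - 1) * (k - 1)))
}
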