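#' DFA configuration
#'
#' Settings for the short-term detrended fluctuation analysis exponent
#' (alpha-1) and its time-varying computation.
#'
#' @param n_min,n_max smallest and largest box sizes in beats (defaults 4 and
#'   16, the short-term range used for exercise HRV).
#' @param window_s analysis window length in seconds (default 120).
#' @param step_s recalculation step in seconds (default 5).
#' @param min_beats minimum beats required in a window (default `4 * n_max`,
#'   guaranteeing at least four boxes at the largest scale).
#' @param artifact_ceiling maximum artifact fraction for a window to be
#'   considered valid (default 0.05).
#' @return a list of class `dfa_config`.
#' @export
dfa_config <- function(n_min = 4L, n_max = 16L, window_s = 120, step_s = 5,
                       min_beats = 4L * n_max, artifact_ceiling = 0.05) {
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  if (n_min < 2L || n_min >= n_max) stop("dfa_config: need 2 <= n_min < n_max")
  if (window_s <= 0 || step_s <= 0) stop("dfa_config: window_s and step_s must be positive")
  if (min_beats < 4L * n_max)
    stop("dfa_config: min_beats must be at least 4 * n_max")
  structure(list(n_min = n_min, n_max = n_max, window_s = window_s,
                 step_s = step_s, min_beats = as.integer(min_beats),
                 artifact_ceiling = artifact_ceiling),
            class = "dfa_config")
}

#' Integrated (cumulative-deviation) profile of a series
#'
#' `y_k = sum_{i<=k} (x_i - mean(x))`.  The last element is always zero by
#' telescoping.
#'
#' @param x numeric vector, length at least 2.
#' @return numeric vector of the same length.
#' @export
integrate_profile <- function(x) {
  if (length(x) < 2L) stop("integrate_profile: need at least 2 points")
  cumsum(x - mean(x))
}

#' DFA fluctuation function at one box size
#'
#' The profile is cut into `floor(N / n)` non-overlapping boxes from the
#' start (leftover points at the end are discarded); within each box the
#' least-squares line is subtracted and `F(n)` is the root-mean-square of
#' all in-box residuals pooled over boxes.
#'
#' @param profile integrated profile from [integrate_profile()].
#' @param n box size in beats; at least two boxes must fit.
#' @return `F(n)`, a non-negative scalar in the units of the input.
#' @export
fluctuation <- function(profile, n) {
  n <- as.integer(n)
  nbox <- length(profile) %/% n
  if (nbox < 2L)
    stop("fluctuation: fewer than 2 boxes of size ", n)
  y <- matrix(profile[seq_len(nbox * n)], nrow = n)
  t <- seq_len(n)
  tc <- t - mean(t)
  stt <- sum(tc^2)
  ybar <- colMeans(y)
  slope <- as.numeric(crossprod(tc, y)) / stt
  resid <- y - rep(ybar, each = n) - outer(tc, slope)
  sqrt(mean(resid^2))
}

#' Short-term DFA scaling exponent (alpha-1)
#'
#' Ordinary least-squares slope of `log10 F(n)` versus `log10 n` over every
#' integer box size in `[n_min, n_max]`.
#'
#' @param x interval sequence; must contain at least `2 * n_max` points and
#'   not be constant.
#' @param cfg a [dfa_config()].
#' @return the scaling exponent, a dimensionless scalar.
#' @export
dfa_alpha1 <- function(x, cfg = dfa_config()) {
  if (!inherits(cfg, "dfa_config")) stop("dfa_alpha1: cfg must be a dfa_config")
  if (length(x) < 2L * cfg$n_max)
    stop("dfa_alpha1: need at least ", 2L * cfg$n_max, " beats, got ", length(x))
  prof <- integrate_profile(x)
  ns <- cfg$n_min:cfg$n_max
  fs <- vapply(ns, function(n) fluctuation(prof, n), numeric(1))
  if (any(fs == 0)) stop("dfa_alpha1: zero fluctuation (constant input)")
  lx <- log10(ns); ly <- log10(fs)
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

#' Time-varying DFA alpha-1 trace
#'
#' Computes alpha-1 over rolling windows: for each center time from
#' `window_s / 2` to `duration - window_s / 2` in steps of `step_s`, the
#' beats occurring in `[t_center - window_s/2, t_center + window_s/2)` are
#' taken, optionally detrended (smoothness priors, applied per window), and
#' alpha-1 plus the window mean heart rate are computed.  Windows with too
#' few beats or an artifact fraction at or above the ceiling are marked
#' invalid and carry no alpha-1.
#'
#' @param rr an [rr_series()]; correction is expected to have been applied.
#' @param cfg a [dfa_config()].
#' @param detrend a [detrend_config()].
#' @return a `data.frame` of class `dfa_trace` with columns `t_center_s`,
#'   `a1`, `mean_hr_bpm`, `n_beats`, `artifact_fraction`, `valid`.
#' @export
time_varying_dfa <- function(rr, cfg = dfa_config(), detrend = detrend_config()) {
  stopifnot(inherits(rr, "rr_series"))
  dur <- rr$beat_times[length(rr$beat_times)]
  half <- cfg$window_s / 2
  if (dur < cfg$window_s)
    stop("time_varying_dfa: recording (", round(dur), " s) shorter than window")
  centers <- seq(half, dur - half, by = cfg$step_s)
  res <- lapply(centers, function(tc) {
    sel <- rr$beat_times >= tc - half & rr$beat_times < tc + half
    ints <- rr$intervals[sel]
    nb <- length(ints)
    afrac <- if (nb > 0) sum(rr$flags[sel] != "normal") / nb else NA_real_
    ok <- nb >= cfg$min_beats && !is.na(afrac) && afrac < cfg$artifact_ceiling
    a1 <- NA_real_
    hr <- if (nb > 0) 60000 / mean(ints) else NA_real_
    if (ok) {
      xs <- if (detrend$enabled) detrend_rr(ints, detrend) else ints
      a1 <- tryCatch(dfa_alpha1(xs, cfg), error = function(e) NA_real_)
      if (!is.finite(a1)) { a1 <- NA_real_; ok <- FALSE }
    }
    data.frame(t_center_s = tc, a1 = a1, mean_hr_bpm = hr, n_beats = nb,
               artifact_fraction = afrac, valid = ok)
  })
  out <- do.call(rbind, res)
  class(out) <- c("dfa_trace", "data.frame")
  out
}

#' Write a DFA trace to CSV
#'
#' @param trace a `dfa_trace` from [time_varying_dfa()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dfa_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
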