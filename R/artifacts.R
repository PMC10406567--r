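#' Default constants for the RR artifact classifier
#'
#' The detector works on successive RR differences (dRR) and deviations from
#' a local median (mRR), each normalized by a time-varying threshold equal to
#' a scaled quartile deviation estimated over a sliding neighborhood of
#' beats.  All constants are exposed here so the decision rule is auditable.
#'
#' @param qd_window sliding window (beats) for the quartile-deviation
#'   threshold estimate.
#' @param med_window window (beats) for the local median RR.
#' @param drr_scale scale factor applied to the quartile deviation of dRR.
#' @param mrr_scale scale factor applied to the quartile deviation of mRR.
#' @param drr_floor_ms,mrr_floor_ms lower bounds on the thresholds (ms), so
#'   that near-constant series do not produce zero thresholds.
#' @param mrr_limit candidate beats must exceed this many mRR threshold
#'   units (or one dRR unit) to be considered outliers.
#' @param merge_tol_ms tolerance (ms) when testing whether an interval
#'   matches the sum-of-two (missed) or a pair matches one local interval
#'   (extra).
#' @return a named list of constants.
#' @export
artifact_detect_config <- function(qd_window = 91L, med_window = 11L,
                                   drr_scale = 5.2, mrr_scale = 5.2,
                                   drr_floor_ms = 25, mrr_floor_ms = 25,
                                   mrr_limit = 3, merge_tol_ms = 60) {
  list(qd_window = as.integer(qd_window), med_window = as.integer(med_window),
       drr_scale = drr_scale, mrr_scale = mrr_scale,
       drr_floor_ms = drr_floor_ms, mrr_floor_ms = mrr_floor_ms,
       mrr_limit = mrr_limit, merge_tol_ms = merge_tol_ms)
}

# running quartile deviation (IQR / 2) over a centered window
running_qd <- function(x, width) {
  n <- length(x)
  half <- width %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    stats::IQR(x[lo:hi], type = 7) / 2
  }, numeric(1))
}

# running median with odd window, edges shrink to available beats
running_med <- function(x, width) {
  n <- length(x)
  half <- width %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    stats::median(x[lo:hi])
  }, numeric(1))
}

#' Detect RR artifacts (missed, extra, ectopic beats)
#'
#' Classifies each beat using a time-varying threshold on successive RR
#' differences: the threshold is a quartile-deviation estimate over a sliding
#' neighborhood (default 91 beats) scaled by a constant.  Ectopic beats are
#' identified by the short-long (negative-then-positive dRR) pattern, missed
#' beats by an interval approximately equal to the sum of two local
#' intervals, extra beats by two successive intervals summing to one local
#' interval; remaining outliers are flagged `long_short`.  The classification
#' depends only on the interval values, so re-running it is idempotent.
#'
#' @param rr an [rr_series()] with at least 3 beats.
#' @param cfg constants from [artifact_detect_config()].
#' @return the series with `flags` populated.
#' @export
detect_artifacts <- function(rr, cfg = artifact_detect_config()) {
  stopifnot(inherits(rr, "rr_series"))
  x <- rr$intervals
  n <- length(x)
  if (n < 3L) stop("detect_artifacts: need at least 3 beats, got ", n)

  drr <- c(0, diff(x))
  med <- running_med(x, cfg$med_window)
  mrr <- x - med
  th1 <- pmax(cfg$drr_scale * running_qd(drr, cfg$qd_window), cfg$drr_floor_ms)
  th2 <- pmax(cfg$mrr_scale * running_qd(mrr, cfg$qd_window), cfg$mrr_floor_ms)
  drrn <- drr / th1
  mrrn <- mrr / th2

  flags <- rep("normal", n)
  j <- 1L
  prev_flagged <- FALSE
  while (j <= n) {
    if (flags[j] != "normal") { j <- j + 1L; next }
    # a beat directly after a flagged one inherits a large dRR from the
    # artifact itself; judge it by its own deviation from the local median
    candidate <- if (prev_flagged) abs(mrrn[j]) > cfg$mrr_limit
                 else abs(drrn[j]) > 1 || abs(mrrn[j]) > cfg$mrr_limit
    prev_flagged <- FALSE
    if (!candidate) { j <- j + 1L; next }
    nxt <- if (j < n) drrn[j + 1L] else 0
    # extra: two successive short intervals summing to one local interval
    if (j < n && abs(x[j] + x[j + 1L] - med[j]) <
          max(th2[j], cfg$merge_tol_ms) &&
        x[j] < med[j] && x[j + 1L] < med[j]) {
      flags[c(j, j + 1L)] <- "extra"
      prev_flagged <- TRUE
      j <- j + 2L
      next
    }
    # missed: one long interval matching the sum of two local intervals
    if (abs(x[j] / 2 - med[j]) < max(th2[j], cfg$merge_tol_ms) &&
        mrrn[j] > cfg$mrr_limit) {
      flags[j] <- "missed"
      prev_flagged <- TRUE
      j <- j + 1L
      next
    }
    # ectopic: premature beat plus its compensatory long partner
    if (drrn[j] < -1 && nxt > 1) {
      flags[j] <- "ectopic"
      if (j < n && mrrn[j + 1L] > 1) flags[j + 1L] <- "ectopic"
      prev_flagged <- TRUE
      j <- j + 1L
      next
    }
    flags[j] <- "long_short"
    prev_flagged <- TRUE
    j <- j + 1L
  }
  rr$flags <- flags
  rr
}

#' Correct flagged RR artifacts
#'
#' Missed-beat intervals are split into two equal halves; extra-beat pairs
#' are merged into their sum; ectopic and long/short intervals are replaced
#' by cubic-spline interpolation over neighboring normal beats, rescaled so
#' the elapsed time of the replaced run is preserved exactly.  Total
#' recording duration is therefore preserved to well within 1 ms per
#' correction.  Flags are carried over to the corrected beats so that
#' artifact fractions remain computable on the corrected series.
#'
#' @param rr an [rr_series()] whose flags have been populated by
#'   [detect_artifacts()].
#' @return a corrected [rr_series()] with `corrected = TRUE`.
#' @export
correct_artifacts <- function(rr) {
  stopifnot(inherits(rr, "rr_series"))
  if (all(rr$flags == "normal")) {
    warning("correct_artifacts: no flagged beats; returning series unchanged")
    rr$corrected <- TRUE
    return(rr)
  }
  x <- rr$intervals
  fl <- rr$flags
  n <- length(x)

  # replace ectopic / long_short runs by spline over normal neighbors,
  # rescaled to preserve the run's elapsed time
  repl <- fl %in% c("ectopic", "long_short")
  if (any(repl)) {
    # anchor the spline on unflagged beats only: missed/extra spikes are
    # still uncorrected at this point and must not distort the interpolant
    good <- which(fl == "normal")
    if (length(good) >= 4L) {
      fit <- stats::spline(x = good, y = x[good], xout = which(repl),
                           method = "natural")$y
      fit <- pmax(fit, 200)  # keep intervals physiologic
      runs <- split(which(repl), cumsum(c(1, diff(which(repl)) != 1)))
      xnew <- x
      xnew[which(repl)] <- fit
      for (run in runs) {
        s <- sum(x[run]); snew <- sum(xnew[run])
        if (snew > 0) xnew[run] <- xnew[run] * (s / snew)
      }
      x <- xnew
    }
  }

  out_int <- numeric(0)
  out_fl <- character(0)
  i <- 1L
  while (i <= n) {
    if (fl[i] == "missed") {
      out_int <- c(out_int, x[i] / 2, x[i] / 2)
      out_fl <- c(out_fl, "missed", "missed")
      i <- i + 1L
    } else if (fl[i] == "extra" && i < n && fl[i + 1L] == "extra") {
      out_int <- c(out_int, x[i] + x[i + 1L])
      out_fl <- c(out_fl, "extra")
      i <- i + 2L
    } else {
      out_int <- c(out_int, x[i])
      out_fl <- c(out_fl, fl[i])
      i <- i + 1L
    }
  }
  rr_series(out_int, flags = out_fl, corrected = TRUE)
}

#' Artifact fraction over a time window
#'
#' Fraction of flagged beats among beats whose occurrence time lies in
#' `[t_start, t_end)`.  A window is usable when its fraction is below the
#' configured ceiling (default 5%).
#'
#' @param rr an [rr_series()].
#' @param t_start,t_end window bounds in seconds, `t_start < t_end`.
#' @param ceiling maximum acceptable artifact fraction (default 0.05).
#' @return a list of class `artifact_summary` with `fraction`, `per_class`
#'   counts, `n_beats`, `usable`, and `ceiling`.
#' @export
artifact_fraction <- function(rr, t_start, t_end, ceiling = 0.05) {
  stopifnot(inherits(rr, "rr_series"))
  if (t_start >= t_end) stop("artifact_fraction: t_start must be < t_end")
  sel <- rr$beat_times >= t_start & rr$beat_times < t_end
  if (!any(sel)) stop("artifact_fraction: no beats in window")
  fl <- rr$flags[sel]
  per_class <- table(factor(fl, levels = c("normal", "ectopic", "missed",
                                           "extra", "long_short")))
  frac <- sum(fl != "normal") / length(fl)
  structure(list(fraction = frac,
                 per_class = as.list(per_class[-1L]),
                 n_beats = length(fl),
                 usable = frac < ceiling,
                 ceiling = ceiling),
            class = "artifact_summary")
}
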