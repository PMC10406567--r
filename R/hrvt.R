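#' Select the rapid-decline segment of a DFA alpha-1 trace
#'
#' During a ramp test the alpha-1 trace typically shows a plateau above 1.0,
#' a rapid near-linear decline through 0.75 and 0.5, and a floor.  This
#' routine selects the decline automatically: restricting to valid windows
#' at or after ramp start, the segment end is the first window with
#' `a1 <= 0.5` (or the trace minimum if 0.5 is never reached) and the
#' segment start is the latest window at or before the end with `a1 >= 1.0`
#' (or the first valid window after ramp start).  An ordinary least-squares
#' line `a1 = intercept + slope * t` is fitted over the segment.  A manual
#' override `segment = c(t0, t1)` preserves the visual-selection workflow.
#'
#' @param trace a `dfa_trace` from [time_varying_dfa()].
#' @param protocol a [ramp_protocol()] (used for the ramp start time).
#' @param segment optional numeric length-2 vector of segment bounds in
#'   seconds, overriding the automatic rule.
#' @param r2_flag segments with `r_squared` below this value are flagged
#'   `low_r2` (default 0.7).
#' @return a list of class `decline_segment` with `t_start`, `t_end`,
#'   `indices`, `slope`, `intercept`, `r_squared`, `n_points`, `low_r2`,
#'   and `artifact_fraction` (mean over segment windows).
#' @export
select_decline_segment <- function(trace, protocol, segment = NULL,
                                   r2_flag = 0.7) {
  stopifnot(inherits(trace, "dfa_trace") || is.data.frame(trace))
  tr <- as.data.frame(trace)
  tr <- tr[tr$valid & is.finite(tr$a1), , drop = FALSE]
  tr <- tr[tr$t_center_s >= protocol$ramp_start_s, , drop = FALSE]
  if (nrow(tr) < 5L)
    stop("select_decline_segment: fewer than 5 valid windows after ramp start")
  if (!is.null(segment)) {
    if (length(segment) != 2L || segment[1L] >= segment[2L])
      stop("select_decline_segment: segment override must be c(t0, t1), t0 < t1")
    sel <- tr$t_center_s >= segment[1L] & tr$t_center_s <= segment[2L]
    seg <- tr[sel, , drop = FALSE]
  } else {
    below <- which(tr$a1 <= 0.5)
    # when 0.5 is never reached, use the last attainment of the minimum so
    # a flat trace fits its full extent (and then fails the slope check)
    i_end <- if (length(below)) below[1L]
             else max(which(tr$a1 == min(tr$a1)))
    # latest window at or before the end with a1 >= 1.0, constrained so at
    # least five fit points remain
    above <- which(tr$a1[seq_len(max(i_end - 4L, 0L))] >= 1.0)
    i_start <- if (length(above)) above[length(above)] else 1L
    seg <- tr[i_start:i_end, , drop = FALSE]
  }
  if (nrow(seg) < 5L)
    stop("select_decline_segment: segment has fewer than 5 points")
  fit <- stats::lm(a1 ~ t_center_s, data = seg)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= -1e-8)
    stop("select_decline_segment: no decline (fitted slope >= 0)")
  tss <- sum((seg$a1 - mean(seg$a1))^2)
  r2 <- 1 - sum(stats::resid(fit)^2) / tss
  structure(list(t_start = seg$t_center_s[1L],
                 t_end = seg$t_center_s[nrow(seg)],
                 indices = match(seg$t_center_s, trace$t_center_s),
                 slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 n_points = nrow(seg),
                 low_r2 = r2 < r2_flag,
                 artifact_fraction = mean(seg$artifact_fraction)),
            class = "decline_segment")
}

#' Time at which the fitted decline crosses a threshold level
#'
#' The crossing time is computed from the fitted line of the decline
#' segment, `t = (level - intercept) / slope`.  A crossing beyond the
#' segment end is allowed and flagged as extrapolated; a crossing before
#' the segment start is an error (the level lies above the fitted start).
#'
#' @param seg a [select_decline_segment()] result.
#' @param level threshold alpha-1 value (0.75 for HRVT1, 0.5 for HRVT2).
#' @return a list with `t_cross` (s) and `extrapolated`.
#' @export
hrvt_time <- function(seg, level) {
  stopifnot(inherits(seg, "decline_segment"))
  t_cross <- (level - seg$intercept) / seg$slope
  if (t_cross < seg$t_start - 1e-9)
    stop(sprintf(
      "hrvt_time: level %.2f is above the fitted value at segment start", level))
  list(t_cross = t_cross, extrapolated = t_cross > seg$t_end)
}

#' Map a crossing time to oxygen uptake
#'
#' Looks up the 20-s rolled V-dot-O2 at the grid second nearest to the
#' crossing time and reports it relative to body mass.  A crossing up to
#' 60 s beyond the end of the gas-exchange series is linearly extrapolated
#' from the final 60 s and flagged.
#'
#' @param t_cross crossing time in seconds.
#' @param b a rolled-stage [breath_series()].
#' @param p a [participant()] providing body mass.
#' @return a list with `vo2_ml_kg_min` and `extrapolated`.
#' @export
hrvt_vo2 <- function(t_cross, b, p) {
  require_stage(b, "rolled_20s", "hrvt_vo2")
  stopifnot(inherits(p, "participant"))
  t_last <- b$t[nrow(b)]
  if (t_cross > t_last + 60)
    stop("hrvt_vo2: crossing time is more than 60 s beyond the gas-exchange span")
  if (t_cross >= b$t[1L] && t_cross <= t_last) {
    i <- which.min(abs(b$t - t_cross))
    v <- b$vo2[i]
    extrap <- FALSE
  } else {
    tail_sel <- b$t >= t_last - 60
    fit <- stats::lm(vo2 ~ t, data = as.data.frame(b)[tail_sel, ])
    v <- unname(stats::predict(fit, data.frame(t = t_cross)))
    extrap <- TRUE
  }
  list(vo2_ml_kg_min = v / p$weight_kg, extrapolated = extrap)
}

#' Map a threshold level to heart rate via the HR versus alpha-1 relation
#'
#' Over the windows of the decline segment, the window-mean heart rate is
#' regressed on alpha-1 (ordinary least squares) and the line is evaluated
#' at the threshold level.  The heart rate comes from the same rolling RR
#' windows as the alpha-1 values, so both regressions cover the same
#' elapsed frame.
#'
#' @param trace the `dfa_trace` the segment was selected from.
#' @param seg a [select_decline_segment()] result.
#' @param level threshold alpha-1 value.
#' @return a list with `hr_bpm` and `hr_slope_warning` (`TRUE` when the
#'   fitted HR-on-alpha-1 slope is non-negative, i.e. HR rising with
#'   alpha-1, which is physiologically unexpected).
#' @export
hrvt_hr <- function(trace, seg, level) {
  stopifnot(inherits(seg, "decline_segment"))
  sub <- as.data.frame(trace)[seg$indices, , drop = FALSE]
  fit <- stats::lm(mean_hr_bpm ~ a1, data = sub)
  co <- stats::coef(fit)
  warn <- is.finite(co[2L]) && co[2L] >= 0
  if (warn) warning("hrvt_hr: HR rises with alpha-1 over the segment")
  list(hr_bpm = unname(co[1L] + co[2L] * level), hr_slope_warning = warn)
}

#' Estimate HRVT1 and HRVT2 for one participant
#'
#' End-to-end orchestration: artifact detection and correction of the RR
#' series, gas-exchange preprocessing, time-varying DFA, decline-segment
#' selection, threshold crossings at alpha-1 = 0.75 (HRVT1) and 0.5
#' (HRVT2), and mapping of each crossing to V-dot-O2 and heart rate.  The
#' `artifact_exceeded` flag is set when the artifact fraction over the
#' decline segment reaches the ceiling.
#'
#' @param rr an [rr_series()] (raw; detection/correction are run here
#'   unless `rr$corrected` is already `TRUE`).
#' @param breaths a raw-stage [breath_series()] (or an already rolled one).
#' @param p a [participant()].
#' @param cfg a [dfa_config()].
#' @param detrend a [detrend_config()].
#' @param levels threshold alpha-1 levels, by default `c(hrvt1 = 0.75,
#'   hrvt2 = 0.5)`.
#' @param segment optional manual segment override, `c(t0, t1)` seconds.
#' @return a list of class `hrvt_result` with the trace, segment, and one
#'   `hrvt_estimate` per level (each holding `level`, `t_cross_s`,
#'   `vo2_ml_kg_min`, `hr_bpm`, `extrapolated`, and quality flags).
#' @export
estimate_hrvt <- function(rr, breaths, p, cfg = dfa_config(),
                          detrend = detrend_config(),
                          levels = c(hrvt1 = 0.75, hrvt2 = 0.5),
                          segment = NULL) {
  stopifnot(inherits(rr, "rr_series"), inherits(p, "participant"))
  if (!rr$corrected) {
    rr <- detect_artifacts(rr)
    if (any(rr$flags != "normal")) rr <- correct_artifacts(rr)
    else rr$corrected <- TRUE
  }
  b <- if (identical(breath_stage(breaths), "rolled_20s")) breaths
       else preprocess_breaths(breaths)
  trace <- tryCatch(time_varying_dfa(rr, cfg, detrend),
                    error = function(e) stop("estimate_hrvt [dfa]: ",
                                             conditionMessage(e)))
  seg <- tryCatch(select_decline_segment(trace, p$protocol, segment = segment),
                  error = function(e) stop("estimate_hrvt [segment]: ",
                                           conditionMessage(e)))
  # the usability ceiling applies to the threshold-interpretation span of
  # the recording itself, not only to the windows that survived gating: the
  # flag is raised if the span as a whole, or any single window overlapping
  # it, reaches the ceiling
  seg_af <- artifact_fraction(rr, seg$t_start - cfg$window_s / 2,
                              seg$t_end + cfg$window_s / 2,
                              ceiling = cfg$artifact_ceiling)
  span <- trace$t_center_s >= seg$t_start & trace$t_center_s <= seg$t_end
  worst <- suppressWarnings(max(trace$artifact_fraction[span], na.rm = TRUE))
  artifact_exceeded <- !seg_af$usable ||
    (is.finite(worst) && worst >= cfg$artifact_ceiling)
  ests <- lapply(seq_along(levels), function(i) {
    lv <- levels[[i]]
    tc <- tryCatch(hrvt_time(seg, lv),
                   error = function(e) stop("estimate_hrvt [crossing]: ",
                                            conditionMessage(e)))
    vo <- tryCatch(hrvt_vo2(tc$t_cross, b, p),
                   error = function(e) stop("estimate_hrvt [vo2 mapping]: ",
                                            conditionMessage(e)))
    hr <- suppressWarnings(hrvt_hr(trace, seg, lv))
    structure(list(level = lv,
                   t_cross_s = tc$t_cross,
                   vo2_ml_kg_min = vo$vo2_ml_kg_min,
                   hr_bpm = hr$hr_bpm,
                   extrapolated = tc$extrapolated || vo$extrapolated,
                   low_r2 = seg$low_r2,
                   artifact_exceeded = artifact_exceeded,
                   hr_slope_warning = hr$hr_slope_warning),
              class = "hrvt_estimate")
  })
  names(ests) <- names(levels)
  structure(list(participant = p$id, trace = trace, segment = seg,
                 estimates = ests, rr = rr, breaths = b),
            class = "hrvt_result")
}

#' @export
print.hrvt_result <- function(x, ...) {
  cat(sprintf("HRVT estimates for participant %s\n", x$participant))
  cat(sprintf("  decline segment: %.0f-%.0f s, slope %.4g /s, R^2 %.3f\n",
              x$segment$t_start, x$segment$t_end, x$segment$slope,
              x$segment$r_squared))
  for (nm in names(x$estimates)) {
    e <- x$estimates[[nm]]
    cat(sprintf("  %s (a1 = %.2f): t = %.0f s, VO2 = %.1f mL/kg/min, HR = %.1f bpm%s\n",
                nm, e$level, e$t_cross_s, e$vo2_ml_kg_min, e$hr_bpm,
                if (e$artifact_exceeded) " [artifact > ceiling]" else ""))
  }
  invisible(x)
}
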