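#' Ramp incremental test protocol
#'
#' The default protocol is 4 min of baseline cycling at 20 W, 6 min of
#' moderate intensity (60 W for females, 80 W for males), 4 min at 20 W,
#' followed by the linear ramp at `slope_w_per_min` until task failure; the
#' ramp therefore starts 840 s into the test.
#'
#' @param slope_w_per_min ramp slope in W per minute (commonly 15, 30 or 45).
#' @param baseline1_s,moderate_s,baseline2_s phase durations in seconds.
#' @param baseline_w,moderate_w phase workloads in W.
#' @return a list of class `ramp_protocol`; `ramp_start_s` is derived as the
#'   sum of the three phase durations.
#' @export
ramp_protocol <- function(slope_w_per_min = 30, baseline1_s = 240,
                          moderate_s = 360, baseline2_s = 240,
                          baseline_w = 20, moderate_w = 80) {
  if (slope_w_per_min <= 0) stop("ramp_protocol: slope must be positive")
  if (any(c(baseline1_s, moderate_s, baseline2_s) <= 0))
    stop("ramp_protocol: phase durations must be positive")
  structure(list(slope_w_per_min = slope_w_per_min,
                 baseline1_s = baseline1_s, moderate_s = moderate_s,
                 baseline2_s = baseline2_s, baseline_w = baseline_w,
                 moderate_w = moderate_w,
                 ramp_start_s = baseline1_s + moderate_s + baseline2_s),
            class = "ramp_protocol")
}

#' Workload at a given test time
#'
#' @param protocol a [ramp_protocol()].
#' @param t time in seconds from test start (vectorized).
#' @return workload in W.
#' @export
protocol_work <- function(protocol, t) {
  p <- protocol
  w <- ifelse(t < p$baseline1_s, p$baseline_w,
       ifelse(t < p$baseline1_s + p$moderate_s, p$moderate_w,
       ifelse(t < p$ramp_start_s, p$baseline_w,
              p$baseline_w + p$slope_w_per_min * (t - p$ramp_start_s) / 60)))
  w
}

#' Participant description
#'
#' @param id participant identifier.
#' @param weight_kg body mass in kg, positive.
#' @param sex `"M"` or `"F"`.
#' @param protocol a [ramp_protocol()].
#' @return a list of class `participant`.
#' @export
participant <- function(id, weight_kg, sex = c("M", "F"),
                        protocol = ramp_protocol()) {
  sex <- match.arg(sex)
  if (!is.numeric(weight_kg) || weight_kg <= 0)
    stop("participant: weight_kg must be positive")
  structure(list(id = id, weight_kg = weight_kg, sex = sex,
                 protocol = protocol), class = "participant")
}

#' Construct a breath-by-breath series
#'
#' A `breath_series` is a data frame with columns `t` (breath time, s,
#' strictly increasing), `vo2` (mL/min) and optionally `vco2` (mL/min),
#' `ve` (L/min) and `hr` (bpm), plus a processing-stage marker.  The stage
#' advances only forward: `raw` -> `filtered` -> `gridded_1s` -> `rolled_20s`.
#'
#' @param t breath times in seconds.
#' @param vo2 oxygen uptake per breath, mL/min, non-negative.
#' @param vco2,ve,hr optional companion channels.
#' @param stage processing stage.
#' @return a `breath_series` data frame.
#' @export
breath_series <- function(t, vo2, vco2 = NULL, ve = NULL, hr = NULL,
                          stage = "raw") {
  if (length(t) != length(vo2)) stop("breath_series: t and vo2 differ in length")
  if (any(diff(t) <= 0)) stop("breath_series: t must be strictly increasing")
  if (any(vo2 < 0)) stop("breath_series: vo2 must be non-negative")
  df <- data.frame(t = as.numeric(t), vo2 = as.numeric(vo2))
  if (!is.null(vco2)) df$vco2 <- as.numeric(vco2)
  if (!is.null(ve)) df$ve <- as.numeric(ve)
  if (!is.null(hr)) df$hr <- as.numeric(hr)
  attr(df, "stage") <- stage
  class(df) <- c("breath_series", "data.frame")
  df
}

breath_stage <- function(b) attr(b, "stage")

require_stage <- function(b, stage, fn) {
  if (!inherits(b, "breath_series")) stop(fn, ": not a breath_series")
  if (!identical(breath_stage(b), stage))
    stop(fn, ": expected stage '", stage, "', got '", breath_stage(b),
         "' (the pipeline is order-fixed: raw -> filtered -> gridded_1s -> rolled_20s)")
  invisible(b)
}

#' Read a breath-by-breath CSV
#'
#' Expects a header `t_s, vo2_ml_min` with optional `vco2_ml_min`,
#' `ve_l_min`, `hr_bpm` columns.
#'
#' @param path file path.
#' @return a raw-stage [breath_series()].
#' @export
read_breaths <- function(path) {
  if (!file.exists(path)) stop("read_breaths: file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("t_s", "vo2_ml_min")
  if (!all(need %in% names(df)))
    stop("read_breaths: requires columns t_s, vo2_ml_min")
  breath_series(df$t_s, df$vo2_ml_min,
                vco2 = if ("vco2_ml_min" %in% names(df)) df$vco2_ml_min,
                ve = if ("ve_l_min" %in% names(df)) df$ve_l_min,
                hr = if ("hr_bpm" %in% names(df)) df$hr_bpm)
}

#' Write a breath series to CSV
#'
#' @param b a [breath_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_breaths <- function(b, path) {
  out <- data.frame(t_s = b$t, vo2_ml_min = b$vo2)
  if (!is.null(b$vco2)) out$vco2_ml_min <- b$vco2
  if (!is.null(b$ve)) out$ve_l_min <- b$ve
  if (!is.null(b$hr)) out$hr_bpm <- b$hr
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Remove outlier breaths by deviation from the local mean
#'
#' A breath is removed when its V-dot-O2 deviates from the local mean by
#' more than `k` local standard deviations, where the local statistics are
#' computed over a centered window of `local_window` breaths excluding the
#' candidate itself.  Removal is decided in one pass over the original
#' series.  With a zero local SD only exactly-equal values survive.
#'
#' @param b a raw-stage [breath_series()] with at least `local_window`
#'   breaths.
#' @param k SD multiple (default 3).
#' @param local_window local window width in breaths (default 9).
#' @return the filtered series (stage `filtered`).
#' @export
filter_outliers <- function(b, k = 3, local_window = 9L) {
  require_stage(b, "raw", "filter_outliers")
  n <- nrow(b)
  if (n < local_window) stop("filter_outliers: need at least ", local_window, " breaths")
  half <- local_window %/% 2L
  keep <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    idx <- setdiff(lo:hi, i)
    m <- mean(b$vo2[idx]); s <- stats::sd(b$vo2[idx])
    if (!is.finite(s) || s == 0) return(b$vo2[i] == m)
    abs(b$vo2[i] - m) <= k * s
  }, logical(1))
  if (!any(keep)) stop("filter_outliers: all breaths removed")
  out <- b[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "stage") <- "filtered"
  class(out) <- c("breath_series", "data.frame")
  out
}

#' Interpolate a breath series to a 1-s grid
#'
#' Linear interpolation of every channel onto the integer-second grid
#' spanning `[ceil(t_first), floor(t_last)]`.
#'
#' @param b a filtered-stage [breath_series()] with at least 2 breaths.
#' @return the gridded series (stage `gridded_1s`).
#' @export
interpolate_1s <- function(b) {
  require_stage(b, "filtered", "interpolate_1s")
  if (nrow(b) < 2L) stop("interpolate_1s: need at least 2 breaths")
  grid <- seq(ceiling(b$t[1L]), floor(b$t[nrow(b)]), by = 1)
  interp <- function(y) stats::approx(b$t, y, xout = grid)$y
  out <- data.frame(t = grid, vo2 = interp(b$vo2))
  for (ch in intersect(c("vco2", "ve", "hr"), names(b))) out[[ch]] <- interp(b[[ch]])
  attr(out, "stage") <- "gridded_1s"
  class(out) <- c("breath_series", "data.frame")
  out
}

# centered moving mean with shrinking edges; attribute marks full windows
rolling_mean_centered <- function(y, width) {
  n <- length(y)
  half_lo <- width %/% 2L
  half_hi <- (width - 1L) %/% 2L
  out <- vapply(seq_len(n), function(i) {
    mean(y[max(1L, i - half_lo):min(n, i + half_hi)])
  }, numeric(1))
  full <- seq_len(n) > half_lo & seq_len(n) <= n - half_hi
  attr(out, "full_window") <- full
  out
}

#' 20-s rolling average of a gridded breath series
#'
#' Centered 20-sample moving mean on the 1-s grid, covering seconds
#' `t - 10` to `t + 9` (an even window cannot be exactly symmetric; this
#' convention makes a step change average to exactly half at the step).
#' On a linear ramp the output therefore trails the input by half a
#' sample's increment.  Edge samples use the available part of the window
#' and are flagged in the `edge` column.
#'
#' @param b a gridded-stage [breath_series()] with at least 20 samples.
#' @return the smoothed series (stage `rolled_20s`) with an `edge` column.
#' @export
rolling_20s <- function(b) {
  require_stage(b, "gridded_1s", "rolling_20s")
  if (nrow(b) < 20L) stop("rolling_20s: need at least 20 s of gridded data")
  out <- b
  for (ch in intersect(c("vo2", "vco2", "ve", "hr"), names(b))) {
    r <- rolling_mean_centered(b[[ch]], 20L)
    out[[ch]] <- as.numeric(r)
    if (ch == "vo2") out$edge <- !attr(r, "full_window")
  }
  attr(out, "stage") <- "rolled_20s"
  class(out) <- c("breath_series", "data.frame")
  out
}

#' Peak oxygen uptake from the smoothed series
#'
#' The highest value of the 20-s rolled V-dot-O2 series; with a
#' [participant()] the mass-relative value is reported as well.
#'
#' @param b a rolled-stage [breath_series()].
#' @param p optional [participant()] for the per-kg value.
#' @return a list with `vo2max_ml_min` and, given `p`,
#'   `vo2max_ml_kg_min`.
#' @export
vo2max <- function(b, p = NULL) {
  require_stage(b, "rolled_20s", "vo2max")
  v <- max(b$vo2)
  out <- list(vo2max_ml_min = v)
  if (!is.null(p)) out$vo2max_ml_kg_min <- v / p$weight_kg
  out
}

#' Maximal heart rate from the 20-s rolled HR channel
#'
#' @param b a rolled-stage [breath_series()] with an `hr` column.
#' @return maximal heart rate in bpm.
#' @export
hrmax <- function(b) {
  require_stage(b, "rolled_20s", "hrmax")
  if (is.null(b$hr)) stop("hrmax: no HR channel in breath series")
  max(b$hr)
}

#' Run the full gas-exchange preprocessing chain
#'
#' Convenience wrapper: outlier filtering, 1-s interpolation and 20-s
#' rolling average in their fixed order.
#'
#' @inheritParams filter_outliers
#' @return a rolled-stage [breath_series()].
#' @export
preprocess_breaths <- function(b, k = 3, local_window = 9L) {
  rolling_20s(interpolate_1s(filter_outliers(b, k = k,
                                             local_window = local_window)))
}
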