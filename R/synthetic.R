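#' Specification of a synthetic ramp-test participant
#'
#' Defines the physiological model from which synthetic RR and
#' breath-by-breath recordings are generated.  Heart rate and oxygen uptake
#' are both driven by the lagged ("effective") workload
#' `W_eff(t) = W(t - mrt_s)`: V-dot-O2 is linear in effective workload and
#' heart rate follows a smoothly saturating curve from `hr_rest` (at the
#' 20 W baseline) to `hr_max` (at `peak_w`).  The recording ends with a
#' short constant-load hold at peak so heart rate settles at its maximum,
#' as at task failure.  Because both responses are functions of effective
#' workload alone, the heart rate and V-dot-O2 at any fixed heart-rate
#' anchor are identical across ramp slopes by construction — the
#' slope-invariance property the estimation pipeline is meant to recover.
#'
#' The time-varying scaling exponent target follows the characteristic
#' reverse-sigmoid profile: a plateau at `a1_plateau`, a near-linear
#' decline to `a1_floor`, then a flat floor.  The decline timing is derived
#' (per slope) so that the profile crosses 0.75 exactly when heart rate
#' reaches `hr_hrvt1` and 0.5 when it reaches `hr_hrvt2`, unless
#' `decline_start_s`/`decline_end_s` are given explicitly.
#'
#' @param a1_plateau scaling-exponent plateau at low intensity (default 1.05).
#' @param a1_floor floor at high intensity (default 0.30).
#' @param decline_start_s,decline_end_s optional explicit decline bounds (s);
#'   by default derived from the heart-rate anchors.
#' @param hr_rest heart rate at the 20 W baseline, bpm (default 90).
#' @param hr_max maximal heart rate, bpm (default 185).
#' @param hr_hrvt1,hr_hrvt2 heart-rate anchors of the two thresholds, bpm
#'   (defaults 150 and 161).
#' @param rr_sd_rest,rr_sd_peak RR fluctuation SD at rest / at peak, ms
#'   (defaults 40 and 4).  Variability shrinks with intensity following an
#'   exponential decay in relative heart-rate reserve (`sd_decay`): most of
#'   the collapse happens at low-to-moderate intensity, as with
#'   parasympathetic withdrawal, so the amplitude is nearly flat across the
#'   later threshold region.
#' @param sd_decay decay constant of the variability-versus-intensity
#'   curve (default 4).
#' @param vo2_baseline resting (0 W) oxygen uptake, mL/min (default 500).
#' @param vo2_gain oxygen cost of work, mL/min per W (default 10).
#' @param mrt_s mean response time of the lagged responses, s (default 30).
#' @param peak_w workload at which heart rate saturates and the test ends,
#'   W (default 300).
#' @param hold_s constant-load hold at peak before test end, s (default 60).
#' @param weight_kg body mass (default 70).
#' @param sex `"M"` or `"F"`.
#' @param protocol a [ramp_protocol()].
#' @param artifact_rates named per-beat probabilities for classes `missed`,
#'   `extra`, `ectopic` (defaults all 0).
#' @param breath_noise_sd multiplicative SD of breath-by-breath noise
#'   (default 0.04).
#' @param spike_rate probability of an injected outlier breath (default 0.01).
#' @param seed integer seed; all randomness of the generators flows from it.
#' @return a list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(a1_plateau = 1.05, a1_floor = 0.30,
                           decline_start_s = NULL, decline_end_s = NULL,
                           hr_rest = 90, hr_max = 185,
                           hr_hrvt1 = 150, hr_hrvt2 = 161,
                           rr_sd_rest = 40, rr_sd_peak = 4, sd_decay = 4,
                           vo2_baseline = 500, vo2_gain = 10,
                           mrt_s = 30, peak_w = 300, hold_s = 60,
                           weight_kg = 70, sex = "M",
                           protocol = ramp_protocol(),
                           artifact_rates = list(missed = 0, extra = 0,
                                                 ectopic = 0),
                           breath_noise_sd = 0.04, spike_rate = 0.01,
                           seed = 1L) {
  if (!(a1_plateau > 0.75 && 0.5 > a1_floor))
    stop("synthetic_spec: need a1_plateau > 0.75 and a1_floor < 0.5")
  if (!(hr_rest < hr_hrvt1 && hr_hrvt1 < hr_hrvt2 && hr_hrvt2 < hr_max))
    stop("synthetic_spec: need hr_rest < hr_hrvt1 < hr_hrvt2 < hr_max")
  if (!is.null(decline_start_s) && !is.null(decline_end_s) &&
      decline_start_s >= decline_end_s)
    stop("synthetic_spec: decline_start_s must be < decline_end_s")
  spec <- structure(list(
    a1_plateau = a1_plateau, a1_floor = a1_floor,
    hr_rest = hr_rest, hr_max = hr_max,
    hr_hrvt1 = hr_hrvt1, hr_hrvt2 = hr_hrvt2,
    rr_sd_rest = rr_sd_rest, rr_sd_peak = rr_sd_peak, sd_decay = sd_decay,
    vo2_baseline = vo2_baseline, vo2_gain = vo2_gain,
    mrt_s = mrt_s, peak_w = peak_w, hold_s = hold_s,
    weight_kg = weight_kg, sex = sex, protocol = protocol,
    artifact_rates = artifact_rates,
    breath_noise_sd = breath_noise_sd, spike_rate = spike_rate,
    seed = as.integer(seed)), class = "synthetic_spec")
  if (is.null(decline_start_s) || is.null(decline_end_s)) {
    gt <- derive_decline(spec)
    spec$decline_start_s <- gt$decline_start_s
    spec$decline_end_s <- gt$decline_end_s
  } else {
    spec$decline_start_s <- decline_start_s
    spec$decline_end_s <- decline_end_s
  }
  spec
}

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  3 * u^2 - 2 * u^3
}

# effective (lagged) workload: the actual load caps at peak_w during the
# end hold, and responses lag it by the mean response time
sim_work_eff <- function(spec, t) {
  pmin(protocol_work(spec$protocol, pmax(t - spec$mrt_s, 0)), spec$peak_w)
}

# model heart rate as a function of time (via effective workload)
sim_hr <- function(spec, t) {
  w <- sim_work_eff(spec, t)
  u <- (w - spec$protocol$baseline_w) / (spec$peak_w - spec$protocol$baseline_w)
  spec$hr_rest + (spec$hr_max - spec$hr_rest) * smoothstep(u)
}

# model oxygen uptake (mL/min) as a function of time
sim_vo2 <- function(spec, t) {
  spec$vo2_baseline + spec$vo2_gain * sim_work_eff(spec, t)
}

# total recording duration: protocol phases + ramp to peak_w + lag + hold
sim_duration <- function(spec) {
  p <- spec$protocol
  ramp_dur <- (spec$peak_w - p$baseline_w) / p$slope_w_per_min * 60
  p$ramp_start_s + ramp_dur + spec$mrt_s + spec$hold_s
}

# invert the heart-rate curve: time during the ramp at which HR reaches `hr`
sim_time_at_hr <- function(spec, hr) {
  lo <- spec$protocol$ramp_start_s
  hi <- sim_duration(spec)
  stats::uniroot(function(t) sim_hr(spec, t) - hr, lower = lo, upper = hi,
                 tol = 1e-10)$root
}

# derive decline bounds so the profile crosses 0.75 / 0.5 at the HR anchors
derive_decline <- function(spec) {
  t075 <- sim_time_at_hr(spec, spec$hr_hrvt1)
  t05 <- sim_time_at_hr(spec, spec$hr_hrvt2)
  f075 <- (spec$a1_plateau - 0.75) / (spec$a1_plateau - spec$a1_floor)
  f05 <- (spec$a1_plateau - 0.50) / (spec$a1_plateau - spec$a1_floor)
  len <- (t05 - t075) / (f05 - f075)
  ds <- t075 - f075 * len
  list(decline_start_s = ds, decline_end_s = ds + len)
}

#' Target scaling-exponent profile of a synthetic participant
#'
#' Piecewise linear: the plateau value before `decline_start_s`, a linear
#' decline to `a1_floor` at `decline_end_s`, then flat.
#'
#' @param spec a [synthetic_spec()].
#' @param t time in seconds (vectorized).
#' @return the target alpha-1 at `t`.
#' @export
a1_profile <- function(spec, t) {
  ds <- spec$decline_start_s; de <- spec$decline_end_s
  frac <- pmin(pmax((t - ds) / (de - ds), 0), 1)
  spec$a1_plateau - frac * (spec$a1_plateau - spec$a1_floor)
}

#' Ground-truth thresholds of a synthetic participant
#'
#' The true crossing times are where the piecewise-linear profile equals
#' 0.75 and 0.5; heart rate and V-dot-O2 truth come from the underlying
#' model at those times.  Because the model maps effective workload to both
#' responses, the HR and V-dot-O2 truth values are slope-invariant when the
#' decline bounds are derived from the heart-rate anchors.
#'
#' @param spec a [synthetic_spec()].
#' @return a data frame with one row: `t_075`, `t_05` (s), `hr_075`,
#'   `hr_05` (bpm), `vo2_075`, `vo2_05` (mL/kg/min).
#' @export
ground_truth <- function(spec) {
  f075 <- (spec$a1_plateau - 0.75) / (spec$a1_plateau - spec$a1_floor)
  f05 <- (spec$a1_plateau - 0.50) / (spec$a1_plateau - spec$a1_floor)
  len <- spec$decline_end_s - spec$decline_start_s
  t075 <- spec$decline_start_s + f075 * len
  t05 <- spec$decline_start_s + f05 * len
  data.frame(t_075 = t075, t_05 = t05,
             hr_075 = sim_hr(spec, t075), hr_05 = sim_hr(spec, t05),
             vo2_075 = sim_vo2(spec, t075) / spec$weight_kg,
             vo2_05 = sim_vo2(spec, t05) / spec$weight_kg)
}

#' Gaussian noise with a power-law spectrum
#'
#' Fourier spectral synthesis: one-sided amplitudes proportional to
#' `f^(-beta/2)` (so the power spectral density is proportional to
#' `f^(-beta)`) with uniformly random phases, inverse-transformed and
#' standardized to zero mean and unit SD.  Under detrended fluctuation
#' analysis such a series scales with exponent `alpha = (beta + 1) / 2`;
#' `beta = 0` is white noise (`alpha = 0.5`).
#'
#' @param n series length.
#' @param beta power-spectral exponent.
#' @return numeric vector of length `n`, mean 0, SD 1.
#' @export
spectral_noise <- function(n, beta) {
  if (n < 8L) stop("spectral_noise: n too small")
  nf <- n %/% 2L
  amp <- (seq_len(nf) / n)^(-beta / 2)
  phase <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = phase)
  if (n %% 2L == 0L) spec[nf] <- complex(real = amp[nf], imaginary = 0)
  full <- c(0, spec, Conj(rev(spec[seq_len(nf - (1 - n %% 2L))])))
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  as.numeric(scale(x))
}

#' Expected short-term DFA slope for a power-law process
#'
#' Deterministic, analytic band response of the short-term DFA estimator:
#' for a stationary Gaussian process synthesized with power-spectral
#' exponent `beta` (block length `M`), the in-box detrended profile depends
#' only on in-box increments, so the expected squared fluctuation at box
#' size `n` is `tr(P A C A' P) / n`, with `C` the Toeplitz autocovariance,
#' `A` the cumulative-sum operator and `P` the linear-detrend projector.
#' The returned value is the least-squares slope of
#' `log10 sqrt(E F^2(n))` versus `log10 n` over the box-size band.
#' Asymptotically this equals `(beta + 1) / 2`, but over a finite small-n
#' band the estimator is biased (white noise, `beta = 0`, reads about
#' 0.58 rather than 0.5); [generate_rr()] inverts this response so the
#' series it emits carry the prescribed measured exponent.
#'
#' @param beta power-spectral exponent.
#' @param ns integer box sizes (default 4:16).
#' @param M synthesis block length in samples (default 128).
#' @return the expected band slope, a scalar.
#' @export
dfa_band_response <- function(beta, ns = 4:16, M = 128L) {
  j <- seq_len(M %/% 2L)
  S <- j^(-beta)
  nlag <- max(ns)
  r <- vapply(0:(nlag - 1L), function(k) sum(S * cos(2 * pi * j * k / M)),
              numeric(1))
  r <- r / r[1L]
  f2 <- vapply(ns, function(n) {
    A <- matrix(0, n, n); A[lower.tri(A, diag = TRUE)] <- 1
    C <- stats::toeplitz(r[seq_len(n)])
    X <- cbind(1, seq_len(n))
    P <- diag(n) - X %*% solve(crossprod(X)) %*% t(X)
    sum(diag(P %*% A %*% C %*% t(A) %*% P)) / n
  }, numeric(1))
  lx <- log10(ns); ly <- 0.5 * log10(f2)
  sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
}

# memoized inverse of the band response: target measured a1 -> beta
beta_cache <- new.env(parent = emptyenv())
beta_for_a1 <- function(a1) {
  if (is.null(beta_cache$grid)) {
    bs <- seq(-1.8, 2.2, by = 0.05)
    beta_cache$grid <- list(beta = bs,
                            a1 = vapply(bs, dfa_band_response, numeric(1)))
  }
  g <- beta_cache$grid
  out <- stats::approx(g$a1, g$beta, xout = a1, rule = 2)$y
  out
}

#' Generate a synthetic RR recording
#'
#' The series is built in 30-s piecewise-stationary blocks: within each
#' block, fluctuations are drawn by spectral synthesis whose power-spectral
#' exponent is chosen, by inverting the analytic [dfa_band_response()], so
#' that the short-term estimator (boxes 4-16) reads the target
#' `a1_profile(block center)` without bias (asymptotically the exponent is
#' the classic `beta = 2 * a1 - 1` correspondence).  Fluctuations are
#' scaled to an SD interpolating from `rr_sd_rest` to `rr_sd_peak` with
#' intensity and added to the mean RR `60000 / HR(t)` at each beat.
#' Consecutive blocks are crossfaded over 5 s to avoid seams.  All
#' randomness flows from `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param block_s block length, s (default 30).
#' @param fade_s crossfade length, s (default 5).
#' @return a list with `rr` (a clean [rr_series()], possibly with injected
#'   artifacts when `spec$artifact_rates` are nonzero, in which case the
#'   truth mask is attached as attribute `"truth"`) and `truth` (the
#'   [ground_truth()] row).
#' @export
generate_rr <- function(spec, block_s = 30, fade_s = 5) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  total <- sim_duration(spec)
  max_hr <- spec$hr_max
  ints <- numeric(0)
  t <- 0
  tail_fl <- numeric(0)  # fluctuation samples extending past the last block
  while (t < total) {
    t_end_block <- min(t + block_s, total)
    t_mid <- (t + t_end_block) / 2
    beta <- beta_for_a1(a1_profile(spec, t_mid))
    n_need <- ceiling((block_s + 2 * fade_s) * max_hr / 60) + 16L
    fl <- spectral_noise(n_need, beta)
    n_fade <- length(tail_fl)
    if (n_fade > 0) {
      w <- seq_len(n_fade) / (n_fade + 1)
      fl[seq_len(n_fade)] <- (1 - w) * tail_fl + w * fl[seq_len(n_fade)]
    }
    i <- 0L
    while (t < t_end_block && i < length(fl)) {
      i <- i + 1L
      hr_t <- sim_hr(spec, t)
      u <- min(max((hr_t - spec$hr_rest) / (spec$hr_max - spec$hr_rest), 0), 1)
      sd_t <- spec$rr_sd_peak + (spec$rr_sd_rest - spec$rr_sd_peak) *
        exp(-spec$sd_decay * u)
      rr_ms <- 60000 / hr_t + sd_t * fl[i]
      rr_ms <- min(max(rr_ms, 250), 2500)
      ints <- c(ints, rr_ms)
      t <- t + rr_ms / 1000
    }
    n_tail <- min(ceiling(fade_s * max_hr / 60), length(fl) - i)
    tail_fl <- if (n_tail > 0) fl[i + seq_len(n_tail)] else numeric(0)
  }
  rr <- rr_series(ints)
  if (sum(unlist(spec$artifact_rates)) > 0)
    rr <- inject_artifacts(rr, spec$artifact_rates)
  list(rr = rr, truth = ground_truth(spec))
}

#' Inject RR artifacts with a known truth mask
#'
#' Randomly replaces beats with missed (two intervals merged into one),
#' extra (one interval split into two) and ectopic (short-long
#' perturbation) patterns at the stated per-class rates.  Uses the current
#' RNG state; seed via `set.seed()` (or through [generate_rr()]).
#'
#' @param rr a clean [rr_series()].
#' @param rates named list with per-beat probabilities `missed`, `extra`,
#'   `ectopic`; their sum must not exceed 0.2.
#' @return the corrupted [rr_series()]; attribute `"truth"` is a logical
#'   vector marking artifact-affected output beats.
#' @export
inject_artifacts <- function(rr, rates) {
  stopifnot(inherits(rr, "rr_series"))
  p_m <- rates$missed %||% 0
  p_x <- rates$extra %||% 0
  p_e <- rates$ectopic %||% 0
  if (p_m + p_x + p_e > 0.2)
    stop("inject_artifacts: total artifact rate above 0.2 is unrealistic")
  x <- rr$intervals
  out <- numeric(0); truth <- logical(0)
  i <- 1L; n <- length(x)
  while (i <= n) {
    u <- stats::runif(1)
    if (u < p_m && i < n) {
      out <- c(out, x[i] + x[i + 1L]); truth <- c(truth, TRUE)
      i <- i + 2L
    } else if (u < p_m + p_x) {
      fr <- stats::runif(1, 0.4, 0.6)
      out <- c(out, x[i] * fr, x[i] * (1 - fr)); truth <- c(truth, TRUE, TRUE)
      i <- i + 1L
    } else if (u < p_m + p_x + p_e && i < n) {
      d <- 0.3 * x[i]
      out <- c(out, x[i] - d, x[i + 1L] + d); truth <- c(truth, TRUE, TRUE)
      i <- i + 2L
    } else {
      out <- c(out, x[i]); truth <- c(truth, FALSE)
      i <- i + 1L
    }
  }
  res <- rr_series(out)
  attr(res, "truth") <- truth
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic breath-by-breath recording
#'
#' Breath timing follows a heart-rate-coupled respiratory rate (12
#' breaths/min at rest rising to 45 at maximal intensity); each breath's
#' V-dot-O2 is the model value under multiplicative Gaussian noise, with
#' occasional large outlier breaths injected at `spec$spike_rate` to
#' exercise the outlier filter.  Companion channels: V-dot-CO2 via a
#' rising respiratory exchange ratio, ventilation proportional to
#' V-dot-CO2, and a lightly noised heart-rate channel.
#'
#' @param spec a [synthetic_spec()].
#' @return a raw-stage [breath_series()] spanning the full protocol.
#' @export
generate_breaths <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  total <- sim_duration(spec)
  t <- 0; ts <- numeric(0)
  while (t < total) {
    hr_t <- sim_hr(spec, t)
    u <- pmin(pmax((hr_t - spec$hr_rest) / (spec$hr_max - spec$hr_rest), 0), 1)
    rb <- 12 + 33 * u
    t <- t + 60 / rb
    if (t < total) ts <- c(ts, t)
  }
  v_true <- sim_vo2(spec, ts)
  noise <- 1 + stats::rnorm(length(ts), 0, spec$breath_noise_sd)
  vo2 <- v_true * noise
  spikes <- stats::runif(length(ts)) < spec$spike_rate
  if (any(spikes))
    vo2[spikes] <- vo2[spikes] *
      ifelse(stats::runif(sum(spikes)) < 0.5, 0.6, 1.45)
  vo2 <- pmax(vo2, 0)
  hr_u <- pmin(pmax((sim_hr(spec, ts) - spec$hr_rest) /
                      (spec$hr_max - spec$hr_rest), 0), 1)
  rer <- 0.85 + 0.3 * hr_u
  vco2 <- v_true * rer * (1 + stats::rnorm(length(ts), 0, spec$breath_noise_sd))
  ve <- 5 + 0.026 * vco2
  hr_ch <- sim_hr(spec, ts) + stats::rnorm(length(ts), 0, 1)
  breath_series(ts, vo2, vco2 = vco2, ve = ve, hr = hr_ch)
}

#' Generate a synthetic cohort with files on disk
#'
#' Draws per-participant physiology, instantiates each participant under
#' every requested ramp slope with shared threshold heart-rate anchors (so
#' the HR and V-dot-O2 ground truth is identical across slopes), and
#' writes RR files, breath files, a manifest CSV and a ground-truth CSV in
#' the same dialects the readers consume.
#'
#' @param n number of participants (at least 3; default 17).
#' @param slopes ramp slopes in W/min (default `c(15, 30, 45)`).
#' @param seed integer master seed.
#' @param outdir output directory (created if needed).
#' @param hrvt1_range range from which each participant's first-threshold
#'   heart-rate anchor is drawn, bpm (default `c(130, 165)`).
#' @param artifact_rates per-class injection rates passed to every
#'   participant (default: 0.4% missed, 0.4% extra, 0.4% ectopic).
#' @return a list with `manifest` and `truth` data frames (also written to
#'   `manifest.csv` / `truth.csv` under `outdir`) and `dir`.
#' @export
generate_cohort <- function(n = 17, slopes = c(15, 30, 45), seed = 1L,
                            outdir = tempfile("cohort"),
                            hrvt1_range = c(130, 165),
                            artifact_rates = list(missed = 0.004,
                                                  extra = 0.004,
                                                  ectopic = 0.004)) {
  if (n < 3) stop("generate_cohort: need n >= 3")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  phys <- data.frame(
    id = sprintf("P%02d", seq_len(n)),
    sex = rep(c("M", "F"), length.out = n),
    hr_rest = round(stats::rnorm(n, 90, 5)),
    hr_max = round(stats::rnorm(n, 185, 7)),
    hr1 = round(stats::runif(n, hrvt1_range[1L], hrvt1_range[2L])),
    hr_gap = round(stats::runif(n, 8, 18)),
    peak_w = round(stats::rnorm(n, 290, 30)),
    vo2_baseline = round(stats::rnorm(n, 500, 50)),
    vo2_gain = round(stats::rnorm(n, 10, 0.4), 2))
  phys$weight_kg <- round(ifelse(phys$sex == "M", stats::rnorm(n, 75, 8),
                                 stats::rnorm(n, 62, 7)), 1)
  phys$hr_max <- pmax(phys$hr_max, phys$hr1 + phys$hr_gap + 10)
  sub_seed <- function(i, s) (seed %% 100000L) * 10000L + i * 100L + s

  manifest <- list(); truth <- list()
  for (i in seq_len(n)) {
    for (k in seq_along(slopes)) {
      sl <- slopes[k]
      proto <- ramp_protocol(slope_w_per_min = sl,
                             moderate_w = if (phys$sex[i] == "F") 60 else 80)
      spec <- synthetic_spec(
        hr_rest = phys$hr_rest[i], hr_max = phys$hr_max[i],
        hr_hrvt1 = phys$hr1[i], hr_hrvt2 = phys$hr1[i] + phys$hr_gap[i],
        vo2_baseline = phys$vo2_baseline[i], vo2_gain = phys$vo2_gain[i],
        peak_w = phys$peak_w[i], weight_kg = phys$weight_kg[i],
        sex = phys$sex[i], protocol = proto,
        artifact_rates = artifact_rates,
        seed = sub_seed(i, k))
      gen <- generate_rr(spec)
      br <- generate_breaths(spec)
      rr_file <- sprintf("rr_%s_%02dw.txt", phys$id[i], sl)
      br_file <- sprintf("breaths_%s_%02dw.csv", phys$id[i], sl)
      write_rr(gen$rr, file.path(outdir, rr_file))
      write_breaths(br, file.path(outdir, br_file))
      manifest[[length(manifest) + 1L]] <- data.frame(
        participant_id = phys$id[i], weight_kg = phys$weight_kg[i],
        sex = phys$sex[i], slope_w_per_min = sl,
        rr_file = rr_file, breath_file = br_file,
        ramp_start_s = proto$ramp_start_s)
      truth[[length(truth) + 1L]] <- cbind(
        data.frame(participant_id = phys$id[i], slope_w_per_min = sl),
        gen$truth)
    }
  }
  manifest <- do.call(rbind, manifest)
  truth <- do.call(rbind, truth)
  utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(truth, file.path(outdir, "truth.csv"), row.names = FALSE)
  list(manifest = manifest, truth = truth, dir = outdir)
}
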