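test_that("the target profile is piecewise linear with exact inverses", {
  spec <- synthetic_spec(decline_start_s = 900, decline_end_s = 1200)
  expect_equal(a1_profile(spec, 100), 1.05)
  expect_equal(a1_profile(spec, 1050), (1.05 + 0.30) / 2)   # midpoint
  expect_equal(a1_profile(spec, 1500), 0.30)
  gt <- ground_truth(spec)
  expect_equal(a1_profile(spec, gt$t_075), 0.75, tolerance = 1e-12)
  expect_equal(a1_profile(spec, gt$t_05), 0.50, tolerance = 1e-12)
  expect_lt(gt$t_075, gt$t_05)
})

test_that("derived decline bounds pin crossings to the heart-rate anchors", {
  spec <- synthetic_spec(seed = 2)
  gt <- ground_truth(spec)
  expect_equal(gt$hr_075, spec$hr_hrvt1, tolerance = 1e-6)
  expect_equal(gt$hr_05, spec$hr_hrvt2, tolerance = 1e-6)
})

test_that("threshold ground truth is ramp-slope invariant by construction", {
  for (seed in 1:3) {
    gts <- lapply(c(15, 30, 45), function(sl)
      ground_truth(synthetic_spec(seed = seed,
                                  protocol = ramp_protocol(slope_w_per_min = sl))))
    hr075 <- vapply(gts, function(g) g$hr_075, numeric(1))
    vo205 <- vapply(gts, function(g) g$vo2_05, numeric(1))
    expect_lt(diff(range(hr075)), 1e-6)
    expect_lt(diff(range(vo205)), 1e-6)
    # crossing times themselves differ with slope
    t075 <- vapply(gts, function(g) g$t_075, numeric(1))
    expect_gt(diff(range(t075)), 60)
  }
})

test_that("spectral synthesis hits prescribed exponents in the DFA band", {
  set.seed(31)
  for (tgt in c(0.5, 0.75, 1.0)) {
    b <- hrvt:::beta_for_a1(tgt)
    a1 <- mean(replicate(25, dfa_alpha1(spectral_noise(150, b))))
    expect_equal(a1, tgt, tolerance = 0.1)
  }
  # spectral_noise output is standardized
  x <- spectral_noise(4096, 0.5)
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(sd(x), 1, tolerance = 1e-12)
})

test_that("generated RR series follow the plateau / floor profile", {
  spec <- quick_spec(seed = 8)
  gen <- generate_rr(spec)
  rr <- gen$rr
  rr$corrected <- TRUE
  trace <- time_varying_dfa(rr)
  v <- trace[trace$valid, ]

  plateau <- v[v$t_center_s < spec$decline_start_s - 60, ]
  expect_equal(mean(plateau$a1), spec$a1_plateau, tolerance = 0.15)

  floor_win <- v[v$t_center_s > spec$decline_end_s + 60, ]
  if (nrow(floor_win) >= 5)
    expect_gte(mean(floor_win$a1 < 0.5), 0.9)

  # mean HR over the final 2 min approaches the model maximum
  dur <- rr$beat_times[length(rr$beat_times)]
  last2 <- rr$intervals[rr$beat_times > dur - 120]
  expect_equal(60000 / mean(last2), spec$hr_max, tolerance = 3 / spec$hr_max)

  # reproducibility from the seed
  gen2 <- generate_rr(quick_spec(seed = 8))
  expect_identical(gen$rr$intervals, gen2$rr$intervals)
})

test_that("artifact injection honors rates and stays detectable", {
  spec <- quick_spec(seed = 9)
  rr <- generate_rr(spec)$rr

  set.seed(90)
  same <- inject_artifacts(rr, list(missed = 0, extra = 0, ectopic = 0))
  expect_identical(same$intervals, rr$intervals)

  # extra-beat splits at rate 0.03: injected count is binomial around n * p
  long <- rr_series(rep(800, 10000))
  set.seed(91)
  inj <- inject_artifacts(long, list(extra = 0.03))
  n_events <- length(inj$intervals) - 10000
  expect_gt(n_events, 250)
  expect_lt(n_events, 350)

  # detector sensitivity on missed/extra beats
  set.seed(92)
  inj2 <- inject_artifacts(rr, list(missed = 0.015, extra = 0.015))
  truth <- attr(inj2, "truth")
  det <- detect_artifacts(inj2)
  expect_gte(mean(det$flags[truth] != "normal"), 0.9)

  expect_error(inject_artifacts(rr, list(missed = 0.15, extra = 0.15)),
               "unrealistic")
})

test_that("generated breaths recover the gas-exchange ground truth", {
  spec <- quick_spec(seed = 10)
  br <- generate_breaths(spec)
  expect_identical(attr(br, "stage"), "raw")

  # work at ramp + 60 s: baseline 20 W plus one minute of slope
  w <- protocol_work(spec$protocol, spec$protocol$ramp_start_s + 60)
  expect_equal(w, 20 + 30)

  rolled <- preprocess_breaths(br)
  v_model <- spec$vo2_baseline + spec$vo2_gain * spec$peak_w
  expect_equal(vo2max(rolled)$vo2max_ml_min, v_model,
               tolerance = 0.02)
  expect_equal(hrmax(rolled), spec$hr_max, tolerance = 2 / spec$hr_max)
})

test_that("cohort generation writes coherent files deterministically", {
  d1 <- withr::local_tempdir()
  coh <- generate_cohort(n = 3, slopes = c(15, 45), seed = 3, outdir = d1,
                         artifact_rates = list(missed = 0, extra = 0,
                                               ectopic = 0))
  expect_equal(nrow(coh$manifest), 6)
  expect_equal(nrow(coh$truth), 6)
  expect_length(list.files(d1, pattern = "^rr_"), 6)
  expect_length(list.files(d1, pattern = "^breaths_"), 6)
  expect_true(file.exists(file.path(d1, "manifest.csv")))

  # HR/VO2 truth identical across the two slopes of each participant
  for (id in unique(coh$truth$participant_id)) {
    sub <- coh$truth[coh$truth$participant_id == id, ]
    expect_lt(diff(range(sub$hr_075)), 1e-6)
    expect_lt(diff(range(sub$vo2_075)), 1e-6)
  }

  # same seed reproduces byte-identical outputs
  d2 <- withr::local_tempdir()
  generate_cohort(n = 3, slopes = c(15, 45), seed = 3, outdir = d2,
                  artifact_rates = list(missed = 0, extra = 0, ectopic = 0))
  f <- "truth.csv"
  expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  rrf <- list.files(d1, pattern = "^rr_")[1]
  expect_identical(readLines(file.path(d1, rrf)),
                   readLines(file.path(d2, rrf)))

  # different seeds give different truths
  d3 <- withr::local_tempdir()
  coh3 <- generate_cohort(n = 3, slopes = c(15, 45), seed = 4, outdir = d3,
                          artifact_rates = list(missed = 0, extra = 0,
                                                ectopic = 0))
  expect_false(isTRUE(all.equal(coh$truth$t_075, coh3$truth$t_075)))
})
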