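# a trace declining linearly from a1 = 1.0 at 300 s to 0.4 at 600 s
linear_decline_trace <- function() {
  t <- seq(60, 600, by = 5)
  a1 <- ifelse(t < 300, 1.0, 1.0 - 0.002 * (t - 300))
  hr <- 180 - 40 * a1
  make_trace(t, a1, hr = hr)
}

test_that("segment selection finds the constructed linear decline", {
  tr <- linear_decline_trace()
  proto <- ramp_protocol(slope_w_per_min = 30, baseline1_s = 100,
                         moderate_s = 100, baseline2_s = 100)  # ramp at 300 s
  seg <- select_decline_segment(tr, proto)
  expect_equal(seg$t_start, 300)
  expect_equal(seg$t_end, 550)       # first window with a1 <= 0.5
  expect_equal(seg$slope, -0.002, tolerance = 1e-12)
  expect_equal(seg$intercept, 1.6, tolerance = 1e-12)
  expect_gt(seg$r_squared, 0.999)
  expect_false(seg$low_r2)
})

test_that("flat traces yield a no-decline error", {
  t <- seq(60, 600, by = 5)
  tr <- make_trace(t, rep(0.9, length(t)))
  proto <- ramp_protocol(slope_w_per_min = 30, baseline1_s = 100,
                         moderate_s = 100, baseline2_s = 100)
  expect_error(select_decline_segment(tr, proto), "no decline")
  expect_error(select_decline_segment(tr[1:3, ], proto), "fewer than 5")
})

test_that("manual segment override restricts the fit window", {
  tr <- linear_decline_trace()
  proto <- ramp_protocol(slope_w_per_min = 30, baseline1_s = 100,
                         moderate_s = 100, baseline2_s = 100)
  seg <- select_decline_segment(tr, proto, segment = c(400, 500))
  expect_equal(seg$t_start, 400)
  expect_equal(seg$t_end, 500)
  expect_equal(seg$slope, -0.002, tolerance = 1e-12)
  expect_error(select_decline_segment(tr, proto, segment = c(500, 400)),
               "t0 < t1")
})

test_that("crossing times invert the fitted line", {
  tr <- linear_decline_trace()
  proto <- ramp_protocol(slope_w_per_min = 30, baseline1_s = 100,
                         moderate_s = 100, baseline2_s = 100)
  seg <- select_decline_segment(tr, proto)
  expect_equal(hrvt_time(seg, 0.75)$t_cross, 425, tolerance = 1e-9)
  expect_equal(hrvt_time(seg, 0.5)$t_cross, 550, tolerance = 1e-9)
  expect_false(hrvt_time(seg, 0.75)$extrapolated)
  # level equal to the fitted value at segment start crosses at t_start
  lvl0 <- seg$intercept + seg$slope * seg$t_start
  expect_equal(hrvt_time(seg, lvl0)$t_cross, seg$t_start, tolerance = 1e-9)
  # a level above the fitted start is unreachable
  expect_error(hrvt_time(seg, lvl0 + 0.05), "above the fitted value")
  # a level below the fitted end extrapolates with a flag
  expect_true(hrvt_time(seg, 0.3)$extrapolated)
})

test_that("VO2 mapping reads the rolled series at the nearest second", {
  v <- seq(700, 3500, length.out = 601)   # linear 700 -> 3500 over 0..600 s
  b <- breath_series(0:600, v)
  attr(b, "stage") <- "rolled_20s"
  p <- participant("X", 70, "M")
  expect_equal(hrvt_vo2(300, b, p)$vo2_ml_kg_min, 2100 / 70)
  expect_equal(hrvt_vo2(299.7, b, p)$vo2_ml_kg_min, v[301] / 70)  # nearest
  expect_false(hrvt_vo2(300, b, p)$extrapolated)
  ex <- hrvt_vo2(630, b, p)
  expect_true(ex$extrapolated)
  expect_equal(ex$vo2_ml_kg_min, (3500 + 30 * (3500 - 700) / 600) / 70,
               tolerance = 1e-6)
  expect_error(hrvt_vo2(700, b, p), "beyond the gas-exchange span")
})

test_that("HR mapping evaluates the HR-on-a1 regression at the level", {
  tr <- linear_decline_trace()   # constructed with HR = 180 - 40 * a1
  proto <- ramp_protocol(slope_w_per_min = 30, baseline1_s = 100,
                         moderate_s = 100, baseline2_s = 100)
  seg <- select_decline_segment(tr, proto)
  expect_equal(hrvt_hr(tr, seg, 0.75)$hr_bpm, 150, tolerance = 1e-9)
  expect_equal(hrvt_hr(tr, seg, 0.5)$hr_bpm, 160, tolerance = 1e-9)

  # constant HR across the segment returns that constant
  trc <- linear_decline_trace()
  trc$mean_hr_bpm <- 155
  segc <- select_decline_segment(trc, proto)
  expect_equal(suppressWarnings(hrvt_hr(trc, segc, 0.75)$hr_bpm), 155)
})

test_that("end-to-end estimation recovers a synthetic participant", {
  spec <- quick_spec(seed = 5)
  gen <- generate_rr(spec)
  br <- generate_breaths(spec)
  p <- participant("S", spec$weight_kg, spec$sex, spec$protocol)
  res <- estimate_hrvt(gen$rr, br, p)
  e1 <- res$estimates$hrvt1; e2 <- res$estimates$hrvt2
  expect_false(e1$artifact_exceeded)
  expect_lt(e1$t_cross_s, e2$t_cross_s)       # 0.75 crossed before 0.5
  expect_lte(e1$vo2_ml_kg_min, e2$vo2_ml_kg_min)
  expect_equal(e1$t_cross_s, gen$truth$t_075, tolerance = 30 / gen$truth$t_075)
  expect_equal(e1$hr_bpm, gen$truth$hr_075, tolerance = 5 / gen$truth$hr_075)

  # determinism: identical inputs give bit-identical outputs
  res2 <- estimate_hrvt(gen$rr, br, p)
  expect_identical(res$estimates, res2$estimates)
})

test_that("excess artifact in the decline region raises the quality flag", {
  spec <- quick_spec(seed = 6, slope = 15)
  gen <- generate_rr(spec)
  br <- generate_breaths(spec)
  p <- participant("S", spec$weight_kg, spec$sex, spec$protocol)

  # corrupt a 120-s patch at the start of the decline at ~7% of beats
  rr <- gen$rr
  patch <- which(rr$beat_times >= spec$decline_start_s &
                   rr$beat_times < spec$decline_start_s + 120)
  set.seed(60)
  mid <- inject_artifacts(rr_series(rr$intervals[patch]),
                          list(missed = 0.023, extra = 0.023,
                               ectopic = 0.024))
  dirty <- rr_series(c(rr$intervals[seq_len(patch[1L] - 1L)],
                       mid$intervals,
                       rr$intervals[(patch[length(patch)] + 1L):length(rr)]))
  res <- estimate_hrvt(dirty, br, p)
  expect_true(res$estimates$hrvt1$artifact_exceeded)
  # the clean recording does not raise the flag
  res0 <- estimate_hrvt(gen$rr, br, p)
  expect_false(res0$estimates$hrvt1$artifact_exceeded)
})
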