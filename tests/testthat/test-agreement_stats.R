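test_that("Pearson r and SEE match the closed-form definitions", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_with_see(x, x)$r, 1)
  expect_equal(pearson_with_see(x, x)$see, 0)

  set.seed(21)
  a <- rnorm(10); b <- 2 * a + rnorm(10)
  # affine invariance of r (positive scale)
  expect_equal(pearson_with_see(3 * a + 1, 0.5 * b - 2)$r,
               pearson_with_see(a, b)$r, tolerance = 1e-12)

  # direct-formula oracle
  r_o <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  beta <- sum((a - mean(a)) * (b - mean(b))) / sum((a - mean(a))^2)
  alpha <- mean(b) - beta * mean(a)
  see_o <- sqrt(sum((b - alpha - beta * a)^2) / (10 - 2))
  ps <- pearson_with_see(a, b)
  expect_equal(ps$r, r_o, tolerance = 1e-12)
  expect_equal(ps$see, see_o, tolerance = 1e-12)

  expect_error(pearson_with_see(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("correlation strength labels follow the printed cut-offs", {
  expect_equal(classify_r(0.84), "high")
  expect_equal(classify_r(0.45), "low")
  expect_equal(classify_r(0.55), "unclassified")
  expect_equal(classify_r(0.2), "unclassified")
  expect_equal(classify_r(-0.9), "high")     # magnitude
  expect_equal(classify_r(0.6), "moderate")
  expect_error(classify_r(1.2), "<= 1")
})

test_that("Bland-Altman uses mean difference with exactly 2 SD limits", {
  x <- c(3, 6, 9); y <- x
  ba0 <- bland_altman(x, y)
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))

  y2 <- c(10, 30, 20); x2 <- y2 + c(1, 2, 3)   # d = {1, 2, 3}
  ba <- bland_altman(x2, y2)
  expect_equal(ba$bias, 2)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_low, 0)
  expect_equal(ba$loa_high, 4)

  # antisymmetry under swapping the two conditions
  ba_sw <- bland_altman(y2, x2)
  expect_equal(ba_sw$bias, -ba$bias)
  expect_equal(ba_sw$sd_diff, ba$sd_diff)

  # strong proportional bias switches to regression-based limits
  set.seed(22)
  m <- seq(10, 50, length.out = 30)
  d <- 0.5 * m + rnorm(30, 0, 0.5)
  xp <- m + d / 2; yp <- m - d / 2
  bap <- bland_altman(xp, yp)
  expect_true(bap$proportional_bias)
  expect_lt(bap$prop_p, 0.05)
  expect_lt(bap$loa_high - bap$loa_low, 4 * sd(d))  # residual, not total, SD
})

test_that("ICC(3,1) matches the two-way decomposition oracle", {
  m_same <- matrix(rep(c(10, 20, 30, 40), 3), ncol = 3)
  ic <- icc_3_1(m_same)
  expect_equal(ic$icc, 1)
  expect_equal(ic$ci, c(1, 1))

  set.seed(23)
  for (i in 1:20) {
    m <- outer(rnorm(17, 40, 8), rep(1, 3)) + matrix(rnorm(51, 0, 2), 17)
    ss <- two_way_oracle(m)
    icc_o <- (ss$ms_rows - ss$ms_err) / (ss$ms_rows + 2 * ss$ms_err)
    expect_equal(icc_3_1(m)$icc, icc_o, tolerance = 1e-10)
  }

  # column permutation invariance
  m <- outer(rnorm(10, 40, 8), rep(1, 3)) + matrix(rnorm(30, 0, 2), 10)
  expect_equal(icc_3_1(m[, c(3, 1, 2)])$icc, icc_3_1(m)$icc,
               tolerance = 1e-12)
})

test_that("ICC strength labels follow the printed cut-offs", {
  expect_equal(classify_icc(0.39), "poor")
  expect_equal(classify_icc(0.40), "fair")
  expect_equal(classify_icc(0.60), "good")
  expect_equal(classify_icc(0.74), "good")
  expect_equal(classify_icc(0.88), "excellent")
  expect_equal(classify_icc(0.93), "excellent")
})

test_that("repeated-measures ANOVA matches the decomposition and its null", {
  set.seed(24)
  m <- outer(rnorm(17, 40, 8), rep(1, 3)) + matrix(rnorm(51, 0, 2), 17)
  ss <- two_way_oracle(m)
  an <- rm_anova(m)
  expect_equal(an$f, ss$ms_cols / ss$ms_err, tolerance = 1e-10)
  expect_equal(an$p, pf(an$f, 2, 32, lower.tail = FALSE), tolerance = 1e-12)

  # location invariance
  expect_equal(rm_anova(m + 100)$f, an$f, tolerance = 1e-10)

  # cross-check against the standard aov fit
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(17), 3)),
                   cond = factor(rep(1:3, each = 17)))
  aov_tab <- summary(stats::aov(y ~ cond + Error(subj), data = df))
  f_aov <- aov_tab[["Error: Within"]][[1]]["cond", "F value"]
  expect_equal(an$f, f_aov, tolerance = 1e-8)

  # no condition effect: F has mean about 1 under the null
  fs <- replicate(300, {
    mm <- outer(rnorm(10, 40, 8), rep(1, 3)) + matrix(rnorm(30, 0, 2), 10)
    rm_anova(mm)$f
  })
  expect_gt(mean(fs), 0.75)
  expect_lt(mean(fs), 1.3)
})

test_that("paired t-test guards degeneracy and matches the formula", {
  x <- c(1, 2, 3, 4)
  expect_error(paired_t(x, x), "zero variance")
  expect_error(paired_t(x + 2, x), "zero variance")

  set.seed(25)
  a <- rnorm(12); b <- a + rnorm(12, 0.3, 0.5)
  d <- a - b
  t_o <- mean(d) / (sd(d) / sqrt(12))
  p_o <- 2 * pt(abs(t_o), 11, lower.tail = FALSE)
  tt <- paired_t(a, b)
  expect_equal(tt$t, t_o, tolerance = 1e-12)
  expect_equal(tt$p, p_o, tolerance = 1e-12)
})

test_that("cohort report assembles all pairs, ICCs and exclusions", {
  set.seed(26)
  n <- 8
  base <- list(hrvt1_vo2 = rnorm(n, 32, 5), hrvt1_hr = rnorm(n, 150, 10),
               hrvt2_vo2 = rnorm(n, 40, 5), hrvt2_hr = rnorm(n, 161, 10))
  est <- do.call(rbind, lapply(c(15, 30, 45), function(s) {
    data.frame(participant = sprintf("P%02d", 1:n), slope = s,
               hrvt1_vo2 = base$hrvt1_vo2 + rnorm(n, 0, 1),
               hrvt1_hr = base$hrvt1_hr + rnorm(n, 0, 2),
               hrvt2_vo2 = base$hrvt2_vo2 + rnorm(n, 0, 1),
               hrvt2_hr = base$hrvt2_hr + rnorm(n, 0, 2))
  }))
  # drop one slope of one participant: it must be excluded
  est <- est[!(est$participant == "P03" & est$slope == 45), ]
  rep <- suppressMessages(cohort_report(est))
  expect_equal(rep$excluded, "P03")
  expect_equal(rep$n, 7)
  expect_equal(nrow(rep$pairwise), 4 * 3)   # 4 metrics x 3 slope pairs
  expect_equal(nrow(rep$overall), 4)
  expect_true(all(c("r", "see", "bias", "loa_low", "loa_high", "t_p",
                    "shapiro_p") %in% names(rep$pairwise)))
  expect_true(all(rep$overall$icc <= 1))
})
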