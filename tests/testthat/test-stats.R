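# build a group object directly from a [subject x channel x cond x chrom x
# lag] array, for controlled inputs
fake_group <- function(hrf, lag, conditions) {
  dimnames(hrf) <- list(NULL, NULL, conditions, c("hbo", "hbr"), NULL)
  structure(list(
    hrf = hrf, lag = lag,
    channels = tibble::tibble(channel = seq_len(dim(hrf)[2])),
    conditions = conditions, n_subjects = dim(hrf)[1]
  ), class = "nirs_group_hrf")
}

test_that("ROI averaging is the unweighted channel mean", {
  lag <- seq(-2, 15, by = 0.2)
  conds <- c("x", "y")
  hrf <- array(0, c(2, 3, 2, 2, length(lag)))
  hrf[1, 1, 1, 1, ] <- 1
  hrf[1, 2, 1, 1, ] <- 2
  hrf[1, 3, 1, 1, ] <- 6
  g <- fake_group(hrf, lag, conds)
  roi_map <- tibble::tibble(roi = c("all", "all", "all", "one"),
                            hemisphere = "left", channel = c(1, 2, 3, 2))
  ra <- roi_average(g, roi_map)
  expect_equal(ra$hrf[1, 1, 1, 1, 1], 3)  # mean of 1, 2, 6
  expect_equal(ra$hrf[1, 2, 1, 1, 1], 2)  # single-channel ROI = identity
  # antisymmetric channels cancel
  hrf[2, 1, 1, 1, ] <- 5
  hrf[2, 2, 1, 1, ] <- -5
  hrf[2, 3, 1, 1, ] <- 0
  ra <- roi_average(fake_group(hrf, lag, conds), roi_map)
  expect_equal(ra$hrf[2, 1, 1, 1, ], rep(0, length(lag)))
  # excluded (NA) channels are dropped from the mean; all-NA drops subject
  hrf[1, 2, , , ] <- NA
  ra <- suppressWarnings(roi_average(fake_group(hrf, lag, conds), roi_map))
  expect_equal(ra$hrf[1, 1, 1, 1, 1], 3.5)  # mean of 1, 6
  expect_true(all(is.na(ra$hrf[1, 2, , , ])))
})

test_that("windowed mean peak uses the prescribed windows", {
  lag <- hrf_lag_grid(25)
  conds <- c("a", "b")
  hrf <- array(0, c(1, 1, 2, 2, length(lag)))
  hrf[1, 1, 1, 1, ] <- 7.5                      # constant
  tri <- pmax(0, 1 - abs(lag - 5))              # triangular peak at 5
  hrf[1, 1, 2, 1, ] <- tri
  g <- fake_group(hrf, lag, conds)
  ra <- roi_average(g, tibble::tibble(roi = "r", hemisphere = "left",
                                      channel = 1))
  mp <- mean_peak(ra, "r", "left", c(2, 8), conditions = "a")
  expect_equal(mp$value, 7.5)
  mp <- mean_peak(ra, "r", "left", c(4, 6), conditions = "b")
  # trapezoid oracle for the window mean
  widx <- lag >= 4 & lag <= 6
  lw <- lag[widx]; tw <- tri[widx]
  oracle <- sum(diff(lw) * (head(tw, -1) + tail(tw, -1)) / 2) /
    (max(lw) - min(lw))
  expect_equal(mp$value, oracle, tolerance = 0.03)
  expect_error(mean_peak(ra, "r", "left", c(10, 20)),
               class = "nirsflow_config_error")
  # conventional contrast windows
  dc <- default_contrasts()
  expect_equal(dc$window_start[dc$contrast == "exec_complex_vs_simple"], 2)
  expect_equal(dc$window_end[dc$contrast == "exec_complex_vs_simple"], 8)
  expect_equal(dc[dc$contrast == "obs_complex_vs_control", ]$window_start, 7)
  expect_equal(dc[dc$contrast == "obs_complex_vs_control", ]$window_end, 10)
  expect_equal(dc[dc$contrast == "obs_complex_vs_simple", ]$window_start, 6)
  expect_equal(dc[dc$contrast == "obs_complex_vs_simple", ]$window_end, 12)
})

test_that("paired t follows the closed form and its symmetries", {
  r <- paired_t(c(2, 3, 4), c(1, 1, 1))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-r$t, 2), tolerance = 1e-12)
  # identical samples: no evidence
  r0 <- paired_t(1:5, 1:5)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  expect_true(r0$degenerate)
  # constant non-zero difference: undefined, flagged
  rc <- paired_t(2:6, 1:5)
  expect_true(rc$degenerate)
  expect_true(is.na(rc$p))
  # antisymmetry
  set.seed(2)
  a <- rnorm(15); b <- rnorm(15)
  r1 <- paired_t(a, b); r2 <- paired_t(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  expect_error(paired_t(1, 2), class = "nirsflow_config_error")
})

test_that("Shapiro-Francia detects non-normality with power", {
  # normal scores correlate perfectly with themselves
  z <- qnorm(ppoints(30))
  expect_gt(shapiro_francia(z)$statistic, 0.999)
  set.seed(11)
  rej <- mean(replicate(400, shapiro_francia(runif(50))$p < 0.05))
  expect_gt(rej, 0.3)
  # exponential samples score lower than matched normal samples
  worse <- replicate(50, {
    seed <- sample.int(1e6, 1)
    set.seed(seed); we <- shapiro_francia(rexp(30))$statistic
    set.seed(seed); wn <- shapiro_francia(rnorm(30))$statistic
    we < wn
  })
  expect_gt(mean(worse), 0.9)
  expect_error(shapiro_francia(rep(1, 10)), class = "nirsflow_config_error")
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_true(all(bh_fdr(c(0.01, 0.02, 0.03, 0.04))$reject))
  expect_false(any(bh_fdr(c(0.2, 0.5))$reject))
  expect_true(bh_fdr(0.001)$reject)
  # brute-force step-up oracle on random vectors
  step_up <- function(p, q) {
    m <- length(p)
    o <- order(p)
    k <- which(p[o] <= seq_len(m) * q / m)
    rej <- logical(m)
    if (length(k) > 0) rej[o[seq_len(max(k))]] <- TRUE
    rej
  }
  set.seed(8)
  for (i in 1:200) {
    p <- runif(sample(1:20, 1))^sample(1:3, 1)
    expect_identical(bh_fdr(p)$reject, step_up(p, 0.05))
  }
})

test_that("confidence bands are mean +/- t-quantile times the SE", {
  cb <- confidence_band(matrix(c(0, 2), 2, 1))
  expect_equal(cb$mean, 1)
  expect_equal(cb$se, 1)
  expect_equal(cb$upper - cb$mean, qt(0.975, 1), tolerance = 1e-9)
  # identical subjects give a zero-width band
  cb <- confidence_band(matrix(5, 4, 3))
  expect_equal(cb$lower, cb$upper)
  expect_error(confidence_band(matrix(1, 1, 3)),
               class = "nirsflow_config_error")
})

test_that("band width shrinks like one over the square root of n", {
  set.seed(4)
  # from n >= 20 the t-quantile is nearly constant and the 1/sqrt(n)
  # scaling of the standard error dominates
  ns <- c(20, 40, 80, 160, 320)
  widths <- sapply(ns, function(n) {
    mean(replicate(40, {
      cb <- confidence_band(matrix(rnorm(n * 5), n, 5))
      mean(cb$upper - cb$lower)
    }))
  })
  slope <- unname(coef(lm(log(widths) ~ log(ns)))[2])
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("time to peak finds the HbO maximum and HbR trough after onset", {
  lag <- hrf_lag_grid(25)
  h <- canonical_hrf(lag, peak_time = 5)
  r <- time_to_peak(h, lag, "hbo")
  expect_equal(r$time_to_peak, 5, tolerance = 1 / 25 + 1e-9)
  expect_false(r$boundary)
  # HbR as a negated, delayed copy returns the delayed trough
  h2 <- -canonical_hrf(lag - 2, peak_time = 5)
  r2 <- time_to_peak(h2, lag, "hbr")
  expect_equal(r2$time_to_peak, 7, tolerance = 1 / 25 + 1e-9)
  # pre-onset values never win even if extreme
  h3 <- h; h3[lag < 0] <- 10
  expect_equal(time_to_peak(h3, lag, "hbo")$time_to_peak, 5,
               tolerance = 0.1)
  # monotone series peaks on the boundary, flagged
  r4 <- time_to_peak(lag, lag, "hbo")
  expect_equal(r4$time_to_peak, 15)
  expect_true(r4$boundary)
  expect_true(time_to_peak(rep(1, length(lag)), lag, "hbo")$flat)
})
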