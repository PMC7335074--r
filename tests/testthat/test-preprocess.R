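make_scan <- function(intensity, probe = small_probe(), fs = 25) {
  spec <- small_design()
  structure(list(
    intensity = intensity, wavelengths = c(690, 830), sampling_rate = fs,
    schedule = generate_schedule(spec, 1), probe = probe, run_id = 1L
  ), class = "nirs_scan")
}

test_that("optical density conversion follows -ln(I / mean I)", {
  p <- small_probe()
  n <- 2000
  nc <- nrow(p$channels)
  # constant intensity -> zero OD
  scan <- make_scan(array(5e4, c(n, nc, 2)), p)
  od <- intensity_to_od(scan)
  expect_true(all(abs(od$od) < 1e-12))
  # single-sample dip of exp(-0.1) -> OD ~ 0.1 at that sample
  i <- array(1e5, c(n, nc, 2))
  i[500, 1, 1] <- 1e5 * exp(-0.1)
  od <- intensity_to_od(make_scan(i, p))
  expect_equal(od$od[500, 1, 1], 0.1, tolerance = 1e-3)
  expect_lt(max(abs(od$od[-500, 1, 1])), 1e-4)
})

test_that("non-positive samples exclude the channel with a reason", {
  p <- small_probe()
  i <- array(1e5, c(500, nrow(p$channels), 2))
  i[100, 2, 2] <- -1
  od <- intensity_to_od(make_scan(i, p))
  expect_equal(od$excluded$channel, p$channels$channel[2])
  expect_equal(od$excluded$reason, "nonpositive")
  expect_true(all(is.na(od$od[, 2, ])))
  expect_false(anyNA(od$od[, -2, ]))
})

test_that("channel pruning applies the dB keep-range at both wavelengths", {
  p <- small_probe()
  nc <- nrow(p$channels)
  lvl <- function(db) 10^(db / 20)
  i <- array(lvl(100), c(100, nc, 2))
  i[, 1, ] <- lvl(70)      # too dim at both
  i[, 2, 2] <- lvl(150)    # saturated at one wavelength only
  i[, 3, ] <- lvl(80)      # exactly at the floor: kept (inclusive)
  pr <- prune_channels(make_scan(i, p))
  expect_false(pr$keep[1])
  expect_equal(pr$reason[1], "below_range")
  expect_false(pr$keep[2])
  expect_equal(pr$reason[2], "above_range")
  expect_true(all(pr$keep[3:nc]))
  expect_true(all(is.na(pr$reason[3:nc])))
})

test_that("widening the keep-range never excludes a kept channel", {
  p <- small_probe()
  nc <- nrow(p$channels)
  set.seed(42)
  for (rep in 1:20) {
    db <- runif(nc, 60, 160)
    i <- array(rep(10^(db / 20), each = 50), c(50, nc, 2))
    scan <- make_scan(i, p)
    narrow <- prune_channels(scan, 85, 130)$keep
    wide <- prune_channels(scan, 80, 140)$keep
    expect_true(all(wide[narrow]))
  }
})

test_that("motion correction leaves artifact-free recordings nearly unchanged", {
  spec <- design_spec()
  p <- default_probe()
  sch <- generate_schedule(spec, 1)
  tp <- truth_params(p, spec, n_spikes = 0, n_shifts = 0)
  sim <- simulate_scan(p, sch, tp, seed = 21)
  od <- intensity_to_od(sim$scan)
  odc <- correct_motion(od)
  for (w in 1:2) {
    expect_gt(cor(c(od$od[, , w]), c(odc$od[, , w])), 0.99)
  }
})

test_that("spline stage removes spikes and re-levels baseline shifts", {
  spec <- design_spec()
  p <- default_probe()
  sch <- generate_schedule(spec, 1)
  tp <- truth_params(p, spec, n_spikes = 0, n_shifts = 0)
  sim <- simulate_scan(p, sch, tp, seed = 22)
  clean <- intensity_to_od(sim$scan)
  fs <- 25
  tgrid <- (seq_len(dim(clean$od)[1]) - 1) / fs

  # spike: 10x the signal SD, 0.4 s FWHM, on one channel's intensity
  i <- sim$scan$intensity
  sdc <- sd(i[, 5, 1])
  bell <- exp(-(tgrid - 100)^2 / (2 * (0.4 / 2.355)^2))
  i[, 5, 1] <- i[, 5, 1] + 10 * sdc * bell
  od_art <- intensity_to_od(make_scan(i, p))
  dev_before <- max(abs(od_art$od[, 5, 1] - clean$od[, 5, 1]))
  odc <- correct_motion(od_art)
  dev_after <- max(abs(odc$od[tgrid > 95 & tgrid < 105, 5, 1] -
                       clean$od[tgrid > 95 & tgrid < 105, 5, 1]))
  expect_lt(dev_after, 0.2 * dev_before)

  # shift: 5x SD step at t = 200 s
  i <- sim$scan$intensity
  sdc <- sd(i[, 8, 2])
  i[, 8, 2] <- i[, 8, 2] + 5 * sdc * (tgrid >= 200)
  od_art <- intensity_to_od(make_scan(i, p))
  lvl <- function(x) mean(x[tgrid > 210 & tgrid < 240]) -
    mean(x[tgrid > 160 & tgrid < 190])
  shift_before <- lvl(od_art$od[, 8, 2]) - lvl(clean$od[, 8, 2])
  odc <- correct_motion(od_art)
  shift_after <- lvl(odc$od[, 8, 2]) - lvl(clean$od[, 8, 2])
  expect_lt(abs(shift_after), 0.2 * abs(shift_before))

  expect_error(correct_motion(clean, window = 1e5),
               class = "nirsflow_config_error")
})

test_that("Savitzky-Golay smoothing matches the reference filter", {
  kern <- nirsflow:::sg_kernel(3, 75)
  set.seed(1)
  x <- matrix(rnorm(2000 * 2), 2000, 2)
  ours <- nirsflow:::fir_reflect(x, kern)
  ref <- apply(x, 2, function(v) signal::sgolayfilt(v, p = 3, n = 75))
  # identical away from the edges (edge policies differ)
  expect_equal(ours[100:1900, ], ref[100:1900, ], tolerance = 1e-10)
})

test_that("zero-phase band-pass has the designed frequency response", {
  fs <- 25
  t <- seq(0, 400 - 1 / fs, by = 1 / fs)
  mid <- t > 100 & t < 300
  # 1.0 Hz attenuated by at least 20 dB
  x <- sin(2 * pi * 1.0 * t)
  y <- bandpass_filter(x, sampling_rate = fs)
  expect_lt(sqrt(mean(y[mid]^2)) / sqrt(mean(x[mid]^2)), 0.1)
  # 0.1 Hz passes with gain within 5%
  x <- sin(2 * pi * 0.1 * t)
  y <- bandpass_filter(x, sampling_rate = fs)
  expect_equal(sqrt(mean(y[mid]^2)) / sqrt(mean(x[mid]^2)), 1,
               tolerance = 0.05)
  # DC rejected
  y <- bandpass_filter(rep(3, length(t)), sampling_rate = fs)
  expect_lt(max(abs(y)), 1e-9)
  # cutoff above Nyquist is a configuration error
  expect_error(bandpass_filter(x, high = 13, sampling_rate = fs),
               class = "nirsflow_config_error")
})

test_that("band-pass agrees with filtfilt away from the edges", {
  fs <- 25
  set.seed(7)
  x <- cumsum(rnorm(10000)) / 50 + sin(2 * pi * 0.2 * seq_len(10000) / fs)
  ours <- bandpass_filter(x, sampling_rate = fs)
  bf <- signal::butter(3, c(0.01, 0.5) / (fs / 2), type = "pass")
  ref <- signal::filtfilt(bf, x - mean(x))
  mid <- 2000:8000
  expect_gt(cor(ours[mid], ref[mid]), 0.999)
  expect_equal(sd(ours[mid]) / sd(ref[mid]), 1, tolerance = 0.02)
})

test_that("the MBLL is linear and scales inversely with pathlength", {
  p <- small_probe()
  n <- 500
  nc <- nrow(p$channels)
  set.seed(3)
  scan <- make_scan(array(1e5, c(n, nc, 2)), p)
  od1 <- intensity_to_od(scan)
  od1$od <- array(rnorm(n * nc * 2, sd = 1e-3), c(n, nc, 2))
  od2 <- od1
  od2$od <- array(rnorm(n * nc * 2, sd = 1e-3), c(n, nc, 2))
  c1 <- mbll(od1)
  c2 <- mbll(od2)
  mixed <- od1
  mixed$od <- 2 * od1$od - 3 * od2$od
  cm <- mbll(mixed)
  expect_equal(cm$hbo, 2 * c1$hbo - 3 * c2$hbo, tolerance = 1e-12)
  expect_equal(cm$hbr, 2 * c1$hbr - 3 * c2$hbr, tolerance = 1e-12)
  # zero OD -> zero concentration
  odz <- od1
  odz$od[] <- 0
  expect_true(all(mbll(odz)$hbo == 0))
  # doubling the ppf (pathlength) halves the concentrations
  expect_equal(mbll(od1, ppf = 12)$hbo, c1$hbo / 2, tolerance = 1e-12)
})

test_that("block-mean resampling is exact and validated", {
  p <- small_probe()
  n <- 100
  nc <- nrow(p$channels)
  od <- intensity_to_od(make_scan(array(1e5, c(n, nc, 2)), p))
  od$od <- array(seq_len(n * nc * 2), c(n, nc, 2))
  r <- resample_od(od, 5)
  expect_equal(dim(r$od)[1], 20)
  expect_equal(r$od[1, 1, 1], mean(od$od[1:5, 1, 1]))
  expect_equal(r$sampling_rate, 5)
  expect_equal(r$native_rate, 25)
  expect_error(resample_od(od, 7), class = "nirsflow_config_error")
})

test_that("the full chain composes and drops pruned channels", {
  spec <- small_design(run_duration = 80)
  p <- small_probe()
  tp <- truth_params(p, spec)
  sim <- simulate_scan(p, generate_schedule(spec, 3), tp, seed = 6)
  sim$scan$intensity[, 2, ] <- sim$scan$intensity[, 2, ] / 1e3  # ~40 dB
  conc <- preprocess(sim$scan, resample = 5)
  long_pos <- match(conc$excluded$channel, conc$channels$channel)
  expect_equal(conc$excluded$reason, "below_range")
  expect_true(all(is.na(conc$hbo[, long_pos])))
  expect_false(anyNA(conc$hbo[, -long_pos]))
  expect_equal(conc$sampling_rate, 5)
})
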