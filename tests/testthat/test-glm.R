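test_that("the Gaussian basis has the documented structure", {
  b <- hrf_basis()
  expect_equal(length(b$means), 18)
  expect_equal(b$means, seq(-2, 15))
  m <- basis_matrix(b, b$means)
  expect_equal(diag(m), rep(1, 18))           # unit peak at each mean
  # partition of unity (up to a constant) in the window interior
  lags <- seq(1, 12, by = 0.05)
  s <- rowSums(basis_matrix(b, lags))
  expect_lt((max(s) - min(s)) / mean(s), 1e-3)
  expect_error(hrf_basis(spacing = 0), class = "nirsflow_config_error")
})

test_that("short-separation selection maximizes signed correlation", {
  spec <- small_design(run_duration = 80)
  p <- small_probe()
  n <- spec$run_duration * spec$sampling_rate
  set.seed(5)
  ss <- matrix(rnorm(n * 1), n, 1)
  conc <- structure(list(
    hbo = cbind(ss[, 1] + rnorm(n, sd = 0.1), rnorm(n)),
    hbr = cbind(rnorm(n), rnorm(n)),
    ss_hbo = ss, ss_hbr = ss,
    channels = tibble::tibble(channel = 1:2),
    ss_channels = tibble::tibble(channel = 9L),
    sampling_rate = 25
  ), class = "nirs_conc")
  sel <- select_ss_channel(conc, "hbo")
  expect_equal(sel$ss_channel[1], 9L)
  expect_gt(sel$r[1], 0.9)

  # signed maximum: a weakly positive candidate beats a strongly negative one
  base <- rnorm(n)
  cand_neg <- -0.9 * base + rnorm(n, sd = 0.2)
  cand_pos <- 0.2 * base + rnorm(n, sd = 1)
  conc$hbo <- cbind(base, base)
  conc$ss_hbo <- cbind(cand_neg, cand_pos)
  conc$ss_channels <- tibble::tibble(channel = c(11L, 12L))
  sel <- select_ss_channel(conc, "hbo")
  expect_equal(sel$ss_channel[1], 12L)

  # identical candidates tie to the lowest index
  conc$ss_hbo <- cbind(base, base)
  sel <- select_ss_channel(conc, "hbo")
  expect_equal(sel$ss_channel, c(11L, 11L))

  # zero-variance candidates are skipped; none usable -> NA with a warning
  conc$ss_hbo <- cbind(rep(1, n), rep(2, n))
  conc$ss_hbr <- conc$ss_hbo
  expect_warning(sel <- select_ss_channel(conc, "hbo"), "short-separation")
  expect_true(all(is.na(sel$ss_channel)))
})

test_that("noiseless deconvolution recovers the injected response", {
  spec <- design_spec()
  p <- default_probe()
  schs <- lapply(1:3, function(r) generate_schedule(spec, r, r))
  tp <- quiet_truth(p, spec)
  sim <- simulate_subject(p, schs, tp, seed = 31)
  concs <- lapply(sim$runs, function(s)
    preprocess(s, motion = NULL, bandpass = NULL))
  fit <- suppressWarnings(fit_hrf_glm(bind_runs(concs), ss = FALSE))
  pk <- max(abs(sim$truth$hrf))
  expect_lt(max(abs(fit$hrf - sim$truth$hrf)), 0.01 * pk)
  # lag grid is the full-rate -2..15 s grid
  expect_equal(length(fit$lag), 426)
  expect_equal(range(fit$lag), c(-2, 15))
})

test_that("zero signal yields an identically zero response", {
  spec <- small_design(run_duration = 80)
  p <- small_probe()
  sch <- generate_schedule(spec, 2)
  tp <- quiet_truth(p, spec, base_amp = 0)
  sim <- simulate_scan(p, sch, tp, seed = 8)
  conc <- preprocess(sim$scan, motion = NULL, bandpass = NULL)
  fit <- suppressWarnings(fit_hrf_glm(conc, ss = FALSE))
  expect_lt(max(abs(fit$hrf)), 1e-18)
})

test_that("baseline correction zeroes the pre-onset window exactly", {
  spec <- small_design(run_duration = 80)
  p <- small_probe()
  tp <- truth_params(p, spec)
  sim <- simulate_scan(p, generate_schedule(spec, 2), tp, seed = 13)
  fit <- fit_hrf_glm(preprocess(sim$scan))
  bl <- fit$lag <= 0
  base_means <- apply(fit$hrf[, , , bl, drop = FALSE], 1:3, mean)
  expect_lt(max(abs(base_means), na.rm = TRUE), 1e-12)
})

test_that("the estimate is exactly equivariant under scaling", {
  spec <- small_design(run_duration = 80)
  p <- small_probe()
  tp <- truth_params(p, spec)
  sim <- simulate_scan(p, generate_schedule(spec, 2), tp, seed = 14)
  conc <- preprocess(sim$scan)
  fit1 <- fit_hrf_glm(conc)
  conc2 <- conc
  for (f in c("hbo", "hbr", "ss_hbo", "ss_hbr")) conc2[[f]] <- 3 * conc2[[f]]
  fit2 <- fit_hrf_glm(conc2)
  expect_equal(fit2$hrf, 3 * fit1$hrf, tolerance = 1e-12)
})

test_that("the shared-design solver equals an explicit QR fit", {
  spec <- small_design(run_duration = 80)
  p <- small_probe()
  tp <- truth_params(p, spec)
  sim <- simulate_scan(p, generate_schedule(spec, 2), tp, seed = 15)
  conc <- preprocess(sim$scan)
  design <- build_glm_design(list(conc$schedule),
                             hrf_basis(sampling_rate = 25),
                             drift_order = 3,
                             decimate = 25 / conc$sampling_rate)
  fit <- fit_hrf_glm(conc, design)
  sel <- fit$ss_selected
  for (j in c(1L, 3L)) {
    sid <- sel$ss_channel[sel$chromophore == "hbo"][j]
    s <- conc$ss_hbo[, match(sid, conc$ss_channels$channel)]
    s <- (s - mean(s)) / sd(s)
    xx <- cbind(design$x, s)
    ref <- stats::lm.fit(xx, conc$hbo[, j])$coefficients
    ours <- fit$coefficients[j, 1, ]
    expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
  }
})

test_that("decimated and native-rate fits agree on noiseless data", {
  spec <- small_design(run_duration = 80)
  p <- small_probe()
  sch <- generate_schedule(spec, 2)
  tp <- quiet_truth(p, spec)
  sim <- simulate_scan(p, sch, tp, seed = 16)
  c25 <- preprocess(sim$scan, motion = NULL, bandpass = NULL)
  c5 <- preprocess(sim$scan, motion = NULL, bandpass = NULL, resample = 5)
  f25 <- suppressWarnings(fit_hrf_glm(c25, ss = FALSE))
  f5 <- suppressWarnings(fit_hrf_glm(c5, ss = FALSE))
  expect_equal(f5$hrf, f25$hrf, tolerance = 1e-6)
  expect_equal(length(f5$lag), length(f25$lag))
})

test_that("short-separation regression reduces superficial contamination", {
  spec <- design_spec()
  p <- default_probe()
  sch <- generate_schedule(spec, 1)
  tp <- truth_params(p, spec, n_spikes = 0, n_shifts = 0)
  rmse_ss <- rmse_no <- numeric(4)
  for (k in 1:4) {
    sim <- simulate_scan(p, sch, tp, seed = 400 + k)
    conc <- preprocess(sim$scan, resample = 5)
    f1 <- fit_hrf_glm(conc, ss = TRUE)
    f0 <- fit_hrf_glm(conc, ss = FALSE)
    rmse_ss[k] <- sqrt(mean((f1$hrf - sim$truth$hrf)^2, na.rm = TRUE))
    rmse_no[k] <- sqrt(mean((f0$hrf - sim$truth$hrf)^2, na.rm = TRUE))
  }
  expect_lt(mean(rmse_ss), mean(rmse_no))
})

test_that("tidy and glance summarize a fit", {
  spec <- small_design(run_duration = 80)
  p <- small_probe()
  tp <- truth_params(p, spec)
  sim <- simulate_scan(p, generate_schedule(spec, 2), tp, seed = 17)
  fit <- fit_hrf_glm(preprocess(sim$scan))
  td <- tidy(fit)
  expect_equal(nrow(td), 5 * 2 * 2 * length(fit$lag))
  expect_named(td, c("channel", "condition", "chromophore", "lag",
                     "estimate"))
  gl <- glance(fit)
  expect_equal(gl$n_channels, 5)
  expect_true(gl$ss_used)
})
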