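#' Ground-truth parameters for the forward simulator
#'
#' Describes everything the simulator injects into a synthetic subject:
#' condition-locked hemodynamic responses with per-channel amplitudes,
#' globally coherent systemic physiology (cardiac, respiratory, Mayer waves),
#' superficial (scalp) contamination shared between co-located short- and
#' long-separation channels, slow drifts, motion artifacts, and white
#' measurement noise on the detector intensities.
#'
#' Response amplitudes are composed multiplicatively from four sources of
#' variability, all drawn per subject: a global subject gain
#' (`N(1, subject_gain_sd^2)`), a subject-by-condition modulation shared
#' across all channels (`N(1, cond_mod_sd^2)`, modelling session-level
#' vigilance/arousal effects on the neurovascular response), a
#' subject-by-region responsiveness shared across conditions
#' (`N(1, region_mod_sd^2)`), and a small independent residual
#' (`resid_amp_sd`, molar). The shared condition modulation makes paired
#' condition differences positively correlated across regions, as global
#' physiological modulation does in real group data.
#'
#' @param layout A `nirs_probe`.
#' @param spec A [design_spec()].
#' @param base_amp Baseline HbO response peak amplitude (molar) for every
#'   long channel and condition.
#' @param effects Optional tibble (`roi`, `hemisphere`, `condition`, `delta`)
#'   of additional HbO peak amplitude (molar) injected into the channels of
#'   the named regions; this is the ground-truth "activation" that group
#'   statistics should recover.
#' @param roi_map ROI map used to resolve `effects` and the regional
#'   variability component.
#' @param hrf_shapes Per-condition response shape table (see
#'   [canonical_hrf()]); defaults give execution conditions an early (6 s)
#'   peak with a 3 s delayed HbR trough and observation/control conditions a
#'   late (10 s) peak with a matched HbR trough.
#' @param hbr_ratio HbR amplitude as a (positive) fraction of HbO; the HbR
#'   response is `-hbr_ratio` times the (possibly delayed) HbO shape.
#' @param subject_gain_sd,cond_mod_sd,region_mod_sd,resid_amp_sd Amplitude
#'   variance components (see above).
#' @param physiology Tibble (`component`, `freq`, `hbo_amp`, `hbr_amp`) of
#'   systemic oscillations (Hz, molar); `NULL` disables.
#' @param physio_gain_sd Log-normal sd of per-channel physiology gains.
#' @param superficial_amp Scalp contamination amplitude (molar HbO
#'   equivalent); one smooth band-limited series per hemisphere, gain 1 on
#'   short channels and `superficial_long_gain` (range) on long channels.
#' @param superficial_fmax Bandwidth of the superficial series (Hz).
#' @param superficial_long_gain Length-2 range of long-channel gains.
#' @param superficial_hbr HbR fraction of the superficial series.
#' @param drift_amp Slow drift amplitude (molar); per-channel random very-low
#'   frequency components plus a linear trend.
#' @param n_spikes,n_shifts Motion artifacts per run (0 disables).
#' @param spike_mag,shift_mag Artifact magnitude in multiples of the
#'   per-channel intensity SD (random sign).
#' @param spike_fwhm Spike full width at half maximum (s).
#' @param artifact_frac Fraction of channels affected by each artifact event.
#' @param baseline_intensity Detector DC level (arbitrary units); the default
#'   1e5 sits at 100 dB under the `20 log10` convention, inside the 80-140 dB
#'   keep-range.
#' @param noise_sd_frac White measurement noise SD as a fraction of
#'   `baseline_intensity`.
#' @param ppf Partial pathlength factor used by the forward Beer-Lambert
#'   model (and by [mbll()] on the way back).
#' @param keep_conc If `TRUE` the ground truth retains the full true
#'   concentration time series (needed by round-trip tests; off in large
#'   group simulations to save memory).
#' @return A `nirs_truth_params` list.
#' @export
truth_params <- function(layout, spec,
                         base_amp = 0.4e-6,
                         effects = NULL,
                         roi_map = tryCatch(default_roi_map(layout),
                                            error = function(e) NULL),
                         hrf_shapes = default_hrf_shapes(spec$conditions),
                         hbr_ratio = 1 / 3,
                         subject_gain_sd = 0.15,
                         cond_mod_sd = 0.2,
                         region_mod_sd = 0.25,
                         resid_amp_sd = 0.03e-6,
                         physiology = tibble(
                           component = c("cardiac", "respiratory", "mayer"),
                           freq = c(1.1, 0.25, 0.095),
                           hbo_amp = c(0.10e-6, 0.08e-6, 0.15e-6),
                           hbr_amp = c(-0.025e-6, -0.02e-6, -0.04e-6)
                         ),
                         physio_gain_sd = 0.3,
                         superficial_amp = 0.25e-6,
                         superficial_fmax = 0.3,
                         superficial_long_gain = c(0.4, 1),
                         superficial_hbr = -0.25,
                         drift_amp = 0.5e-6,
                         n_spikes = 2, n_shifts = 1,
                         spike_mag = 10, shift_mag = 5,
                         spike_fwhm = 0.4,
                         artifact_frac = 0.25,
                         baseline_intensity = 1e5,
                         noise_sd_frac = 0.003,
                         ppf = 6,
                         keep_conc = FALSE) {
  if (baseline_intensity <= 0) {
    abort("baseline_intensity must be positive", class = "nirsflow_config_error")
  }
  if (noise_sd_frac < 0) {
    abort("noise SD must be non-negative", class = "nirsflow_config_error")
  }
  long <- layout$channels[layout$channels$type == "long", ]
  amp <- matrix(base_amp, nrow(long), length(spec$conditions),
                dimnames = list(NULL, spec$conditions))
  if (!is.null(effects) && nrow(effects) > 0) {
    if (is.null(roi_map)) {
      abort("effects require an ROI map for this layout",
            class = "nirsflow_config_error")
    }
    for (k in seq_len(nrow(effects))) {
      chans <- roi_map$channel[roi_map$roi == effects$roi[k] &
                               roi_map$hemisphere == effects$hemisphere[k]]
      rows <- match(chans, long$channel)
      amp[rows, effects$condition[k]] <-
        amp[rows, effects$condition[k]] + effects$delta[k]
    }
  }
  structure(list(
    amplitudes = amp, effects = effects, roi_map = roi_map,
    hrf_shapes = hrf_shapes, hbr_ratio = hbr_ratio,
    subject_gain_sd = subject_gain_sd, cond_mod_sd = cond_mod_sd,
    region_mod_sd = region_mod_sd, resid_amp_sd = resid_amp_sd,
    physiology = physiology, physio_gain_sd = physio_gain_sd,
    superficial_amp = superficial_amp, superficial_fmax = superficial_fmax,
    superficial_long_gain = superficial_long_gain,
    superficial_hbr = superficial_hbr,
    drift_amp = drift_amp,
    n_spikes = n_spikes, n_shifts = n_shifts,
    spike_mag = spike_mag, shift_mag = shift_mag, spike_fwhm = spike_fwhm,
    artifact_frac = artifact_frac,
    baseline_intensity = baseline_intensity, noise_sd_frac = noise_sd_frac,
    ppf = ppf, keep_conc = keep_conc
  ), class = "nirs_truth_params")
}

# band-limited unit-variance noise via random spectrum below fmax
bandlimited_noise <- function(n, fs, fmax) {
  nf <- nextn(n, c(2, 3, 5))
  f <- fs * (seq_len(nf) - 1) / nf
  keep <- pmin(f, fs - f) <= fmax & f > 0
  z <- complex(real = rnorm(nf), imaginary = rnorm(nf))
  z[!keep] <- 0
  x <- Re(fft(z, inverse = TRUE))[seq_len(n)]
  s <- sd(x)
  if (s > 0) x / s else x
}

# subject-level random draws shared across that subject's runs
draw_subject_effects <- function(truth, layout, conditions) {
  long <- layout$channels[layout$channels$type == "long", ]
  n_long <- nrow(long)
  n_short <- sum(layout$channels$type == "short")
  gain <- max(0.2, 1 + rnorm(1, 0, truth$subject_gain_sd))
  cond_mod <- pmax(0.2, 1 + rnorm(length(conditions), 0, truth$cond_mod_sd))
  if (!is.null(truth$roi_map)) {
    rois <- unique(paste(truth$roi_map$roi, truth$roi_map$hemisphere))
    region_mod <- pmax(0.2, 1 + rnorm(length(rois), 0, truth$region_mod_sd))
    names(region_mod) <- rois
    ch_roi <- paste(truth$roi_map$roi, truth$roi_map$hemisphere)[
      match(long$channel, truth$roi_map$channel)]
    region_by_channel <- region_mod[ch_roi]
    region_by_channel[is.na(region_by_channel)] <- 1
  } else {
    region_mod <- NULL
    region_by_channel <- rep(1, n_long)
  }
  amp <- truth$amplitudes * gain *
    (region_by_channel %o% rep(1, ncol(truth$amplitudes)))
  amp <- sweep(amp, 2, cond_mod, "*")
  amp <- amp + matrix(rnorm(length(amp), 0, truth$resid_amp_sd),
                      nrow(amp), ncol(amp)) * (truth$amplitudes != 0)
  n_phys <- if (is.null(truth$physiology)) 0 else nrow(truth$physiology)
  physio_gain <- if (n_phys > 0) {
    matrix(exp(rnorm((n_long + n_short) * n_phys, 0, truth$physio_gain_sd)),
           n_long + n_short, n_phys)
  } else NULL
  sup_gain <- c(runif(n_long, truth$superficial_long_gain[1],
                      truth$superficial_long_gain[2]),
                rep(1, n_short))
  list(amp = amp, physio_gain = physio_gain, sup_gain = sup_gain,
       gain = gain, cond_mod = cond_mod, region_mod = region_mod)
}

# condition event trains convolved with unit-peak response kernels;
# onsets are discretized to the nearest sample
condition_responses <- function(schedule, fs, n, kernels) {
  conditions <- colnames(kernels)
  klen <- nrow(kernels)
  out <- matrix(0, n, length(conditions),
                dimnames = list(NULL, conditions))
  for (e in seq_len(nrow(schedule$events))) {
    c_idx <- match(schedule$events$condition[e], conditions)
    i0 <- round(schedule$events$onset[e] * fs) + 1L
    idx <- i0:min(n, i0 + klen - 1L)
    out[idx, c_idx] <- out[idx, c_idx] + kernels[seq_along(idx), c_idx]
  }
  out
}

sim_run <- function(layout, schedule, truth, sub, run_seed) {
  spec <- schedule$spec
  fs <- spec$sampling_rate
  n <- round(spec$run_duration * fs)
  ch <- layout$channels
  long_idx <- which(ch$type == "long")
  n_ch <- nrow(ch)
  conditions <- spec$conditions
  tgrid <- (seq_len(n) - 1) / fs

  shp <- truth$hrf_shapes[match(conditions, truth$hrf_shapes$condition), ]
  klag <- seq(0, max(shp$support_end), by = 1 / fs)
  kern <- condition_kernels(shp, klag)
  k_hbo <- kern$hbo
  k_hbr <- kern$hbr

  with_seed(run_seed, {
    # all series are [time x channel]
    e_hbo <- condition_responses(schedule, fs, n, k_hbo)
    e_hbr <- condition_responses(schedule, fs, n, k_hbr)
    hbo <- matrix(0, n, n_ch)
    hbr <- matrix(0, n, n_ch)
    hbo[, long_idx] <- e_hbo %*% t(sub$amp)
    hbr[, long_idx] <- e_hbr %*% t(-truth$hbr_ratio * sub$amp)

    if (!is.null(truth$physiology) && nrow(truth$physiology) > 0) {
      ph <- truth$physiology
      phase <- runif(nrow(ph), 0, 2 * pi)
      s <- sapply(seq_len(nrow(ph)),
                  function(i) sin(2 * pi * ph$freq[i] * tgrid + phase[i]))
      hbo <- hbo + s %*% t(sub$physio_gain * rep(ph$hbo_amp, each = n_ch))
      hbr <- hbr + s %*% t(sub$physio_gain * rep(ph$hbr_amp, each = n_ch))
    }

    superficial <- NULL
    if (truth$superficial_amp > 0) {
      hemis <- unique(ch$hemisphere)
      superficial <- sapply(hemis, function(h)
        bandlimited_noise(n, fs, truth$superficial_fmax))
      colnames(superficial) <- hemis
      # channel table is ordered long-first, matching sup_gain
      w <- matrix(0, n_ch, length(hemis))
      w[cbind(seq_len(n_ch), match(ch$hemisphere, hemis))] <- sub$sup_gain
      hbo <- hbo + truth$superficial_amp * (superficial %*% t(w))
      hbr <- hbr + truth$superficial_amp * truth$superficial_hbr *
        (superficial %*% t(w))
    }

    if (truth$drift_amp > 0) {
      f1 <- runif(n_ch, 0.002, 0.008)
      ph1 <- runif(n_ch, 0, 2 * pi)
      slope <- rnorm(n_ch, 0, 0.5)
      dr <- truth$drift_amp *
        (sin(outer(tgrid, 2 * pi * f1) + rep(ph1, each = n)) +
           (tgrid / spec$run_duration) %o% slope)
      hbo <- hbo + dr
      hbr <- hbr + 0.3 * dr
    }

    # forward modified Beer-Lambert per wavelength
    eps <- extinction_coefficients(log_base = "e")
    path <- ch$separation * truth$ppf
    i0 <- truth$baseline_intensity
    fw <- forward_intensity(hbo, hbr, path, eps[1, "hbo"], eps[1, "hbr"],
                            eps[2, "hbo"], eps[2, "hbr"], i0,
                            noise_sd = truth$noise_sd_frac * i0)
    i1 <- fw[[1]]
    i2 <- fw[[2]]

    artifacts <- NULL
    n_art <- truth$n_spikes + truth$n_shifts
    if (n_art > 0) {
      types <- c(rep("spike", truth$n_spikes), rep("shift", truth$n_shifts))
      times <- runif(n_art, 5, spec$run_duration - 5)
      artifacts <- tibble(time = times, type = types,
                          magnitude = ifelse(types == "spike",
                                             truth$spike_mag, truth$shift_mag) *
                            sample(c(-1, 1), n_art, replace = TRUE))
      col_sd <- function(x) sqrt(pmax(colMeans(x^2) - colMeans(x)^2, 0))
      sd1 <- col_sd(i1)
      sd2 <- col_sd(i2)
      sigma_s <- truth$spike_fwhm / 2.355
      for (a in seq_len(n_art)) {
        chans <- sample(n_ch, max(1, round(truth$artifact_frac * n_ch)))
        wave <- if (artifacts$type[a] == "spike") {
          exp(-(tgrid - artifacts$time[a])^2 / (2 * sigma_s^2))
        } else {
          as.numeric(tgrid >= artifacts$time[a])
        }
        i1[, chans] <- i1[, chans] +
          wave %o% (artifacts$magnitude[a] * sd1[chans])
        i2[, chans] <- i2[, chans] +
          wave %o% (artifacts$magnitude[a] * sd2[chans])
      }
    }

    scan <- structure(list(
      intensity = array(c(i1, i2), c(n, n_ch, 2)),
      wavelengths = c(690, 830),
      sampling_rate = fs,
      schedule = schedule,
      probe = layout,
      run_id = schedule$run_id
    ), class = "nirs_scan")

    run_truth <- list(artifacts = artifacts)
    if (truth$keep_conc) {
      run_truth$conc_hbo <- hbo
      run_truth$conc_hbr <- hbr
      run_truth$superficial <- superficial
    }
    list(scan = scan, run_truth = run_truth)
  })
}

# true per-trial response of every long channel on the -2..15 s lag grid
true_hrf_array <- function(layout, truth, sub, conditions, fs) {
  long <- layout$channels[layout$channels$type == "long", ]
  lag <- hrf_lag_grid(fs)
  shp <- truth$hrf_shapes[match(conditions, truth$hrf_shapes$condition), ]
  kern <- condition_kernels(shp, lag)
  hrf <- array(0, c(nrow(long), length(conditions), 2, length(lag)),
               dimnames = list(NULL, conditions, c("hbo", "hbr"), NULL))
  for (i in seq_along(conditions)) {
    hrf[, i, 1, ] <- sub$amp[, i] %o% kern$hbo[, i]
    hrf[, i, 2, ] <- (-truth$hbr_ratio * sub$amp[, i]) %o% kern$hbr[, i]
  }
  hrf
}

#' Simulate a synthetic subject (one or more runs)
#'
#' Draws subject-level amplitude and gain variability once, then generates
#' each run's raw dual-wavelength intensity scan by the forward chain: true
#' concentration series (per-condition responses convolved with the event
#' train, plus superficial contamination, systemic physiology and drift) ->
#' forward Beer-Lambert optical density per wavelength ->
#' `intensity = baseline * exp(-OD)` -> motion artifacts -> white noise.
#'
#' @param layout A `nirs_probe`.
#' @param schedules A `nirs_schedule` or list of them (one per run).
#' @param truth A [truth_params()] object.
#' @param seed Integer seed; fixes every random component.
#' @return A `nirs_sim` list: `runs` (list of `nirs_scan`), `truth` (ground
#'   truth: `hrf` array `[long channel x condition x chromophore x lag]`,
#'   subject draws, per-run artifact tables, and - when
#'   `truth_params(keep_conc = TRUE)` - the true concentration series).
#' @export
simulate_subject <- function(layout, schedules, truth, seed) {
  if (inherits(schedules, "nirs_schedule")) schedules <- list(schedules)
  spec <- schedules[[1]]$spec
  seeds <- child_seeds(seed, length(schedules) + 1L)
  sub <- with_seed(seeds[1],
                   draw_subject_effects(truth, layout, spec$conditions))
  runs <- vector("list", length(schedules))
  run_truths <- vector("list", length(schedules))
  for (r in seq_along(schedules)) {
    res <- sim_run(layout, schedules[[r]], truth, sub, seeds[r + 1L])
    runs[[r]] <- res$scan
    run_truths[[r]] <- res$run_truth
  }
  gt <- structure(list(
    hrf = true_hrf_array(layout, truth, sub, spec$conditions,
                         spec$sampling_rate),
    lag = hrf_lag_grid(spec$sampling_rate),
    subject = sub,
    params = truth,
    runs = run_truths
  ), class = "nirs_truth")
  structure(list(runs = runs, truth = gt, layout = layout),
            class = "nirs_sim")
}

#' Simulate a single run
#'
#' Convenience wrapper around [simulate_subject()] for one schedule.
#'
#' @inheritParams simulate_subject
#' @param schedule A single `nirs_schedule`.
#' @return A list with `scan` (a `nirs_scan`) and `truth` (see
#'   [simulate_subject()]).
#' @export
simulate_scan <- function(layout, schedule, truth, seed) {
  sim <- simulate_subject(layout, schedule, truth, seed)
  list(scan = sim$runs[[1]], truth = sim$truth)
}

#' @export
print.nirs_scan <- function(x, ...) {
  d <- dim(x$intensity)
  cat("<nirs_scan> run ", x$run_id, ": ", d[2], " channels x ", d[3],
      " wavelengths x ", d[1], " samples @ ", x$sampling_rate, " Hz\n",
      sep = "")
  invisible(x)
}

#' @rdname simulate_subject
#' @param x A `nirs_scan`.
#' @param ... Unused.
#' @export
tidy.nirs_scan <- function(x, ...) {
  d <- dim(x$intensity)
  tidyr::expand_grid(
    wavelength = x$wavelengths,
    channel = x$probe$channels$channel,
    time = (seq_len(d[1]) - 1) / x$sampling_rate
  ) |>
    dplyr::mutate(intensity = c(x$intensity))
}
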