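#' Convert raw intensity to optical density change
#'
#' `OD(t) = -ln(I(t) / mean_t I)` per channel and wavelength. Channels
#' containing non-positive intensity samples cannot be log-transformed; they
#' are flagged with reason `"nonpositive"` and their series set to `NA` so no
#' data flows downstream.
#'
#' @param scan A `nirs_scan`.
#' @return A `nirs_od` object: `od` array `[time x channel x wavelength]`,
#'   `excluded` tibble (`channel`, `reason`), plus inherited metadata.
#' @export
intensity_to_od <- function(scan) {
  stopifnot(inherits(scan, "nirs_scan"))
  intensity <- scan$intensity
  d <- dim(intensity)
  bad <- logical(d[2])
  for (w in seq_len(d[3])) {
    bad <- bad | colSums(intensity[, , w] <= 0) > 0L
  }
  if (!any(bad)) {
    od <- od_convert_flat(intensity, d[1])
    dim(od) <- d
  } else {
    ok <- !bad
    od <- array(NA_real_, d)
    for (w in seq_len(d[3])) {
      od[, ok, w] <- od_convert(intensity[, ok, w, drop = TRUE])
    }
  }
  excluded <- if (any(bad)) {
    tibble(channel = scan$probe$channels$channel[bad], reason = "nonpositive")
  } else {
    tibble(channel = integer(), reason = character())
  }
  structure(list(
    od = od, excluded = excluded, wavelengths = scan$wavelengths,
    sampling_rate = scan$sampling_rate, schedule = scan$schedule,
    probe = scan$probe, run_id = scan$run_id
  ), class = "nirs_od")
}

#' Prune channels by signal level
#'
#' A channel is kept only if its mean raw intensity, expressed as
#' `20 log10(mean_t I)` in instrument units, lies inside
#' `[low_db, high_db]` at *both* wavelengths (below the floor the
#' signal-to-noise ratio is inadequate; above the ceiling the detector
#' saturates). The dB reference is the instrument unit, so real-data users
#' must rescale their intensities to the convention of their system.
#'
#' @param scan A `nirs_scan`.
#' @param low_db,high_db Keep-range bounds in dB (inclusive).
#' @return A tibble with one row per channel: `channel`, `level_db_w1`,
#'   `level_db_w2`, `keep`, `reason` (`NA` when kept).
#' @export
prune_channels <- function(scan, low_db = 80, high_db = 140) {
  stopifnot(inherits(scan, "nirs_scan"))
  m1 <- colMeans(scan$intensity[, , 1])
  m2 <- colMeans(scan$intensity[, , 2])
  db1 <- ifelse(m1 > 0, 20 * log10(m1), -Inf)
  db2 <- ifelse(m2 > 0, 20 * log10(m2), -Inf)
  low <- db1 < low_db | db2 < low_db
  high <- db1 > high_db | db2 > high_db
  reason <- rep(NA_character_, d2 <- length(db1))
  reason[high] <- "above_range"
  reason[low] <- "below_range"
  tibble::new_tibble(list(
    channel = scan$probe$channels$channel,
    level_db_w1 = db1, level_db_w2 = db2,
    keep = !(low | high),
    reason = reason
  ), nrow = d2)
}

# Savitzky-Golay smoothing kernel (center row of the projection matrix)
sg_kernel <- function(order, width) {
  f <- signal::sgolay(p = order, n = width)
  as.numeric(f[(width + 1L) / 2L, ])
}

#' Hybrid spline + Savitzky-Golay motion correction
#'
#' Two-stage correction of motion artifacts in optical density, per channel
#' and wavelength. Stage 1 detects artifact segments by a sliding
#' amplitude-change statistic (difference of adjacent `window`-long means of
#' a 1 s moving average, which cancels cardiac pulsation and measurement
#' noise); windows whose statistic clears both detection thresholds are
#' flagged and the mask dilated by `dilation` seconds. Each flagged segment is then fit by a spline, the
#' spline subtracted, the segment re-leveled to the preceding signal, and
#' the subsequent signal shifted to remove any residual step. Stage 2
#' smooths remaining high-frequency transients with a Savitzky-Golay
#' polynomial filter. Clean series pass through nearly unchanged.
#'
#' @param od A `nirs_od`.
#' @param window Detection window (s).
#' @param threshold Detection threshold in multiples of the channel's
#'   robust per-sample noise SD (estimated from the differenced series).
#' @param rel_threshold Additional relative floor, in multiples of the
#'   channel's median + 1.48 MAD windowed amplitude change; both thresholds
#'   must be exceeded, which keeps noise-free data untouched.
#' @param dilation Mask dilation (s) applied either side of a detection.
#' @param sg_window Savitzky-Golay window (s).
#' @param sg_order Savitzky-Golay polynomial order.
#' @param level_window Averaging window (s) used for segment re-leveling.
#' @return The corrected `nirs_od`; attribute `n_segments` counts corrected
#'   segments.
#' @export
correct_motion <- function(od, window = 0.5, threshold = 8,
                           rel_threshold = 8, dilation = 1,
                           sg_window = 3, sg_order = 3, level_window = 0.5) {
  stopifnot(inherits(od, "nirs_od"))
  fs <- od$sampling_rate
  d <- dim(od$od)
  if (round(window * fs) > d[1]) {
    abort("detection window longer than series", class = "nirsflow_config_error")
  }
  width <- round(sg_window * fs)
  if (width %% 2 == 0) width <- width + 1L
  if (width > d[1]) {
    abort("Savitzky-Golay window longer than series",
          class = "nirsflow_config_error")
  }
  kern <- sg_kernel(sg_order, width)
  nseg <- 0L
  x <- matrix(od$od, d[1], d[2] * d[3])
  ok <- colSums(is.na(x)) == 0L
  # stage 1: detection vectorized over all series. The amplitude-change
  # statistic is the difference of adjacent `window`-long means of a 1 s
  # moving average (which cancels cardiac pulsation and measurement noise):
  # large for spikes and baseline steps at this time scale, small for
  # hemodynamic and slow physiological transitions.
  xo <- x[, ok, drop = FALSE]
  n <- d[1]
  w <- max(3L, round(window * fs))
  cw <- max(3L, round(1.0 * fs))
  rng <- detect_stat(xo, w, cw)
  # two robust scales: (a) the per-sample noise SD from the differenced
  # series - instrument artifacts are defined in multiples of the signal SD
  # and tower over it, while hemodynamic transitions stay within a few
  # noise SDs per window; (b) a relative floor (median + 1.48 MAD of the
  # statistic itself) that protects noise-free data. A window is flagged
  # only when the statistic clears both.
  sigma_d <- 1.4826 * col_median_abs_diff(xo, 4L) / sqrt(2)
  floor_rel <- col_median(rng, 4L) + 1.4826 * 1.4826 * col_mad(rng, 4L)
  scale <- pmax(threshold * sigma_d, rel_threshold * floor_rel,
                .Machine$double.eps)
  flagged <- which(col_max(rng) > scale)
  if (length(flagged) > 0) {
    res <- correct_segments(xo[, flagged, drop = FALSE],
                            rng[, flagged, drop = FALSE], scale[flagged],
                            dil = round(dilation * fs),
                            wl = max(2L, round(level_window * fs)),
                            kw = max(3L, round(0.25 * fs)))
    nseg <- res[[2]]
    # stage 2: Savitzky-Golay smoothing of the corrected series; untouched
    # channels pass through unchanged (the band-pass stage handles their
    # broadband noise)
    xo[, flagged] <- fir_reflect(res[[1]], kern)
    x[, ok] <- xo
  }
  od$od <- array(x, d)
  attr(od, "n_segments") <- nseg
  od
}

#' Resample optical density to a lower rate by block averaging
#'
#' Averages consecutive blocks of `sampling_rate / rate` samples (exact
#' anti-aliased decimation for the retained 0-0.5 Hz analysis band). Applied
#' after motion correction - which needs the native rate to see fast
#' transients - and before band-pass filtering, this cuts the cost of all
#' downstream stages without touching the retained band.
#'
#' @param od A `nirs_od`.
#' @param rate Target rate (Hz); must divide the native sampling rate.
#' @return The resampled `nirs_od`.
#' @export
resample_od <- function(od, rate) {
  stopifnot(inherits(od, "nirs_od"))
  f <- od$sampling_rate / rate
  if (f != round(f) || f < 1) {
    abort("target rate must divide the native sampling rate",
          class = "nirsflow_config_error")
  }
  if (f == 1) return(od)
  d <- dim(od$od)
  m <- block_mean_rows(matrix(od$od, d[1], d[2] * d[3]), as.integer(f))
  od$od <- array(m, c(nrow(m), d[2], d[3]))
  od$native_rate <- od$sampling_rate
  od$sampling_rate <- rate
  od
}

# squared magnitude of the digital Butterworth response on the FFT grid,
# i.e. the transfer function of forward-backward (zero-phase) filtering
butter_gain2 <- function(n, fs, low, high, order) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  w <- 2 * pi * (seq_len(n) - 1) / n
  z <- exp(-1i * w)
  num <- as.vector(outer(z, seq_along(bf$b) - 1, "^") %*% bf$b)
  den <- as.vector(outer(z, seq_along(bf$a) - 1, "^") %*% bf$a)
  Mod(num / den)^2
}

#' Zero-phase Butterworth band-pass filter
#'
#' Band-pass filtering with an order-`order` Butterworth design applied with
#' zero phase (forward-backward magnitude response, i.e. effective order
#' `2 * order`), removing slow drifts below `low` and oscillations above
#' `high`. The response is applied in the frequency domain on mirror-extended
#' series so that all channels are filtered in one batch; phase is exactly
#' zero, which preserves response timing.
#'
#' @param x A `nirs_od`, `nirs_conc`, matrix (series in columns) or vector.
#' @param low,high Pass-band edges (Hz).
#' @param order Design order of the one-way filter (default 3; the zero-phase
#'   magnitude response then has order 6).
#' @param sampling_rate Required when `x` is a bare matrix/vector.
#' @return Same shape/class as `x`.
#' @export
bandpass_filter <- function(x, low = 0.01, high = 0.5, order = 3,
                            sampling_rate = NULL) {
  UseMethod("bandpass_filter")
}

bandpass_matrix <- function(x, fs, low, high, order) {
  if (high >= fs / 2) {
    abort("high cutoff must be below the Nyquist frequency",
          class = "nirsflow_config_error")
  }
  if (low <= 0 || low >= high) {
    abort("need 0 < low < high", class = "nirsflow_config_error")
  }
  x <- as.matrix(x)
  n <- nrow(x)
  # require ~3 time constants of the high-pass corner
  if (n / fs < 3 / (2 * pi * low)) {
    abort("series too short for the requested high-pass corner",
          class = "nirsflow_config_error")
  }
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  # even mirror extension -> periodic continuity, then length to a nice FFT size
  nf <- nextn(2L * n, c(2, 3, 5))
  xp <- rbind(xc, xc[n:1, , drop = FALSE],
              matrix(0, nf - 2L * n, ncol(xc)))
  g2 <- butter_gain2(nf, fs, low, high, order)
  y <- Re(mvfft(mvfft(xp) * g2, inverse = TRUE)) / nf
  y[seq_len(n), , drop = FALSE]
}

#' @export
bandpass_filter.default <- function(x, low = 0.01, high = 0.5, order = 3,
                                    sampling_rate = NULL) {
  if (is.null(sampling_rate)) {
    abort("sampling_rate required for matrix/vector input",
          class = "nirsflow_config_error")
  }
  if (is.matrix(x)) {
    bandpass_matrix(x, sampling_rate, low, high, order)
  } else {
    as.numeric(bandpass_matrix(matrix(x, ncol = 1), sampling_rate, low,
                               high, order))
  }
}

#' @export
bandpass_filter.nirs_od <- function(x, low = 0.01, high = 0.5, order = 3,
                                    sampling_rate = NULL) {
  d <- dim(x$od)
  m <- matrix(x$od, d[1], d[2] * d[3])
  ok <- !apply(is.na(m), 2, any)
  m[, ok] <- bandpass_matrix(m[, ok, drop = FALSE], x$sampling_rate, low,
                             high, order)
  x$od <- array(m, d)
  x
}

#' @export
bandpass_filter.nirs_conc <- function(x, low = 0.01, high = 0.5, order = 3,
                                      sampling_rate = NULL) {
  for (f in c("hbo", "hbr", "ss_hbo", "ss_hbr")) {
    if (!is.null(x[[f]]) && ncol(x[[f]]) > 0) {
      ok <- !apply(is.na(x[[f]]), 2, any)
      x[[f]][, ok] <- bandpass_matrix(x[[f]][, ok, drop = FALSE],
                                      x$sampling_rate, low, high, order)
    }
  }
  x
}

#' Modified Beer-Lambert law
#'
#' Converts optical density changes at the two wavelengths into molar
#' concentration changes of oxy- and deoxy-hemoglobin:
#' `E %*% c = od / (separation * ppf)` solved per channel, with `E` the
#' natural-log extinction matrix from [extinction_coefficients()]. Long
#' channels form the cortical concentration scan; short-separation channels
#' are converted the same way and kept separately as physiology regressors.
#'
#' @param od A `nirs_od`.
#' @param ppf Partial pathlength factor (wavelength-independent scalar).
#' @return A `nirs_conc` object: matrices `hbo`, `hbr`
#'   `[time x long channel]` (molar), `ss_hbo`, `ss_hbr`
#'   `[time x short channel]`, channel tables, and inherited metadata.
#'   Excluded channels are `NA` columns.
#' @export
mbll <- function(od, ppf = 6) {
  stopifnot(inherits(od, "nirs_od"))
  eps <- extinction_coefficients(od$wavelengths, log_base = "e")
  ei <- solve(eps)
  ch <- od$probe$channels
  path <- ch$separation * ppf
  od1 <- sweep(od$od[, , 1], 2, path, "/")
  od2 <- sweep(od$od[, , 2], 2, path, "/")
  hbo_all <- od1 * ei[1, 1] + od2 * ei[1, 2]
  hbr_all <- od1 * ei[2, 1] + od2 * ei[2, 2]
  long <- ch$type == "long"
  structure(list(
    hbo = hbo_all[, long, drop = FALSE],
    hbr = hbr_all[, long, drop = FALSE],
    ss_hbo = hbo_all[, !long, drop = FALSE],
    ss_hbr = hbr_all[, !long, drop = FALSE],
    channels = ch[long, ], ss_channels = ch[!long, ],
    sampling_rate = od$sampling_rate,
    native_rate = od$native_rate %||% od$sampling_rate,
    schedule = od$schedule,
    probe = od$probe, ppf = ppf, excluded = od$excluded,
    run_id = od$run_id
  ), class = "nirs_conc")
}

#' @export
print.nirs_conc <- function(x, ...) {
  cat("<nirs_conc> ", ncol(x$hbo), " long channels (+", ncol(x$ss_hbo),
      " short), ", nrow(x$hbo), " samples @ ", x$sampling_rate, " Hz\n",
      sep = "")
  invisible(x)
}

#' @rdname mbll
#' @param x A `nirs_conc`.
#' @param ... Unused.
#' @export
tidy.nirs_conc <- function(x, ...) {
  tidyr::expand_grid(
    chromophore = c("hbo", "hbr"),
    channel = x$channels$channel,
    time = (seq_len(nrow(x$hbo)) - 1) / x$sampling_rate
  ) |>
    dplyr::mutate(conc = c(c(x$hbo), c(x$hbr)))
}

#' Full preprocessing chain
#'
#' Raw scan to concentration: channel pruning by signal level, optical
#' density conversion, hybrid motion correction, zero-phase band-pass
#' filtering, and the modified Beer-Lambert law.
#'
#' @param scan A `nirs_scan`.
#' @param low_db,high_db Pruning bounds (dB).
#' @param motion Named list of [correct_motion()] arguments, or `NULL` to
#'   skip the stage.
#' @param bandpass Named list of [bandpass_filter()] arguments, or `NULL` to
#'   skip.
#' @param resample Optional analysis rate (Hz) for [resample_od()], applied
#'   after motion correction; `NULL` keeps the native rate.
#' @param ppf Partial pathlength factor for [mbll()].
#' @return A `nirs_conc`.
#' @export
preprocess <- function(scan, low_db = 80, high_db = 140,
                       motion = list(), bandpass = list(), resample = NULL,
                       ppf = 6) {
  pr <- prune_channels(scan, low_db, high_db)
  od <- intensity_to_od(scan)
  drop <- pr$channel[!pr$keep]
  drop <- setdiff(drop, od$excluded$channel)
  if (length(drop) > 0) {
    idx <- match(drop, scan$probe$channels$channel)
    od$od[, idx, ] <- NA_real_
    od$excluded <- dplyr::bind_rows(
      od$excluded,
      tibble(channel = drop,
             reason = pr$reason[match(drop, pr$channel)]))
  }
  if (!is.null(motion)) od <- do.call(correct_motion, c(list(od), motion))
  if (!is.null(resample)) od <- resample_od(od, resample)
  if (!is.null(bandpass)) od <- do.call(bandpass_filter, c(list(od), bandpass))
  mbll(od, ppf = ppf)
}
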