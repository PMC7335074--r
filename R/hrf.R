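#' Canonical two-gamma hemodynamic response
#'
#' Difference of two gamma functions, each parameterized by its mode (peak
#' time) and gamma shape, normalized to unit peak. The positive lobe peaks at
#' `peak_time`; an undershoot of relative amplitude `undershoot` peaks
#' `undershoot_delay` seconds later. Zero for `t <= 0` (causal).
#'
#' @param t Time since trial onset (s); may be a vector.
#' @param peak_time Mode of the positive lobe (s).
#' @param shape Gamma shape parameter (dimensionless, > 1); larger is
#'   narrower relative to the peak time.
#' @param undershoot Relative undershoot amplitude (0 disables).
#' @param undershoot_delay Delay of the undershoot mode after `peak_time` (s).
#' @return Numeric vector, unit peak amplitude.
#' @examples
#' t <- seq(0, 25, 0.04)
#' h <- canonical_hrf(t, peak_time = 6)
#' t[which.max(h)]
#' @export
canonical_hrf <- function(t, peak_time = 6, shape = 6, undershoot = 0.12,
                          undershoot_delay = 6) {
  stopifnot(peak_time > 0, shape > 1)
  g <- function(t, mode, a) {
    out <- numeric(length(t))
    pos <- t > 0
    out[pos] <- (t[pos] / mode)^(a - 1) * exp(-(t[pos] - mode) * (a - 1) / mode)
    out
  }
  h <- g(t, peak_time, shape) -
    undershoot * g(t, peak_time + undershoot_delay, shape)
  pk <- max(h)
  if (pk > 0) h <- h / pk
  h
}

#' Lag grid of the estimated hemodynamic response
#'
#' @param sampling_rate Hz.
#' @param t_range Lag window (s), default -2 to 15 s.
#' @return Numeric vector of lags (s).
#' @export
hrf_lag_grid <- function(sampling_rate = 25, t_range = c(-2, 15)) {
  seq(t_range[1], t_range[2], by = 1 / sampling_rate)
}

# default per-condition response shapes: execution conditions follow the
# typical early-peaking response with a delayed HbR trough; observation (and
# the visual control) rise slowly and peak late with an HbR trough that
# tracks the HbO peak. Responses are modeled as completing within the
# deconvolution lag window (taper to zero by support_end).
default_hrf_shapes <- function(conditions) {
  tibble(
    condition = conditions,
    class = dplyr::case_when(
      grepl("^exec", conditions) ~ "execution",
      grepl("^obs", conditions) ~ "observation",
      TRUE ~ "control"
    ),
    peak_time = ifelse(grepl("^exec", conditions), 6, 10),
    shape = ifelse(grepl("^exec", conditions), 6, 5),
    undershoot = ifelse(grepl("^exec", conditions), 0.15, 0.08),
    undershoot_delay = 5,
    hbr_delay = ifelse(grepl("^exec", conditions), 3, 0),
    support_end = 15,
    taper_width = 3
  )
}

# raised-cosine taper to zero over [t_end - width, t_end]; zero beyond
taper_window <- function(t, t_end, width) {
  w <- rep(1, length(t))
  w[t >= t_end] <- 0
  ramp <- t > t_end - width & t < t_end
  w[ramp] <- 0.5 * (1 + cos(pi * (t[ramp] - (t_end - width)) / width))
  w
}

# unit-peak HbO/HbR trial-response kernels per condition on the lag grid
condition_kernels <- function(shapes, lags) {
  k_hbo <- sapply(seq_len(nrow(shapes)), function(i) {
    h <- canonical_hrf(lags, shapes$peak_time[i], shapes$shape[i],
                       shapes$undershoot[i], shapes$undershoot_delay[i]) *
      taper_window(lags, shapes$support_end[i], shapes$taper_width[i])
    h / max(h)
  })
  k_hbr <- sapply(seq_len(nrow(shapes)), function(i) {
    h <- canonical_hrf(lags - shapes$hbr_delay[i], shapes$peak_time[i],
                       shapes$shape[i], shapes$undershoot[i],
                       shapes$undershoot_delay[i]) *
      taper_window(lags, shapes$support_end[i], shapes$taper_width[i])
    h / max(h)
  })
  colnames(k_hbo) <- colnames(k_hbr) <- shapes$condition
  list(hbo = k_hbo, hbr = k_hbr)
}
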