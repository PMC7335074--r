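#' Stack per-subject HRF fits into a group array
#'
#' @param fits List of `nirs_hrf_fit` (one per subject), all on the same
#'   probe, conditions and lag grid.
#' @return A `nirs_group_hrf`: `hrf` array
#'   `[subject x channel x condition x chromophore x lag]`, lag grid,
#'   channel table and conditions.
#' @export
stack_hrf_fits <- function(fits) {
  stopifnot(length(fits) >= 1)
  d <- dim(fits[[1]]$hrf)
  hrf <- array(NA_real_, c(length(fits), d))
  for (s in seq_along(fits)) hrf[s, , , , ] <- fits[[s]]$hrf
  dimnames(hrf) <- c(list(NULL), dimnames(fits[[1]]$hrf))
  structure(list(
    hrf = hrf, lag = fits[[1]]$lag, channels = fits[[1]]$channels,
    conditions = fits[[1]]$conditions, n_subjects = length(fits)
  ), class = "nirs_group_hrf")
}

#' Average HRFs over region-of-interest channels
#'
#' Unweighted mean over the non-excluded channels of each ROI, per subject,
#' condition, chromophore and lag. Subjects with no surviving channel in an
#' ROI get `NA` there (and a warning) and are dropped from that ROI's
#' statistics downstream.
#'
#' @param group A `nirs_group_hrf` (or a single `nirs_hrf_fit`).
#' @param roi_map Tibble (`roi`, `hemisphere`, `channel`), e.g.
#'   [default_roi_map()].
#' @return A `nirs_roi_hrf`: `hrf` array
#'   `[subject x roi x condition x chromophore x lag]` and the `rois` table.
#' @export
roi_average <- function(group, roi_map) {
  if (inherits(group, "nirs_hrf_fit")) group <- stack_hrf_fits(list(group))
  stopifnot(inherits(group, "nirs_group_hrf"))
  keys <- dplyr::distinct(roi_map[, c("roi", "hemisphere")])
  d <- dim(group$hrf)
  out <- array(NA_real_, c(d[1], nrow(keys), d[3], d[4], d[5]))
  ch_ids <- group$channels$channel
  for (k in seq_len(nrow(keys))) {
    chans <- roi_map$channel[roi_map$roi == keys$roi[k] &
                             roi_map$hemisphere == keys$hemisphere[k]]
    idx <- match(chans, ch_ids)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0) {
      abort(sprintf("ROI %s (%s) has no channels in the layout",
                    keys$roi[k], keys$hemisphere[k]),
            class = "nirsflow_config_error")
    }
    sub <- group$hrf[, idx, , , , drop = FALSE]
    ok <- !is.na(sub)
    cnt <- rowSums(aperm(ok, c(1, 3, 4, 5, 2)), dims = 4)
    sm <- rowSums(aperm(ifelse(ok, sub, 0), c(1, 3, 4, 5, 2)), dims = 4)
    avg <- sm / cnt  # NaN where no channel survives
    avg[cnt == 0] <- NA_real_
    out[, k, , , ] <- avg
    if (any(cnt == 0)) {
      warn(sprintf("ROI %s (%s): %d subject(s) have no surviving channels",
                   keys$roi[k], keys$hemisphere[k],
                   length(unique(which(cnt == 0, arr.ind = TRUE)[, 1]))))
    }
  }
  dimnames(out) <- list(NULL, NULL, group$conditions, c("hbo", "hbr"), NULL)
  structure(list(hrf = out, rois = keys, lag = group$lag,
                 conditions = group$conditions,
                 n_subjects = d[1]), class = "nirs_roi_hrf")
}

#' @rdname roi_average
#' @param x A `nirs_roi_hrf`.
#' @param ... Unused.
#' @export
tidy.nirs_roi_hrf <- function(x, ...) {
  d <- dim(x$hrf)
  tidyr::expand_grid(
    lag = x$lag,
    chromophore = c("hbo", "hbr"),
    condition = x$conditions,
    roi_index = seq_len(d[2]),
    subject = seq_len(d[1])
  )[, 5:1] |>
    dplyr::mutate(estimate = c(x$hrf),
                  roi = x$rois$roi[.data$roi_index],
                  hemisphere = x$rois$hemisphere[.data$roi_index]) |>
    dplyr::select(-"roi_index")
}

roi_index <- function(roi_hrf, roi, hemisphere) {
  k <- which(roi_hrf$rois$roi == roi & roi_hrf$rois$hemisphere == hemisphere)
  if (length(k) != 1) {
    abort(sprintf("ROI %s (%s) not found", roi, hemisphere),
          class = "nirsflow_config_error")
  }
  k
}

#' Windowed mean peak activation
#'
#' Mean of the ROI-averaged HRF over a fixed time window, per subject and
#' condition. The same window is applied to both conditions of a contrast;
#' the conventional windows are 2-8 s for execution contrasts, 7-10 s for
#' observation versus control, and 6-12 s for observation complex versus
#' simple.
#'
#' @param roi_hrf A `nirs_roi_hrf`.
#' @param roi,hemisphere ROI selector.
#' @param window Length-2 numeric window (s), within the lag grid.
#' @param conditions Conditions to extract (default all).
#' @param chromophore `"hbo"` or `"hbr"`.
#' @return Tibble: `subject`, `condition`, `value` (molar).
#' @export
mean_peak <- function(roi_hrf, roi, hemisphere, window,
                      conditions = roi_hrf$conditions,
                      chromophore = "hbo") {
  lag <- roi_hrf$lag
  if (window[1] < min(lag) - 1e-9 || window[2] > max(lag) + 1e-9) {
    abort("window outside the HRF lag grid", class = "nirsflow_config_error")
  }
  k <- roi_index(roi_hrf, roi, hemisphere)
  widx <- which(lag >= window[1] & lag <= window[2])
  vals <- roi_hrf$hrf[, k, conditions, chromophore, widx, drop = FALSE]
  m <- rowMeans(vals, dims = 3)[, 1, ]
  m <- matrix(m, nrow = dim(vals)[1])
  tidyr::expand_grid(condition = conditions,
                     subject = seq_len(nrow(m)))[, 2:1] |>
    dplyr::mutate(value = c(m))
}

#' Paired Student's t test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = a - b`, two-sided p on
#' `n - 1` degrees of freedom. A zero-variance difference is degenerate: the
#' test is flagged and p is reported as `NA`.
#'
#' @param a,b Equal-length numeric vectors of per-subject values.
#' @return One-row tibble: `n`, `mean_diff`, `t`, `df`, `p`, `degenerate`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2) abort("paired t needs n >= 2", class = "nirsflow_config_error")
  d <- a - b
  if (sd(d) == 0) {
    # no variability: identical samples carry no evidence (t = 0, p = 1);
    # a constant non-zero difference leaves t undefined
    zero <- mean(d) == 0
    return(tibble(n = n, mean_diff = mean(d),
                  t = if (zero) 0 else NA_real_, df = n - 1L,
                  p = if (zero) 1 else NA_real_, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  tibble(n = n, mean_diff = unname(ht$estimate), t = unname(ht$statistic),
         df = unname(ht$parameter), p = ht$p.value, degenerate = FALSE)
}

#' Shapiro-Francia normality test
#'
#' `W'` is the squared correlation between the ordered sample and the
#' expected normal order statistics; the p value uses Royston's normal
#' approximation for `ln(1 - W')`. Valid for 5 <= n <= 5000.
#'
#' @param x Numeric vector.
#' @return One-row tibble: `statistic` (W'), `p`.
#' @export
shapiro_francia <- function(x) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2) {
    abort("Shapiro-Francia test undefined for a constant vector",
          class = "nirsflow_config_error")
  }
  ht <- nortest::sf.test(x)
  tibble(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up procedure: with ordered p-values `p_(1) <= ... <= p_(m)`, reject
#' all hypotheses up to the largest `i` with `p_(i) <= i q / m`. Returns
#' BH-adjusted p-values; the rejection mask equals `adjusted <= q`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed, never
#'   rejected).
#' @param q Target false discovery rate.
#' @return Tibble: `p`, `adjusted`, `reject`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", class = "nirsflow_config_error")
  }
  adj <- p.adjust(p, method = "BH")
  tibble(p = p, adjusted = adj,
         reject = !is.na(adj) & adj <= q)
}

#' Pointwise confidence band of a group mean time course
#'
#' At every lag, mean +/- t-quantile times the standard error across
#' subjects: a pointwise (not simultaneous) band.
#'
#' @param x Matrix `[subject x lag]` (or vector of per-subject values for a
#'   single point).
#' @param lag Optional lag grid for the output.
#' @param level Confidence level.
#' @return Tibble: `lag`, `mean`, `se`, `lower`, `upper`, `n`.
#' @export
confidence_band <- function(x, lag = NULL, level = 0.95) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n < 2) {
    abort("confidence band needs at least 2 subjects",
          class = "nirsflow_config_error")
  }
  m <- colMeans(x)
  se <- sqrt((colMeans(x^2) - m^2) * n / (n - 1)) / sqrt(n)
  tq <- qt(1 - (1 - level) / 2, df = n - 1)
  tibble(lag = lag %||% seq_along(m), mean = m, se = se,
         lower = m - tq * se, upper = m + tq * se, n = n)
}

#' Time to peak of an HRF
#'
#' Lag of the response extremum over the post-onset window (lags >= 0): the
#' maximum for HbO, and the maximal *decrease* (minimum) for HbR. A peak on
#' the last lag is flagged as a boundary hit; a flat series returns `NA`.
#'
#' @param hrf Numeric vector, one HRF time course.
#' @param lag Lag grid (s) matching `hrf`.
#' @param chromophore `"hbo"` (maximum) or `"hbr"` (minimum).
#' @return One-row tibble: `time_to_peak` (s), `peak_value`, `boundary`,
#'   `flat`.
#' @export
time_to_peak <- function(hrf, lag, chromophore = c("hbo", "hbr")) {
  chromophore <- match.arg(chromophore)
  pos <- lag >= 0
  h <- hrf[pos]
  l <- lag[pos]
  if (all(!is.finite(h)) || diff(range(h, na.rm = TRUE)) == 0) {
    return(tibble(time_to_peak = NA_real_, peak_value = NA_real_,
                  boundary = FALSE, flat = TRUE))
  }
  i <- if (chromophore == "hbo") which.max(h) else which.min(h)
  tibble(time_to_peak = l[i], peak_value = h[i],
         boundary = i == length(h), flat = FALSE)
}

#' Default condition contrasts and their peak windows
#'
#' @return Tibble: `contrast`, `condition_a`, `condition_b`,
#'   `window_start`, `window_end` (s).
#' @export
default_contrasts <- function() {
  tibble(
    contrast = c("exec_complex_vs_simple", "obs_complex_vs_control",
                 "obs_simple_vs_control", "obs_complex_vs_simple"),
    condition_a = c("exec_complex", "obs_complex", "obs_simple",
                    "obs_complex"),
    condition_b = c("exec_simple", "control", "control", "obs_simple"),
    window_start = c(2, 7, 7, 6),
    window_end = c(8, 10, 10, 12)
  )
}

#' ROI contrast statistics with per-hemisphere FDR control
#'
#' For every contrast and ROI: windowed mean peak values per subject in both
#' conditions, a Shapiro-Francia normality check of the paired differences,
#' a paired t test, and Benjamini-Hochberg adjustment applied separately to
#' each (contrast, hemisphere) family of ROIs.
#'
#' @param roi_hrf A `nirs_roi_hrf`.
#' @param contrasts Contrast table, see [default_contrasts()].
#' @param chromophore Chromophore analyzed (HbO by convention; it has the
#'   better signal-to-noise ratio).
#' @param fdr_q False discovery rate.
#' @return Tibble: one row per contrast x ROI with `t`, `df`, `p`,
#'   `q` (BH-adjusted), `significant`, normality statistic and p.
#' @export
run_contrasts <- function(roi_hrf, contrasts = default_contrasts(),
                          chromophore = "hbo", fdr_q = 0.05) {
  res <- purrr::pmap_dfr(contrasts, function(contrast, condition_a,
                                             condition_b, window_start,
                                             window_end) {
    purrr::pmap_dfr(roi_hrf$rois, function(roi, hemisphere) {
      mp <- mean_peak(roi_hrf, roi, hemisphere,
                      c(window_start, window_end),
                      conditions = c(condition_a, condition_b),
                      chromophore = chromophore)
      a <- mp$value[mp$condition == condition_a]
      b <- mp$value[mp$condition == condition_b]
      keep <- is.finite(a) & is.finite(b)
      tt <- paired_t(a[keep], b[keep])
      sf <- tryCatch(shapiro_francia(a[keep] - b[keep]),
                     error = function(e) tibble(statistic = NA_real_,
                                                p = NA_real_))
      tibble(contrast = contrast, roi = roi, hemisphere = hemisphere,
             condition_a = condition_a, condition_b = condition_b,
             window_start = window_start, window_end = window_end,
             n = tt$n, mean_diff = tt$mean_diff, t = tt$t, df = tt$df,
             p = tt$p, degenerate = tt$degenerate,
             sf_statistic = sf$statistic, sf_p = sf$p)
    })
  })
  res |>
    dplyr::group_by(.data$contrast, .data$hemisphere) |>
    dplyr::mutate(q = bh_fdr(.data$p, fdr_q)$adjusted,
                  significant = !is.na(.data$q) & .data$q <= fdr_q) |>
    dplyr::ungroup()
}

#' Temporal characteristics: time-to-peak comparison
#'
#' Per-subject time to peak of the ROI-averaged HRF for an execution and an
#' observation condition, for both chromophores, with a paired t test of the
#' HbO time-to-peak difference between the two condition classes.
#'
#' @param roi_hrf A `nirs_roi_hrf`.
#' @param roi,hemisphere ROI used for the summary.
#' @param exec_condition,obs_condition Condition labels of the two classes.
#' @return List with `summary` (tibble: `class`, `chromophore`, `mean_ttp`,
#'   `sd_ttp`, `n`) and `hbo_test` (paired t of observation minus execution
#'   HbO time to peak).
#' @export
temporal_summary <- function(roi_hrf, roi = "M1", hemisphere = "right",
                             exec_condition = "exec_complex",
                             obs_condition = "obs_complex") {
  k <- roi_index(roi_hrf, roi, hemisphere)
  grid <- tidyr::expand_grid(
    class = c("execution", "observation"),
    chromophore = c("hbo", "hbr"),
    subject = seq_len(dim(roi_hrf$hrf)[1])
  )
  ttp <- purrr::pmap_dfr(grid, function(class, chromophore, subject) {
    cond <- if (class == "execution") exec_condition else obs_condition
    h <- roi_hrf$hrf[subject, k, cond, chromophore, ]
    out <- time_to_peak(h, roi_hrf$lag, chromophore)
    dplyr::mutate(out, class = class, chromophore = chromophore,
                  subject = subject)
  })
  summary <- ttp |>
    dplyr::group_by(.data$class, .data$chromophore) |>
    dplyr::summarise(mean_ttp = mean(.data$time_to_peak, na.rm = TRUE),
                     sd_ttp = sd(.data$time_to_peak, na.rm = TRUE),
                     n = sum(is.finite(.data$time_to_peak)),
                     .groups = "drop")
  obs <- ttp$time_to_peak[ttp$class == "observation" &
                          ttp$chromophore == "hbo"]
  exe <- ttp$time_to_peak[ttp$class == "execution" &
                          ttp$chromophore == "hbo"]
  list(summary = summary, per_subject = ttp,
       hbo_test = paired_t(obs, exe))
}
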