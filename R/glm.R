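#' Gaussian temporal basis for HRF deconvolution
#'
#' Consecutive Gaussian bumps with standard deviation `sigma`, means
#' `spacing` apart spanning `t_range` (inclusive), each normalized to unit
#' peak so coefficients carry the units of the data (molar). The defaults
#' (sigma 1 s, spacing 1 s, -2 to 15 s) give 18 basis functions whose sum is
#' nearly constant over the interior of the window, so any smooth response
#' shape on the lag grid is representable.
#'
#' @param t_range Lag window (s).
#' @param sigma Gaussian SD (s).
#' @param spacing Distance between consecutive means (s).
#' @param sampling_rate Hz (carried for evaluation grids).
#' @return A `nirs_basis` object.
#' @export
hrf_basis <- function(t_range = c(-2, 15), sigma = 1, spacing = 1,
                      sampling_rate = 25) {
  if (spacing <= 0) {
    abort("basis spacing must be positive", class = "nirsflow_config_error")
  }
  if (sigma <= 0 || t_range[1] >= t_range[2]) {
    abort("need sigma > 0 and an increasing t_range",
          class = "nirsflow_config_error")
  }
  means <- seq(t_range[1], t_range[2], by = spacing)
  structure(list(means = means, sigma = sigma, t_range = t_range,
                 sampling_rate = sampling_rate),
            class = "nirs_basis")
}

#' @rdname hrf_basis
#' @param basis A `nirs_basis`.
#' @param lags Numeric vector of lags (s) at which to evaluate.
#' @return `basis_matrix()`: matrix `[length(lags) x n_basis]`.
#' @export
basis_matrix <- function(basis, lags) {
  sapply(basis$means, function(m) exp(-(lags - m)^2 / (2 * basis$sigma^2)))
}

#' @export
print.nirs_basis <- function(x, ...) {
  cat("<nirs_basis> ", length(x$means), " Gaussian bumps, sigma ", x$sigma,
      " s, means ", x$t_range[1], "..", x$t_range[2], " s\n", sep = "")
  invisible(x)
}

#' Build the GLM design for one or more runs
#'
#' Columns are, in order: one regressor per (condition, basis function) -
#' the event impulse train convolved with that basis bump (onsets discretized
#' to the nearest sample); per-run Legendre drift polynomials of order
#' `drift_order` (including the run intercept). The per-channel
#' short-separation regressor is appended at fit time. The common block is
#' Cholesky-factorized once, so fitting many channels and subjects against
#' the same schedules is cheap.
#'
#' @param schedules A `nirs_schedule` or list of them.
#' @param basis A [hrf_basis()].
#' @param drift_order Legendre drift order per run.
#' @param decimate Row block-averaging factor matching a concentration scan
#'   resampled with [resample_od()]; the design is built at the native rate
#'   and decimated by the identical block means, so the decimated model is
#'   exact.
#' @return A `nirs_design_matrix`: `x`, `cols` (tibble describing columns),
#'   Cholesky factor of the normal matrix, and metadata.
#' @export
build_glm_design <- function(schedules, basis = hrf_basis(),
                             drift_order = 3, decimate = 1L) {
  if (inherits(schedules, "nirs_schedule")) schedules <- list(schedules)
  spec <- schedules[[1]]$spec
  fs <- spec$sampling_rate
  conditions <- spec$conditions
  nb <- length(basis$means)
  klag <- seq(min(basis$means) - 4 * basis$sigma,
              max(basis$means) + 4 * basis$sigma, by = 1 / fs)
  kern <- basis_matrix(basis, klag)
  l0 <- round(klag[1] * fs)
  n_run <- round(spec$run_duration * fs)
  n_tot <- n_run * length(schedules)
  n_hrf <- length(conditions) * nb
  n_drift <- (drift_order + 1L) * length(schedules)
  x <- matrix(0, n_tot, n_hrf + n_drift)
  for (r in seq_along(schedules)) {
    off <- (r - 1L) * n_run
    ev <- schedules[[r]]$events
    for (e in seq_len(nrow(ev))) {
      c_idx <- match(ev$condition[e], conditions)
      cols <- (c_idx - 1L) * nb + seq_len(nb)
      i0 <- round(ev$onset[e] * fs) + 1L
      idx <- i0 + l0 + seq_len(nrow(kern)) - 1L
      valid <- idx >= 1L & idx <= n_run
      x[off + idx[valid], cols] <- x[off + idx[valid], cols] +
        kern[valid, , drop = FALSE]
    }
    dcols <- n_hrf + (r - 1L) * (drift_order + 1L) + seq_len(drift_order + 1L)
    x[off + seq_len(n_run), dcols] <- legendre_drift(n_run, drift_order)
  }
  decimate <- as.integer(decimate)
  if (decimate > 1L) {
    stopifnot(n_run %% decimate == 0L)
    x <- do.call(rbind, lapply(seq_along(schedules), function(r) {
      block_mean_rows(x[(r - 1L) * n_run + seq_len(n_run), , drop = FALSE],
                      decimate)
    }))
    n_run <- n_run %/% decimate
  }
  cols <- dplyr::bind_rows(
    tidyr::expand_grid(condition = conditions, basis_index = seq_len(nb)) |>
      dplyr::mutate(kind = "hrf"),
    tidyr::expand_grid(run = seq_along(schedules),
                       order = 0:drift_order) |>
      dplyr::mutate(kind = "drift")
  )
  ctc <- crossprod(x)
  ch <- tryCatch(chol(ctc), error = function(e) NULL)
  if (is.null(ch)) {
    q <- qr(x)
    bad <- q$pivot[(q$rank + 1L):ncol(x)]
    abort(paste0("design matrix is rank deficient; collinear columns: ",
                 paste(bad, collapse = ", ")),
          class = "nirsflow_config_error")
  }
  structure(list(x = x, cols = cols, chol_ctc = ch, basis = basis,
                 drift_order = drift_order, schedules = schedules,
                 conditions = conditions, sampling_rate = fs / decimate,
                 native_rate = fs, decimate = decimate, n_run = n_run),
            class = "nirs_design_matrix")
}

#' Select the best-correlated short-separation regressor
#'
#' For each long channel, the short-separation channel whose concentration
#' series has the highest Pearson correlation (signed maximum) with that
#' long channel, per chromophore. Zero-variance or missing candidates are
#' skipped; ties resolve to the lowest short-channel index. If no candidate
#' survives, the channel gets no regressor (`NA`).
#'
#' @param conc A `nirs_conc` (band-passed; selection follows filtering in the
#'   standard chain).
#' @param chromophore `"hbo"` or `"hbr"`.
#' @return Tibble: `channel`, `chromophore`, `ss_channel` (id or `NA`), `r`.
#' @export
select_ss_channel <- function(conc, chromophore = c("hbo", "hbr")) {
  chromophore <- match.arg(chromophore)
  y <- conc[[chromophore]]
  s <- conc[[paste0("ss_", chromophore)]]
  n_long <- ncol(y)
  if (is.null(s) || ncol(s) == 0) {
    return(tibble(channel = conc$channels$channel,
                  chromophore = chromophore,
                  ss_channel = NA_integer_, r = NA_real_))
  }
  col_ok <- function(m) {
    no_na <- colSums(is.na(m)) == 0L
    v <- colMeans(m^2) - colMeans(m)^2
    no_na & !is.na(v) & v > 0
  }
  ok_s <- col_ok(s)
  ok_y <- col_ok(y)
  sel <- rep(NA_integer_, n_long)
  rbest <- rep(NA_real_, n_long)
  if (any(ok_s) && any(ok_y)) {
    r <- suppressWarnings(cor(y[, ok_y, drop = FALSE],
                              s[, ok_s, drop = FALSE]))
    pick <- apply(r, 1, which.max)  # which.max takes the first (lowest) tie
    sel[ok_y] <- conc$ss_channels$channel[which(ok_s)][pick]
    rbest[ok_y] <- r[cbind(seq_len(nrow(r)), pick)]
  }
  if (all(is.na(sel))) {
    warn("no usable short-separation channel; GLM will omit the physiology regressor")
  }
  tibble(channel = conc$channels$channel, chromophore = chromophore,
         ss_channel = sel, r = rbest)
}

#' Estimate hemodynamic response functions by OLS deconvolution
#'
#' Ordinary-least-squares GLM per long channel and chromophore: the data are
#' regressed on the Gaussian-basis event regressors, per-run polynomial
#' drifts, and (optionally) the best-correlated short-separation channel as
#' a simultaneous physiology regressor. The HRF is the basis expansion of
#' the fitted coefficients on the lag grid, baseline-corrected by
#' subtracting its mean over the -2..0 s window.
#'
#' @param conc A `nirs_conc` (single run) or the result of [bind_runs()].
#' @param design Optional precomputed [build_glm_design()]; built from the
#'   scan's schedule(s) when omitted.
#' @param basis,drift_order Passed to [build_glm_design()] when `design` is
#'   omitted.
#' @param ss Use short-separation regressors (`TRUE`) or fit without
#'   (`FALSE`).
#' @return A `nirs_hrf_fit`: `hrf` array `[channel x condition x chromophore
#'   x lag]` (molar), `lag` grid (s), `coefficients`, `sigma2` residual
#'   variances, `ss_selected` table, channel table, and fit metadata.
#' @export
fit_hrf_glm <- function(conc, design = NULL, basis = NULL, drift_order = 3,
                        ss = TRUE) {
  stopifnot(inherits(conc, "nirs_conc"))
  schedules <- conc$schedules %||% list(conc$schedule)
  native <- conc$native_rate %||% conc$sampling_rate
  if (is.null(design)) {
    basis <- basis %||% hrf_basis(sampling_rate = native)
    design <- build_glm_design(schedules, basis, drift_order,
                               decimate = native / conc$sampling_rate)
  }
  fs <- design$native_rate
  x <- design$x
  if (nrow(x) != nrow(conc$hbo)) {
    abort("design and concentration series have different lengths",
          class = "nirsflow_config_error")
  }
  nb <- length(design$basis$means)
  conditions <- design$conditions
  n_cond <- length(conditions)
  n_hrf <- n_cond * nb
  p <- ncol(x)
  r_chol <- design$chol_ctc

  lag <- hrf_lag_grid(fs, design$basis$t_range)
  b_lag <- basis_matrix(design$basis, lag)
  n_long <- ncol(conc$hbo)
  hrf <- array(NA_real_, c(n_long, n_cond, 2, length(lag)),
               dimnames = list(NULL, conditions, c("hbo", "hbr"), NULL))
  sigma2 <- matrix(NA_real_, n_long, 2, dimnames = list(NULL, c("hbo", "hbr")))
  beta_store <- array(NA_real_, c(n_long, 2, p + 1L))

  sel_tbl <- dplyr::bind_rows(select_ss_channel(conc, "hbo"),
                              select_ss_channel(conc, "hbr"))
  if (!ss) sel_tbl$ss_channel <- NA_integer_

  for (ci in 1:2) {
    chrom <- c("hbo", "hbr")[ci]
    y_all <- conc[[chrom]]
    s_all <- conc[[paste0("ss_", chrom)]]
    ok <- colSums(is.na(y_all)) == 0L
    if (!any(ok)) next
    y <- y_all[, ok, drop = FALSE]
    cty <- crossprod(x, y)
    yty <- colSums(y^2)
    sel <- sel_tbl$ss_channel[sel_tbl$chromophore == chrom][ok]
    # precompute per short channel: standardized series, C's and u
    ss_info <- list()
    for (sid in unique(sel[!is.na(sel)])) {
      s_col <- s_all[, match(sid, conc$ss_channels$channel)]
      s_col <- (s_col - mean(s_col)) / sd(s_col)
      cts <- crossprod(x, s_col)
      u <- backsolve(r_chol, cts, transpose = TRUE)
      ss_info[[as.character(sid)]] <-
        list(s = s_col, cts = cts, u = u,
             denom = sum(s_col^2) - sum(u^2))
    }
    for (j in seq_len(ncol(y))) {
      v <- backsolve(r_chol, cty[, j], transpose = TRUE)
      sid <- sel[j]
      if (!is.na(sid) && ss_info[[as.character(sid)]]$denom > 1e-10) {
        info <- ss_info[[as.character(sid)]]
        sty <- sum(info$s * y[, j])
        gamma <- (sty - sum(info$u * v)) / info$denom
        beta <- backsolve(r_chol, v - gamma * info$u)
        rss <- yty[j] - sum(v^2) - gamma^2 * info$denom
        df <- nrow(x) - p - 1L
      } else {
        gamma <- NA_real_
        beta <- backsolve(r_chol, v)
        rss <- yty[j] - sum(v^2)
        df <- nrow(x) - p
      }
      jj <- which(ok)[j]
      beta_store[jj, ci, ] <- c(beta, gamma)
      sigma2[jj, ci] <- max(rss, 0) / df
      bmat <- matrix(beta[seq_len(n_hrf)], nb, n_cond)
      hrf[jj, , ci, ] <- t(b_lag %*% bmat)
    }
  }
  # baseline correction over [-2, 0] s
  base_idx <- which(lag >= design$basis$t_range[1] & lag <= 0)
  base_mean <- rowMeans(hrf[, , , base_idx, drop = FALSE], dims = 3)
  hrf <- hrf - array(base_mean, dim(hrf))
  structure(list(
    hrf = hrf, lag = lag, coefficients = beta_store, sigma2 = sigma2,
    ss_selected = sel_tbl, channels = conc$channels,
    excluded = conc$excluded, conditions = conditions,
    basis = design$basis, drift_order = design$drift_order,
    ss_used = ss, sampling_rate = conc$sampling_rate, native_rate = fs
  ), class = "nirs_hrf_fit")
}

#' Concatenate preprocessed runs
#'
#' Stacks the concentration series of several runs of the same subject and
#' probe; the GLM then fits one HRF per condition across runs with run-wise
#' drift regressors. A channel excluded in any run is excluded from the
#' concatenation.
#'
#' @param conc_list List of `nirs_conc`, one per run.
#' @return A `nirs_conc` with `schedules` set and series stacked in time.
#' @export
bind_runs <- function(conc_list) {
  stopifnot(length(conc_list) >= 1)
  out <- conc_list[[1]]
  if (length(conc_list) > 1) {
    for (f in c("hbo", "hbr", "ss_hbo", "ss_hbr")) {
      out[[f]] <- do.call(rbind, lapply(conc_list, `[[`, f))
    }
    out$excluded <- dplyr::distinct(
      dplyr::bind_rows(lapply(conc_list, `[[`, "excluded")))
  }
  out$schedules <- lapply(conc_list, `[[`, "schedule")
  out$run_lengths <- vapply(conc_list, function(c) nrow(c$hbo), integer(1))
  out
}

#' @rdname fit_hrf_glm
#' @param x A `nirs_hrf_fit`.
#' @param ... Unused.
#' @export
tidy.nirs_hrf_fit <- function(x, ...) {
  d <- dim(x$hrf)
  tidyr::expand_grid(
    lag = x$lag,
    chromophore = c("hbo", "hbr"),
    condition = x$conditions,
    channel = x$channels$channel
  )[, 4:1] |>
    dplyr::mutate(estimate = c(x$hrf)) |>
    dplyr::arrange(.data$channel, .data$condition, .data$chromophore,
                   .data$lag)
}

#' @rdname fit_hrf_glm
#' @export
glance.nirs_hrf_fit <- function(x, ...) {
  tibble(
    n_channels = nrow(x$channels),
    n_excluded = nrow(x$excluded),
    n_conditions = length(x$conditions),
    n_basis = length(x$basis$means),
    drift_order = x$drift_order,
    ss_used = x$ss_used,
    mean_sigma = sqrt(mean(x$sigma2, na.rm = TRUE))
  )
}

#' @export
print.nirs_hrf_fit <- function(x, ...) {
  cat("<nirs_hrf_fit> ", dim(x$hrf)[1], " channels x ", dim(x$hrf)[2],
      " conditions x 2 chromophores on ", length(x$lag), " lags (",
      min(x$lag), "..", max(x$lag), " s)",
      if (x$ss_used) " with short-separation regression", "\n", sep = "")
  invisible(x)
}
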