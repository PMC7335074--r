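#' Plot group ROI time courses with confidence bands
#'
#' Group-mean HRF per condition with pointwise 95% confidence bands, one
#' panel per ROI, for one chromophore.
#'
#' @param object A `nirs_roi_hrf`.
#' @param conditions Conditions to draw (default all).
#' @param chromophore `"hbo"` or `"hbr"`.
#' @param level Confidence level of the band.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nirs_roi_hrf <- function(object, conditions = NULL,
                                  chromophore = "hbo", level = 0.95, ...) {
  conditions <- conditions %||% object$conditions
  bands <- purrr::map_dfr(seq_len(nrow(object$rois)), function(k) {
    purrr::map_dfr(conditions, function(cc) {
      m <- object$hrf[, k, cc, chromophore, , drop = TRUE]
      m <- matrix(m, nrow = dim(object$hrf)[1])
      m <- m[stats::complete.cases(m), , drop = FALSE]
      if (nrow(m) < 2) return(NULL)
      confidence_band(m, lag = object$lag, level = level) |>
        dplyr::mutate(roi = object$rois$roi[k],
                      hemisphere = object$rois$hemisphere[k],
                      condition = cc)
    })
  })
  ggplot2::ggplot(bands, ggplot2::aes(.data$lag, .data$mean,
                                      colour = .data$condition,
                                      fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_grid(hemisphere ~ roi) +
    ggplot2::labs(x = "time since onset (s)",
                  y = sprintf("%s change (M)", toupper(chromophore)),
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot one channel of a raw scan
#'
#' @param scan A `nirs_scan`.
#' @param channel Channel id.
#' @return A ggplot object.
#' @export
plot_channel <- function(scan, channel = 1) {
  idx <- match(channel, scan$probe$channels$channel)
  n <- dim(scan$intensity)[1]
  df <- tibble(
    time = rep((seq_len(n) - 1) / scan$sampling_rate, 2),
    wavelength = factor(rep(scan$wavelengths, each = n)),
    intensity = c(scan$intensity[, idx, 1], scan$intensity[, idx, 2])
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$intensity,
                                   colour = .data$wavelength)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = scan$schedule$events$onset,
                        alpha = 0.2, linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "intensity (a.u.)",
                  colour = "wavelength (nm)") +
    ggplot2::theme_minimal()
}
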