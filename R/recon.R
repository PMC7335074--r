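#' Toy sensitivity matrix on a flattened voxel grid
#'
#' Stand-in for a photon-migration sensitivity profile: each long channel's
#' row is a Gaussian kernel centered at its source-detector midpoint on a 2D
#' scalp-tangent grid, with width proportional to the channel separation,
#' normalized to unit row sum. Only the algebra of the inverse problem is
#' contractual; this builder provides a geometrically plausible, strictly
#' non-negative operator with overlapping support for channels that share an
#' optode.
#'
#' @param layout A `nirs_probe`.
#' @param spacing Voxel grid spacing (cm).
#' @param width_scale Kernel SD as a fraction of channel separation.
#' @param margin Grid margin beyond the optode bounding box (cm).
#' @return A `nirs_sensitivity`: matrix `a` `[long channel x voxel]`, voxel
#'   `grid` tibble (`voxel`, `x`, `y`), and channel ids.
#' @export
build_toy_sensitivity <- function(layout, spacing = 0.5, width_scale = 0.5,
                                  margin = 2) {
  ch <- layout$channels
  long <- ch[ch$type == "long", ]
  opt <- layout$optodes
  xs <- seq(min(opt$x) - margin, max(opt$x) + margin, by = spacing)
  ys <- seq(min(opt$y) - margin, max(opt$y) + margin, by = spacing)
  if (length(xs) == 0 || length(ys) == 0) {
    abort("empty reconstruction grid", class = "nirsflow_config_error")
  }
  grid <- tidyr::expand_grid(x = xs, y = ys)
  grid <- dplyr::mutate(grid, voxel = dplyr::row_number(),
                        .before = "x")
  d2 <- outer(long$x, grid$x, "-")^2 + outer(long$y, grid$y, "-")^2
  sigma <- width_scale * long$separation
  a <- exp(-d2 / (2 * sigma^2))
  a <- a / rowSums(a)
  structure(list(a = a, grid = grid, channels = long$channel,
                 spacing = spacing, width_scale = width_scale),
            class = "nirs_sensitivity")
}

#' Regularized minimum-norm image reconstruction
#'
#' Solves the underdetermined forward model `y = A X` for the voxel image
#' `X` by the Tikhonov-regularized minimum-norm inverse
#' `X = A' (A A' + lambda I)^{-1} y`, computed with a Cholesky solve (no
#' explicit inverse). `y` is a channel-space vector - typically the mean of
#' the estimated hemodynamic response over a time window.
#'
#' @param y Numeric vector, one value per sensitivity-matrix channel.
#' @param sensitivity A `nirs_sensitivity` (or bare matrix `A`).
#' @param lambda Regularization parameter (default 0.01), applied to the
#'   unscaled identity exactly as written; set `scaled = TRUE` to scale
#'   `lambda` by `max(diag(AA'))` as some tomography codes do.
#' @param scaled Scale lambda by the largest diagonal entry of `AA'`.
#' @return A `nirs_recon_map`: tibble `image` (`voxel`, `x`, `y`, `value`)
#'   plus `lambda`; or, for a bare-matrix call, the numeric voxel vector.
#' @export
reconstruct_map <- function(y, sensitivity, lambda = 0.01, scaled = FALSE) {
  a <- if (inherits(sensitivity, "nirs_sensitivity")) sensitivity$a
       else as.matrix(sensitivity)
  if (length(y) != nrow(a)) {
    abort("y must have one value per channel row of A",
          class = "nirsflow_config_error")
  }
  if (lambda < 0) abort("lambda must be >= 0", class = "nirsflow_config_error")
  aat <- tcrossprod(a)
  lam <- if (scaled) lambda * max(diag(aat)) else lambda
  m <- aat + diag(lam, nrow(aat))
  r <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(r)) {
    abort("A A' + lambda I is singular; use lambda > 0",
          class = "nirsflow_config_error")
  }
  sol <- as.numeric(crossprod(a, backsolve(r, backsolve(r, y,
                                                        transpose = TRUE))))
  if (!inherits(sensitivity, "nirs_sensitivity")) return(sol)
  structure(list(
    image = dplyr::mutate(sensitivity$grid, value = sol),
    lambda = lambda, scaled = scaled
  ), class = "nirs_recon_map")
}

#' Window-averaged reconstruction maps
#'
#' Averages the group-mean HRF over the baseline window (-2..0 s) and every
#' consecutive 3 s window after stimulus onset, and reconstructs one map per
#' window, condition and chromophore.
#'
#' @param group A `nirs_group_hrf` (group-mean responses are reconstructed)
#'   or a single `nirs_hrf_fit`.
#' @param sensitivity A `nirs_sensitivity` built on the same layout.
#' @param lambda Regularization parameter.
#' @param conditions Conditions to map (default all).
#' @param window_length Post-onset window length (s).
#' @return Tibble: `condition`, `chromophore`, `window_start`, `window_end`,
#'   `voxel`, `x`, `y`, `value`.
#' @export
window_maps <- function(group, sensitivity, lambda = 0.01,
                        conditions = NULL, window_length = 3) {
  if (inherits(group, "nirs_hrf_fit")) group <- stack_hrf_fits(list(group))
  lag <- group$lag
  conditions <- conditions %||% group$conditions
  wins <- rbind(c(min(lag), 0),
                cbind(seq(0, max(lag) - window_length, by = window_length),
                      seq(window_length, max(lag), by = window_length)))
  # group-mean HRF per channel (subjects with NA channels dropped per channel)
  gm <- colMeans(group$hrf, na.rm = TRUE, dims = 1)
  purrr::map_dfr(seq_len(nrow(wins)), function(w) {
    widx <- which(lag >= wins[w, 1] & lag <= wins[w, 2])
    purrr::map_dfr(conditions, function(cc) {
      purrr::map_dfr(c("hbo", "hbr"), function(ch) {
        y <- rowMeans(gm[, cc, ch, widx, drop = FALSE], dims = 1)
        y[!is.finite(y)] <- 0
        rec <- reconstruct_map(as.numeric(y), sensitivity, lambda)
        dplyr::mutate(rec$image, condition = cc, chromophore = ch,
                      window_start = wins[w, 1], window_end = wins[w, 2],
                      .before = "voxel")
      })
    })
  })
}

#' Plot a reconstructed map
#'
#' @param object A `nirs_recon_map`.
#' @param ... Unused.
#' @export
autoplot.nirs_recon_map <- function(object, ...) {
  ggplot2::ggplot(object$image, ggplot2::aes(.data$x, .data$y,
                                             fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (cm)", y = "y (cm)",
                  fill = "concentration\nchange (M)") +
    ggplot2::theme_minimal()
}
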