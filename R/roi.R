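#' Region-of-interest channel map
#'
#' Six regions of interest per hemisphere over the long-separation channels:
#' pars opercularis IFG / ventral premotor cortex (`IFG/PMv`), primary motor
#' cortex (`M1`), inferior parietal lobule / supramarginal gyrus (`IPL/SMG`),
#' middle occipital gyrus (`MOG`), temporo-parietal junction (`TPJ`) and
#' superior temporal sulcus (`STS`). The packaged assignment is a plausible
#' partition of the schematic probe by channel position (anterior-inferior to
#' posterior); replace it with [read_roi_map()] when channel-level anatomy is
#' available.
#'
#' @param layout A `nirs_probe`.
#' @return A tibble with columns `roi`, `hemisphere`, `channel`.
#' @export
default_roi_map <- function(layout) {
  ch <- layout$channels
  long <- ch[ch$type == "long", ]
  sizes <- c("IFG/PMv" = 5, "M1" = 5, "IPL/SMG" = 5, "MOG" = 4,
             "TPJ" = 4, "STS" = 3)
  purrr::map_dfr(split(long, long$hemisphere), function(h) {
    h <- h[order(h$x, h$y), ]
    stopifnot(nrow(h) == sum(sizes))
    tibble(
      roi = rep(names(sizes), sizes),
      hemisphere = h$hemisphere[1],
      channel = h$channel
    )
  })
}

#' Read / write an ROI map as YAML
#'
#' The YAML layout is a named list `roi name -> list(hemisphere, channels)`;
#' one entry per (roi, hemisphere).
#'
#' @param path File path.
#' @param roi_map A tibble as returned by [default_roi_map()].
#' @param layout Optional `nirs_probe` used to validate channel ids.
#' @return `read_roi_map()` returns the tibble; `write_roi_map()` the path,
#'   invisibly.
#' @export
read_roi_map <- function(path, layout = NULL) {
  raw <- yaml::read_yaml(path)
  out <- purrr::map_dfr(raw, function(e) {
    tibble(hemisphere = e$hemisphere, channel = as.integer(e$channels))
  }, .id = "entry")
  out$roi <- sub("\\.(left|right)$", "", out$entry)
  out <- out[, c("roi", "hemisphere", "channel")]
  if (!is.null(layout)) {
    bad <- setdiff(out$channel, layout$channels$channel)
    if (length(bad) > 0) {
      abort(sprintf("ROI map references unknown channels: %s",
                    paste(bad, collapse = ", ")),
            class = "nirsflow_config_error")
    }
  }
  out
}

#' @rdname read_roi_map
#' @export
write_roi_map <- function(roi_map, path) {
  keys <- split(roi_map, paste0(roi_map$roi, ".", roi_map$hemisphere))
  out <- purrr::map(keys, function(e) {
    list(hemisphere = e$hemisphere[1], channels = as.integer(e$channel))
  })
  yaml::write_yaml(out, path)
  invisible(path)
}
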