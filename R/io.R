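#' Write / read a raw scan as CSV with a JSON sidecar
#'
#' The intensity matrix is written as plain CSV (time in rows; one column
#' per channel x wavelength, named `ch<id>_w<nm>`), and the layout, schedule
#' and acquisition metadata go to a JSON sidecar next to it
#' (`<path>.json`). This is the package's interchange format for raw scans.
#'
#' @param scan A `nirs_scan`.
#' @param path CSV file path.
#' @return `write_scan_csv()` returns `path` invisibly; `read_scan_csv()`
#'   returns a `nirs_scan`.
#' @export
write_scan_csv <- function(scan, path) {
  stopifnot(inherits(scan, "nirs_scan"))
  d <- dim(scan$intensity)
  ids <- scan$probe$channels$channel
  m <- matrix(scan$intensity, d[1], d[2] * d[3])
  colnames(m) <- paste0("ch", rep(ids, times = d[3]),
                        "_w", rep(scan$wavelengths, each = d[2]))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  sidecar <- list(
    wavelengths = scan$wavelengths,
    sampling_rate = scan$sampling_rate,
    run_id = scan$run_id,
    events = scan$schedule$events,
    design = unclass(scan$schedule$spec),
    optodes = scan$probe$optodes,
    channels = scan$probe$channels
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_scan_csv
#' @param path CSV file path written by [write_scan_csv()].
#' @export
read_scan_csv <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  probe <- structure(list(optodes = as_tibble(side$optodes),
                          channels = as_tibble(side$channels)),
                     class = "nirs_probe")
  spec <- do.call(design_spec, side$design[
    c("conditions", "trials_per_condition", "trial_duration", "isi_range",
      "initial_baseline", "n_runs", "run_duration", "sampling_rate")])
  schedule <- structure(list(events = as_tibble(side$events),
                             run_id = side$run_id, spec = spec),
                        class = "nirs_schedule")
  n_ch <- nrow(probe$channels)
  structure(list(
    intensity = array(m, c(nrow(m), n_ch, length(side$wavelengths))),
    wavelengths = side$wavelengths,
    sampling_rate = side$sampling_rate,
    schedule = schedule,
    probe = probe,
    run_id = side$run_id
  ), class = "nirs_scan")
}

#' Write study results as tidy CSV files with provenance
#'
#' Writes `contrasts.csv`, `temporal_summary.csv`, `time_to_peak.csv`,
#' `roi_hrf_group_mean.csv` and (when present) `recon_maps.csv`, plus
#' `provenance.json` holding the configuration hash and master seed. Every
#' CSV carries the hash in a header comment line.
#'
#' @param study A `nirs_study`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(study, dir) {
  stopifnot(inherits(study, "nirs_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stamp <- sprintf("# nirsflow config %s seed %d", study$hash, study$seed)
  emit <- function(df, name) {
    path <- file.path(dir, name)
    writeLines(stamp, path)
    suppressWarnings(
      utils::write.table(df, path, append = TRUE, sep = ",",
                         row.names = FALSE, qmethod = "double"))
    path
  }
  emit(study$contrasts, "contrasts.csv")
  emit(study$temporal$summary, "temporal_summary.csv")
  emit(study$temporal$per_subject, "time_to_peak.csv")
  gm <- tidy(study$roi_hrf) |>
    dplyr::group_by(.data$roi, .data$hemisphere, .data$condition,
                    .data$chromophore, .data$lag) |>
    dplyr::summarise(mean = mean(.data$estimate, na.rm = TRUE),
                     .groups = "drop")
  emit(gm, "roi_hrf_group_mean.csv")
  if (!is.null(study$recon)) emit(study$recon, "recon_maps.csv")
  jsonlite::write_json(
    list(hash = study$hash, seed = study$seed,
         n_subjects = study$config$n_subjects),
    file.path(dir, "provenance.json"), auto_unbox = TRUE)
  invisible(dir)
}
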