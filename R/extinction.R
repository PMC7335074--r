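# Molar decadic extinction coefficients for hemoglobin, 1/(cm M), from the
# standard compiled spectra used throughout continuous-wave NIRS. Values at
# the two instrument wavelengths.
.extinction_table <- data.frame(
  wavelength = c(690, 830),
  hbo = c(276.0, 974.0),
  hbr = c(2051.96, 693.04)
)

#' Hemoglobin extinction coefficient matrix
#'
#' Returns the 2 x 2 extinction matrix `E` with rows indexed by wavelength and
#' columns `(HbO, HbR)`, used by the modified Beer-Lambert law. Optical
#' density in this package is defined with the natural logarithm, so the
#' tabulated decadic coefficients are multiplied by `ln(10)` by default.
#'
#' @param wavelengths Wavelengths in nm; must be a subset of the packaged
#'   table (690, 830).
#' @param log_base `"e"` (default, matches `-ln` optical density) or `"10"`
#'   for the raw decadic values.
#' @return Numeric matrix `[wavelength x chromophore]` in 1/(cm M).
#' @export
extinction_coefficients <- function(wavelengths = c(690, 830),
                                    log_base = c("e", "10")) {
  log_base <- match.arg(log_base)
  idx <- match(wavelengths, .extinction_table$wavelength)
  if (anyNA(idx)) {
    abort(sprintf("no extinction coefficients tabulated for %s nm",
                  paste(wavelengths[is.na(idx)], collapse = ", ")),
          class = "nirsflow_config_error")
  }
  e <- as.matrix(.extinction_table[idx, c("hbo", "hbr")])
  rownames(e) <- as.character(wavelengths)
  colnames(e) <- c("hbo", "hbr")
  if (log_base == "e") e <- e * log(10)
  if (abs(det(e)) < 1e-12 * prod(sqrt(rowSums(e^2)))) {
    abort("extinction matrix is singular: wavelengths are degenerate",
          class = "nirsflow_config_error")
  }
  e
}
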