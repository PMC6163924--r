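#' Nominal spectrometer wavelength grid
#'
#' The array-spectrometer grid assumed throughout: 300--1140 nm at a nominal
#' 3.3 nm step, the resolution of field silicon-diode array instruments.
#'
#' @param from,to wavelength range in nm.
#' @param step grid step in nm.
#' @return numeric vector of wavelengths (nm), strictly increasing.
#' @export
spectral_grid <- function(from = 300, to = 1140, step = 3.3) {
  seq(from, to, by = step)
}

#' Construct a reflectance spectrum
#'
#' A spectrum is the reflectance of one plot at one date on a common
#' wavelength grid; it is the substrate of all index and unmixing math.
#' Reflectance is unitless; values above 1 up to 1.5 are tolerated
#' (calibration overshoot against a white standard) but flagged.
#'
#' @param wavelengths wavelengths in nm, strictly increasing.
#' @param reflectance reflectance per band, same length as `wavelengths`.
#' @param plot_id,date optional labels.
#' @return object of class `"spectrum"`: a list with elements
#'   `wavelengths`, `reflectance`, `plot_id`, `date`, and logical
#'   `overshoot` flagging any reflectance above 1.
#' @export
spectrum <- function(wavelengths, reflectance, plot_id = NA_character_,
                     date = NA_character_) {
  wavelengths <- as.numeric(wavelengths)
  reflectance <- as.numeric(reflectance)
  if (length(wavelengths) != length(reflectance))
    stop_ev("ev_config_error", "wavelengths and reflectance differ in length")
  if (length(wavelengths) < 2 || any(diff(wavelengths) <= 0))
    stop_ev("ev_config_error", "wavelengths must be strictly increasing (>= 2 bands)")
  if (any(!is.finite(reflectance)))
    stop_ev("ev_config_error", "reflectance contains non-finite values")
  if (any(reflectance < 0) || any(reflectance > 1.5))
    stop_ev("ev_config_error", "reflectance outside [0, 1.5]")
  structure(
    list(wavelengths = wavelengths, reflectance = reflectance,
         plot_id = plot_id, date = date,
         overshoot = any(reflectance > 1)),
    class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> plot %s, date %s: %d bands, %.1f-%.1f nm, reflectance %.3f-%.3f%s\n",
              x$plot_id, x$date, length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths),
              min(x$reflectance), max(x$reflectance),
              if (isTRUE(x$overshoot)) " [overshoot > 1]" else ""))
  invisible(x)
}

#' Nearest-band reflectance lookup
#'
#' Returns the reflectance at the grid wavelength nearest to a nominal
#' wavelength. Index definitions name nominal bands (e.g. 670 nm) that do
#' not fall exactly on the 3.3 nm grid; no interpolation is applied. Exact
#' ties are broken toward the lower wavelength.
#'
#' @param spec a [spectrum()].
#' @param nominal_nm requested wavelength in nm; must lie within the grid
#'   range.
#' @return reflectance at the nearest grid band (scalar).
#' @export
band <- function(spec, nominal_nm) {
  w <- spec$wavelengths
  if (nominal_nm < w[1] || nominal_nm > w[length(w)])
    stop_ev("ev_range_error",
            sprintf("wavelength %.1f nm outside grid range [%.1f, %.1f]",
                    nominal_nm, w[1], w[length(w)]))
  spec$reflectance[band_index(w, nominal_nm)]
}

# nearest index on an increasing grid, ties toward the lower wavelength
band_index <- function(wavelengths, nominal_nm) {
  d <- abs(wavelengths - nominal_nm)
  # which.min returns the first (lower-wavelength) minimizer; guard the
  # floating-point near-tie at half the grid step
  i <- which.min(d)
  if (i > 1 && abs(d[i - 1] - d[i]) < 1e-9) i - 1L else i
}

#' Write spectra to CSV
#'
#' Wide layout: first column `wavelength_nm`, one column per plot id. All
#' spectra must share one grid (and, by convention, one date per file).
#'
#' @param spectra list of [spectrum()] objects on a common grid.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(length(spectra) >= 1)
  w <- spectra[[1]]$wavelengths
  for (s in spectra)
    if (!isTRUE(all.equal(s$wavelengths, w)))
      stop_ev("ev_alignment_error", "spectra are not on a common wavelength grid")
  m <- vapply(spectra, function(s) s$reflectance, numeric(length(w)))
  df <- data.frame(wavelength_nm = w, m, check.names = FALSE)
  names(df)[-1] <- vapply(spectra, function(s) as.character(s$plot_id), "")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read spectra from CSV
#'
#' Inverse of [write_spectra_csv()].
#'
#' @param path CSV path with a `wavelength_nm` column and one column per plot.
#' @param date optional date label attached to every spectrum.
#' @return list of [spectrum()] objects named by plot id.
#' @export
read_spectra_csv <- function(path, date = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"wavelength_nm" %in% names(df))
    stop_ev("ev_config_error", "spectra CSV lacks a wavelength_nm column")
  w <- df$wavelength_nm
  ids <- setdiff(names(df), "wavelength_nm")
  out <- lapply(ids, function(id) spectrum(w, df[[id]], plot_id = id, date = date))
  names(out) <- ids
  out
}
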