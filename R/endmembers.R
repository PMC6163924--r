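#' Endmember spectral library
#'
#' Bundles a bare-soil and a dense-vegetation reference spectrum on one
#' wavelength grid. These are the two pure surface types that linear
#' unmixing decomposes a mixed canopy spectrum into, and the mixing basis of
#' the synthetic generator. When `soil`/`vegetation` are omitted, parametric
#' curves are supplied: a gently brightening brown soil ramp, and a
#' vegetation spectrum with a green reflectance bump near 550 nm, a red
#' absorption trough near 670 nm, a sigmoidal red edge centered near 715 nm
#' rising to a NIR plateau, a shallow water absorption dip near 970 nm and a
#' mild decline beyond 1000 nm. The shapes are qualitatively realistic;
#' they are not field measurements.
#'
#' @param wavelengths grid in nm (default [spectral_grid()]).
#' @param soil,vegetation reflectance vectors on `wavelengths`; defaults are
#'   the parametric curves above.
#' @return object of class `"endmember_library"`: list with `wavelengths`,
#'   `soil`, `vegetation`.
#' @export
endmember_library <- function(wavelengths = spectral_grid(),
                              soil = NULL, vegetation = NULL) {
  w <- as.numeric(wavelengths)
  if (length(w) < 2 || any(diff(w) <= 0))
    stop_ev("ev_config_error", "wavelengths must be strictly increasing")
  if (is.null(soil)) soil <- default_soil_curve(w)
  if (is.null(vegetation)) vegetation <- default_vegetation_curve(w)
  if (length(soil) != length(w) || length(vegetation) != length(w))
    stop_ev("ev_config_error", "endmember length does not match the grid")
  if (any(soil < 0 | soil > 1) || any(vegetation < 0 | vegetation > 1))
    stop_ev("ev_config_error", "endmember reflectance outside [0, 1]")
  # require a usable red edge so downstream indices are non-degenerate
  if (w[1] <= 670 && w[length(w)] >= 780) {
    v <- spectrum(w, vegetation)
    if (band(v, 780) - band(v, 670) < 0.25)
      stop_ev("ev_config_error",
              "vegetation endmember lacks a red-edge step (R780 - R670 < 0.25)")
  }
  structure(list(wavelengths = w, soil = soil, vegetation = vegetation),
            class = "endmember_library")
}

# brown soil: brightness increasing almost linearly with wavelength
default_soil_curve <- function(w) {
  0.08 + 0.00028 * (w - 300) + 0.015 * sin((w - 300) / 900)
}

# green vegetation: green bump, red trough, red-edge sigmoid, NIR plateau
# with a shallow 970 nm water dip and decline beyond 1000 nm
default_vegetation_curve <- function(w) {
  base <- 0.035 + 0.06 * exp(-((w - 550) / 35)^2)
  plateau <- 0.42 / (1 + exp(-(w - 715) / 12))
  water_dip <- -0.03 * exp(-((w - 970) / 28)^2)
  tail_decline <- -0.00012 * pmax(w - 1000, 0)
  pmin(pmax(base + plateau + water_dip + tail_decline, 0), 1)
}

#' @export
print.endmember_library <- function(x, ...) {
  cat(sprintf("<endmember_library> %d bands, %.1f-%.1f nm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

# soil / vegetation endmembers as spectrum objects
endmember_spectrum <- function(lib, which = c("soil", "vegetation")) {
  which <- match.arg(which)
  spectrum(lib$wavelengths, lib[[which]], plot_id = which)
}

#' Write an endmember library to CSV
#'
#' Columns `wavelength_nm, soil, vegetation` (one file per date when
#' endmembers are selected per measurement day).
#'
#' @param lib an [endmember_library()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_endmembers_csv <- function(lib, path) {
  utils::write.csv(data.frame(wavelength_nm = lib$wavelengths,
                              soil = lib$soil, vegetation = lib$vegetation),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an endmember library from CSV
#'
#' @param path CSV with columns `wavelength_nm, soil, vegetation`.
#' @return an [endmember_library()].
#' @export
read_endmembers_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("wavelength_nm", "soil", "vegetation")
  if (!all(need %in% names(df)))
    stop_ev("ev_config_error", "endmember CSV needs wavelength_nm, soil, vegetation")
  endmember_library(df$wavelength_nm, df$soil, df$vegetation)
}
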