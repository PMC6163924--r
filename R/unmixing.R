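# Two-endmember linear spectral unmixing.
#
# The mixed canopy spectrum is regressed on the bare-soil and
# dense-vegetation endmember spectra by ordinary least squares without an
# intercept; the cover estimate is the vegetation coefficient divided by
# the sum of both coefficients. Coefficients are left unconstrained (no
# non-negativity, no sum-to-one), so the estimate can exit [0, 1] on noisy
# or mismatched endmembers -- that is informative, not an error.

#' Fit linear spectral unmixing for one spectrum
#'
#' @param mixed observed mixed canopy [spectrum()].
#' @param soil,vegetation endmember [spectrum()] objects on the identical
#'   grid (or an [endmember_library()] passed as `soil` with
#'   `vegetation = NULL`).
#' @param band_range wavelength interval (nm) used in the fit; the default
#'   excludes 300-400 nm, which is dominated by scattering.
#' @param intercept include an intercept term (default FALSE; an intercept
#'   absorbs the soil fraction ambiguously and is exposed only for
#'   sensitivity analysis).
#' @return object of class `"unmix_fit"`: list with `coef_vegetation`,
#'   `coef_soil`, `cover_estimate`, `residual_rms`, `n_bands_used`,
#'   `intercept` (estimated value or NA), `band_range`.
#' @export
fit_unmixing <- function(mixed, soil, vegetation = NULL,
                         band_range = c(400, 1140), intercept = FALSE) {
  if (inherits(soil, "endmember_library") && is.null(vegetation)) {
    lib <- soil
    soil <- endmember_spectrum(lib, "soil")
    vegetation <- endmember_spectrum(lib, "vegetation")
  }
  w <- mixed$wavelengths
  if (!isTRUE(all.equal(w, soil$wavelengths)) ||
      !isTRUE(all.equal(w, vegetation$wavelengths)))
    stop_ev("ev_alignment_error", "mixed and endmember spectra must share one grid")
  sel <- w >= band_range[1] & w <= band_range[2]
  if (sum(sel) < (2 + intercept))
    stop_ev("ev_range_error", "band_range contains too few grid bands")
  y <- mixed$reflectance[sel]
  s <- soil$reflectance[sel]
  v <- vegetation$reflectance[sel]
  X <- if (intercept) cbind(`(Intercept)` = 1, soil = s, vegetation = v)
       else cbind(soil = s, vegetation = v)
  if (kappa(X, exact = TRUE) > 1e8)
    stop_ev("ev_degenerate_error",
            "endmember spectra are (near-)collinear; unmixing is degenerate")
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  cs <- cf[["soil"]]; cv <- cf[["vegetation"]]
  if (abs(cs + cv) < 1e-12)
    stop_ev("ev_undefined_cover_error",
            "coefficients sum to zero; cover estimate undefined")
  structure(list(
    coef_vegetation = cv, coef_soil = cs,
    cover_estimate = cv / (cv + cs),
    residual_rms = sqrt(mean(fit$residuals^2)),
    n_bands_used = sum(sel),
    intercept = if (intercept) cf[["(Intercept)"]] else NA_real_,
    band_range = band_range),
    class = "unmix_fit")
}

#' @export
print.unmix_fit <- function(x, ...) {
  cat(sprintf(
    "<unmix_fit> cover %.4f (veg %.4f, soil %.4f), RMS %.2e, %d bands [%g-%g nm]\n",
    x$cover_estimate, x$coef_vegetation, x$coef_soil, x$residual_rms,
    x$n_bands_used, x$band_range[1], x$band_range[2]))
  invisible(x)
}

#' @export
coef.unmix_fit <- function(object, ...) {
  c(soil = object$coef_soil, vegetation = object$coef_vegetation)
}

#' Unmix every spectrum of a trial
#'
#' Applies [fit_unmixing()] per plot with one endmember pair per date
#' (endmembers were selected per measurement day in the field protocol).
#' Degenerate fits are recorded as missing with their reason, never
#' silently dropped.
#'
#' @param spectra list of [spectrum()] objects carrying `plot_id` and
#'   `date` labels.
#' @param endmembers either one [endmember_library()] used for all dates,
#'   or a named list of libraries keyed by date label.
#' @param band_range,intercept passed to [fit_unmixing()].
#' @return data.frame `plot_id, date, cover_estimate, coef_veg, coef_soil,
#'   residual_rms, missing_reason`.
#' @export
unmix_trial <- function(spectra, endmembers, band_range = c(400, 1140),
                        intercept = FALSE) {
  per_date <- !inherits(endmembers, "endmember_library")
  rows <- lapply(spectra, function(s) {
    lib <- if (per_date) {
      if (is.null(endmembers[[as.character(s$date)]]))
        stop_ev("ev_config_error",
                sprintf("no endmembers supplied for date '%s'", s$date))
      endmembers[[as.character(s$date)]]
    } else endmembers
    res <- tryCatch(fit_unmixing(s, lib, band_range = band_range,
                                 intercept = intercept),
                    earlyvigor_error = function(e)
                      structure(list(reason = class(e)[1]), class = "unmix_miss"))
    if (inherits(res, "unmix_miss"))
      data.frame(plot_id = as.character(s$plot_id), date = as.character(s$date),
                 cover_estimate = NA_real_, coef_veg = NA_real_,
                 coef_soil = NA_real_, residual_rms = NA_real_,
                 missing_reason = res$reason, stringsAsFactors = FALSE)
    else
      data.frame(plot_id = as.character(s$plot_id), date = as.character(s$date),
                 cover_estimate = res$cover_estimate,
                 coef_veg = res$coef_vegetation, coef_soil = res$coef_soil,
                 residual_rms = res$residual_rms,
                 missing_reason = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
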