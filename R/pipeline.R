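# End-to-end pipeline over a trial: sensor method series, contour
# screening, and the method x trait summary.

#' Compute every sensor method series for a trial
#'
#' Produces the long method table consumed by [build_summary()]:
#' image-based canopy cover (HSV segmentation of the rendered quadrat
#' images), the emulated two-band active-sensor NDVI, the spectral
#' unmixing cover estimate, and the nine narrow-band vegetation indices.
#'
#' @param trial a [generate_trial()] result (or compatible list with
#'   `traits`, `spectra`, optional `images`, `endmembers`, `design`).
#' @param thresholds [hsv_thresholds()] for segmentation.
#' @param band_range unmixing band range (nm).
#' @return data.frame `method, plot_id, date_index, value`.
#' @export
method_series <- function(trial, thresholds = hsv_thresholds(),
                          band_range = c(400, 1140)) {
  traits <- trial$traits
  keys <- sprintf("d%d_%s", traits$date_index, traits$plot_id)
  base <- traits[c("plot_id", "date_index")]

  cc_vals <- if (!is.null(trial$images)) {
    vapply(keys, function(k)
      segment_green(trial$images[[k]], thresholds)$canopy_cover, numeric(1))
  } else {
    traits$cc_true
  }
  rows <- list(cbind(base, method = "canopy_cover", value = unname(cc_vals)))

  gs <- vapply(keys, function(k) greenseeker_ndvi(trial$spectra[[k]]), numeric(1))
  rows <- c(rows, list(cbind(base, method = "greenseeker", value = unname(gs))))

  um <- vapply(keys, function(k)
    tryCatch(fit_unmixing(trial$spectra[[k]], trial$endmembers,
                          band_range = band_range)$cover_estimate,
             earlyvigor_error = function(e) NA_real_), numeric(1))
  rows <- c(rows, list(cbind(base, method = "spectral_unmixing",
                             value = unname(um))))

  for (vi in vi_definitions()) {
    vals <- vapply(keys, function(k)
      tryCatch(compute_index(trial$spectra[[k]], vi),
               ev_undefined_value = function(e) NA_real_), numeric(1))
    rows <- c(rows, list(cbind(base, method = vi$name, value = unname(vals))))
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[c("method", "plot_id", "date_index", "value")]
}

#' Contour-map aggregates for every trait of a trial
#'
#' Builds one [contour_matrix()] per trait and date from the trial
#' spectra and aggregates across dates.
#'
#' @param trial a [generate_trial()] result.
#' @param traits trait columns to screen (default dw, nc, nup, cc).
#' @return named list (by trait) of [aggregate_contour()] results.
#' @export
contour_screen <- function(trial, traits = c("dw", "nc", "nup", "cc")) {
  alias <- c(dw = "dw_kg_ha", nc = "nc_pct", nup = "nup_kg_ha", cc = "cc_true")
  tt <- trial$traits
  out <- list()
  for (tr in traits) {
    col <- if (tr %in% names(tt)) tr else alias[[tr]]
    mats <- lapply(seq_len(trial$design$n_dates), function(d) {
      sel <- tt$date_index == d
      keys <- sprintf("d%d_%s", d, tt$plot_id[sel])
      contour_matrix(trial$spectra[keys], tt[[col]][sel], trait = tr,
                     date = as.character(d))
    })
    out[[tr]] <- aggregate_contour(mats)
  }
  out
}

#' Run the full early-vigor analysis on a trial
#'
#' Convenience wrapper: [method_series()], [contour_screen()] and
#' [build_summary()] in one call.
#'
#' @param trial a [generate_trial()] result.
#' @param thresholds segmentation [hsv_thresholds()].
#' @param screen_contour run the exhaustive band-pair screen (default
#'   TRUE; the most expensive stage).
#' @return list with `summary` (a [build_summary()] result), `methods`
#'   (the long method table) and `contour` (named aggregates or NULL).
#' @export
analyze_trial <- function(trial, thresholds = hsv_thresholds(),
                          screen_contour = TRUE) {
  methods <- method_series(trial, thresholds)
  aggs <- if (screen_contour) contour_screen(trial) else NULL
  traits <- trial$traits
  traits$dw <- traits$dw_kg_ha; traits$nc <- traits$nc_pct
  traits$nup <- traits$nup_kg_ha; traits$cc <- traits$cc_true
  list(summary = build_summary(methods, traits, aggs),
       methods = methods, contour = aggs)
}
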