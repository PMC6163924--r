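# Narrow-band vegetation indices and the emulated active-sensor NDVI.
#
# Each definition names its nominal bands; reflectances are resolved by
# nearest-band lookup (see band()). Formulas with a denominator signal a
# classed "ev_undefined_value" error carrying the index name when the
# denominator vanishes, so screening code can record the cell as missing
# instead of propagating NaN.

undefined_value <- function(index, reason = "zero_denominator") {
  stop(structure(
    class = c("ev_undefined_value", "earlyvigor_error", "error", "condition"),
    list(message = sprintf("%s undefined: %s", index, reason),
         index = index, reason = reason, call = sys.call(-1))))
}

nd <- function(a, b, index) {
  if (a + b == 0) undefined_value(index)
  (a - b) / (a + b)
}

#' Vegetation index definitions
#'
#' The nine narrow-band indices evaluated by the pipeline, each a list with
#' `name`, `bands` (nominal nm, named `b<nm>`) and `fun` (a function of the
#' named reflectance vector). The set covers red/NIR ratios (NDVI), red-edge
#' formulations (NDRE, REIP, MTCI, MCARI), a soil-adjusted index (ATSAVI,
#' with its standard adjustment constants 1.22 and 0.03 and soil factor
#' 0.23), a visible-band physiology index (PRI), a two-NIR-band water index
#' (WBI) and an early-plant-vigor index (EPVI). REIP uses the four-band
#' linear-interpolation (Guyot-Baret) form of the red-edge inflection point.
#'
#' @param names optional character vector selecting a subset.
#' @return named list of index definitions.
#' @export
vi_definitions <- function(names = NULL) {
  defs <- list(
    ATSAVI = list(bands = c(800, 670), fun = function(R) {
      den <- 1.22 * R[["b800"]] + R[["b670"]] + 0.23
      if (den == 0) undefined_value("ATSAVI")
      1.22 * (R[["b800"]] - 1.22 * R[["b670"]] - 0.03) / den
    }),
    EPVI = list(bands = c(750, 670, 862), fun = function(R) {
      if (R[["b862"]] == 0) undefined_value("EPVI")
      (R[["b750"]] - R[["b670"]]) / R[["b862"]]
    }),
    MCARI = list(bands = c(700, 670, 550), fun = function(R) {
      if (R[["b670"]] == 0) undefined_value("MCARI")
      ((R[["b700"]] - R[["b670"]]) - 0.2 * (R[["b700"]] - R[["b550"]])) *
        (R[["b700"]] / R[["b670"]])
    }),
    MTCI = list(bands = c(750, 710, 680), fun = function(R) {
      den <- R[["b710"]] - R[["b680"]]
      if (den == 0) undefined_value("MTCI")
      (R[["b750"]] - R[["b710"]]) / den
    }),
    NDRE = list(bands = c(790, 720), fun = function(R)
      nd(R[["b790"]], R[["b720"]], "NDRE")),
    NDVI = list(bands = c(864, 671), fun = function(R)
      nd(R[["b864"]], R[["b671"]], "NDVI")),
    PRI = list(bands = c(531, 570), fun = function(R)
      nd(R[["b531"]], R[["b570"]], "PRI")),
    REIP = list(bands = c(668, 778, 698, 738), fun = function(R) {
      den <- R[["b738"]] - R[["b698"]]
      if (den == 0) undefined_value("REIP")
      700 + 40 * ((R[["b668"]] + R[["b778"]]) / 2 - R[["b698"]]) / den
    }),
    WBI = list(bands = c(900, 970), fun = function(R) {
      if (R[["b970"]] == 0) undefined_value("WBI")
      R[["b900"]] / R[["b970"]]
    })
  )
  for (nm in names(defs)) defs[[nm]]$name <- nm
  if (!is.null(names)) {
    missing <- setdiff(names, base::names(defs))
    if (length(missing))
      stop_ev("ev_config_error", paste("unknown index:", paste(missing, collapse = ", ")))
    defs <- defs[names]
  }
  defs
}

#' Compute one vegetation index on one spectrum
#'
#' Resolves every nominal band of the definition by nearest-band lookup and
#' evaluates the formula.
#'
#' @param spec a [spectrum()].
#' @param vi one element of [vi_definitions()] (or a compatible list with
#'   `name`, `bands`, `fun`).
#' @return scalar index value.
#' @export
compute_index <- function(spec, vi) {
  R <- vapply(vi$bands, function(b) band(spec, b), numeric(1))
  names(R) <- paste0("b", vi$bands)
  vi$fun(R)
}

#' Emulated two-band active-sensor NDVI
#'
#' Active red/NIR canopy sensors measure broad (~25 nm) bands centered near
#' 656 nm and 774 nm. This emulation averages grid reflectance over an
#' unweighted boxcar of +/- `half_width` nm around each center and returns
#' the normalized difference (NIR - red) / (NIR + red).
#'
#' @param spec a [spectrum()].
#' @param center_red,center_nir band centers in nm.
#' @param half_width half band width in nm (default 12.5).
#' @return scalar NDVI.
#' @export
greenseeker_ndvi <- function(spec, center_red = 656, center_nir = 774,
                             half_width = 12.5) {
  boxcar <- function(center) {
    sel <- spec$wavelengths >= center - half_width &
      spec$wavelengths <= center + half_width
    if (!any(sel))
      stop_ev("ev_range_error",
              sprintf("no grid bands within %.1f +/- %.1f nm", center, half_width))
    mean(spec$reflectance[sel])
  }
  r <- boxcar(center_red); n <- boxcar(center_nir)
  nd(n, r, "greenseeker_ndvi")
}

#' Index value table over a collection of spectra
#'
#' Evaluates a set of index definitions on every spectrum. Undefined values
#' (zero denominators) are recorded as missing with their reason, never
#' silently dropped.
#'
#' @param spectra nonempty list of [spectrum()] objects.
#' @param vis list of index definitions (default all of [vi_definitions()]).
#' @param include_greenseeker also add the emulated active-sensor NDVI row
#'   per spectrum (default FALSE).
#' @return data.frame with columns `plot_id`, `date`, `method`, `value`,
#'   `missing_reason`.
#' @export
index_table <- function(spectra, vis = vi_definitions(),
                        include_greenseeker = FALSE) {
  if (length(spectra) == 0 || length(vis) == 0)
    stop_ev("ev_config_error", "index_table requires spectra and index definitions")
  rows <- list()
  for (s in spectra) {
    for (vi in vis) {
      val <- tryCatch(list(v = compute_index(s, vi), reason = NA_character_),
                      ev_undefined_value = function(e)
                        list(v = NA_real_, reason = e$reason))
      rows[[length(rows) + 1L]] <- data.frame(
        plot_id = as.character(s$plot_id), date = as.character(s$date),
        method = vi$name, value = val$v, missing_reason = val$reason,
        stringsAsFactors = FALSE)
    }
    if (include_greenseeker) {
      val <- tryCatch(list(v = greenseeker_ndvi(s), reason = NA_character_),
                      ev_undefined_value = function(e)
                        list(v = NA_real_, reason = e$reason))
      rows[[length(rows) + 1L]] <- data.frame(
        plot_id = as.character(s$plot_id), date = as.character(s$date),
        method = "greenseeker", value = val$v, missing_reason = val$reason,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
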