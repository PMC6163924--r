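# Published reference values shipped with the package.

#' Published per-date R-squared reference table
#'
#' Per-date squared Pearson correlations of each sensor method with the
#' target traits (dry weight `dw`, N content `nc`, N uptake `nup`, canopy
#' cover `cc`), transcribed from the summary table of a four-date winter
#' wheat early-vigor field study. Cells the study reported as
#' non-significant are missing (`NA`). These values serve as inputs to the
#' summary arithmetic ([summarize_r2()]); the per-date field data behind
#' them were never deposited and cannot be recomputed.
#'
#' @return list with `r2` (data.frame `trait, method, d1..d4`), `contour`
#'   (data.frame `trait, best_mean_r2, cv_at_best, band1_nm, band2_nm`:
#'   the maximum of the mean contour-map matrix and the CV of that band
#'   pair), and `contour_wavelengths` (per-date optimum band pairs).
#' @export
reference_r2_table <- function() {
  path <- function(f) system.file("extdata", f, package = "earlyvigor",
                                  mustWork = TRUE)
  list(r2 = utils::read.csv(path("reference_r2.csv"), stringsAsFactors = FALSE),
       contour = utils::read.csv(path("reference_contour.csv"),
                                 stringsAsFactors = FALSE),
       contour_wavelengths = utils::read.csv(
         path("reference_contour_wavelengths.csv"), stringsAsFactors = FALSE))
}

#' Summary arithmetic applied to the published reference table
#'
#' Reshapes the [reference_r2_table()] values into per-trait
#' [summarize_r2()] calls: mean and CV across dates for rows with all four
#' values, and the contour-map ratio rows. This reproduces the published
#' aggregate columns from the published per-date cells.
#'
#' @return named list (by trait) of [summarize_r2()] results.
#' @export
reference_summary <- function() {
  ref <- reference_r2_table()
  out <- list()
  for (tr in unique(ref$r2$trait)) {
    sub <- ref$r2[ref$r2$trait == tr, ]
    con_row <- sub[sub$method == "contour_map", ]
    meth <- sub[sub$method != "contour_map", ]
    long <- data.frame(
      method = rep(meth$method, times = 4),
      date_index = rep(1:4, each = nrow(meth)),
      r2 = c(meth$d1, meth$d2, meth$d3, meth$d4),
      stringsAsFactors = FALSE)
    ca <- ref$contour[ref$contour$trait == tr, ]
    contour <- list(
      per_date_r2 = as.numeric(con_row[c("d1", "d2", "d3", "d4")]),
      best_mean_r2 = ca$best_mean_r2, cv_at_best = ca$cv_at_best,
      best_pair = c(ca$band1_nm, ca$band2_nm))
    out[[tr]] <- summarize_r2(long, contour, trait = tr, n_dates = 4)
  }
  out
}
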