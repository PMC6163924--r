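# Method x trait correlation summary: per-date R-squared with
# significance, mean and CV across dates, and the contour-map ratio rows.

#' Squared Pearson correlation with significance
#'
#' Direction of the sensor-trait relationship is usually not of interest,
#' so the squared correlation is reported; the two-sided p-value comes from
#' the t transform with n - 2 degrees of freedom. Incomplete pairs are
#' dropped first.
#'
#' @param x,y numeric vectors of paired observations.
#' @return list with `r2`, `p_value`, `n` (complete pairs used).
#' @export
r2_and_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3)
    stop_ev("ev_samplesize_error", "need >= 3 complete paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_ev("ev_undefined_correlation_error",
            "zero variance in x or y; correlation undefined")
  ct <- stats::cor.test(x, y)
  list(r2 = unname(ct$estimate)^2, p_value = ct$p.value, n = n)
}

#' Significance stars
#'
#' `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05
#' (strict inequalities), otherwise an empty string.
#'
#' @param p_value p-value(s) in [0, 1].
#' @return character vector of labels.
#' @export
significance_stars <- function(p_value) {
  vapply(p_value, function(p) {
    if (is.na(p)) return(NA_character_)
    if (p < 0 || p > 1) stop_ev("ev_domain_error", "p-value outside [0, 1]")
    if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  }, character(1))
}

# the nine established narrow-band vegetation indices
ESTABLISHED_VIS <- c("ATSAVI", "EPVI", "MCARI", "MTCI", "NDRE", "NDVI",
                     "PRI", "REIP", "WBI")

#' Summary arithmetic on a per-date R-squared table
#'
#' The aggregation core of the method x trait summary, applicable both to
#' R-squared values computed from data by [build_summary()] and to a
#' transcribed published table. Per method: mean and CV (sample SD / mean)
#' across dates, computed only for rows with a value on every date
#' (non-significant values enter at their raw magnitude; truly missing
#' values propagate). Ratio rows divide the contour-map maximum by the best
#' competing value: per date from values rounded half-up to 2 decimals
#' (the display precision), for the mean column from unrounded means.
#' "Best established sensor method" scans every method except the contour
#' map; "best established hyperspectral vegetation index" scans only the
#' nine narrow-band indices.
#'
#' @param r2_table data.frame with columns `method`, `date_index`, `r2`
#'   and optionally `p_value` for one trait; the contour-map row is
#'   supplied separately.
#' @param contour list with `per_date_r2` (numeric, one per date),
#'   `best_mean_r2` (maximum of the mean contour matrix), `cv_at_best`,
#'   and optionally `per_date_bands` (2 x n_dates) and `best_pair`.
#' @param trait trait label.
#' @param n_dates number of dates.
#' @return list: `methods` (data.frame `method, date_index, r2, stars,
#'   mean_r2, cv_r2`), `contour` (as supplied, plus mean/CV formatting),
#'   `ratio_sensor`, `ratio_vi` (numeric length `n_dates + 1`; the last
#'   element is the mean-column ratio).
#' @export
summarize_r2 <- function(r2_table, contour, trait = NA_character_,
                         n_dates = 4) {
  methods <- unique(r2_table$method)
  has_p <- "p_value" %in% names(r2_table)
  wide <- matrix(NA_real_, length(methods), n_dates,
                 dimnames = list(methods, NULL))
  stars <- matrix("", length(methods), n_dates)
  for (k in seq_len(nrow(r2_table))) {
    i <- match(r2_table$method[k], methods)
    j <- r2_table$date_index[k]
    wide[i, j] <- r2_table$r2[k]
    if (has_p && is.finite(r2_table$p_value[k]))
      stars[i, j] <- significance_stars(r2_table$p_value[k])
  }
  complete <- rowSums(is.na(wide)) == 0
  mean_r2 <- ifelse(complete, rowMeans(wide), NA_real_)
  cv_r2 <- rep(NA_real_, length(methods))
  cv_r2[complete] <- apply(wide[complete, , drop = FALSE], 1, cv_sample)

  ratio_for <- function(candidates) {
    per_date <- vapply(seq_len(n_dates), function(j) {
      best <- suppressWarnings(max(round_half_up(wide[candidates, j]),
                                   na.rm = TRUE))
      if (!is.finite(best) || is.na(contour$per_date_r2[j])) NA_real_
      else round_half_up(round_half_up(contour$per_date_r2[j]) / best)
    }, numeric(1))
    best_mean <- suppressWarnings(max(mean_r2[match(candidates, methods)],
                                      na.rm = TRUE))
    mean_ratio <- if (!is.finite(best_mean) || is.na(contour$best_mean_r2))
      NA_real_ else round_half_up(contour$best_mean_r2 / best_mean)
    c(per_date, mean = mean_ratio)
  }
  sensor_methods <- setdiff(methods, "contour_map")
  vi_methods <- intersect(methods, ESTABLISHED_VIS)
  list(
    trait = trait,
    methods = data.frame(
      method = rep(methods, each = n_dates),
      date_index = rep(seq_len(n_dates), length(methods)),
      r2 = as.vector(t(wide)), stars = as.vector(t(stars)),
      stringsAsFactors = FALSE),
    mean_cv = data.frame(method = methods, mean_r2 = unname(mean_r2),
                         cv_r2 = cv_r2, stringsAsFactors = FALSE),
    contour = contour,
    ratio_sensor = if (length(sensor_methods)) ratio_for(sensor_methods) else NULL,
    ratio_vi = if (length(vi_methods)) ratio_for(vi_methods) else NULL)
}

#' Build the full method x trait summary from data
#'
#' Correlates every sensor method with every target trait per date,
#' attaches significance, aggregates mean and CV across dates, and appends
#' the contour-map rows and ratio rows. Canopy cover is excluded as a
#' method when it is the target trait.
#'
#' @param methods long data.frame of sensor readings: columns `method,
#'   plot_id, date_index, value` (one value per plot x date, or missing).
#' @param traits data.frame with `plot_id, date_index` and trait columns
#'   among `dw, nc, nup, cc` (aliases `dw_kg_ha, nc_pct, nup_kg_ha,
#'   cc_true` are recognized).
#' @param contour_aggregates named list (by trait) of
#'   [aggregate_contour()] results, or NULL to omit contour rows.
#' @return object of class `"vigor_summary"`: named list (by trait) of
#'   [summarize_r2()] results, with attribute `n_dates`.
#' @export
build_summary <- function(methods, traits, contour_aggregates = NULL) {
  alias <- c(dw = "dw_kg_ha", nc = "nc_pct", nup = "nup_kg_ha", cc = "cc_true")
  for (t in names(alias))
    if (!t %in% names(traits) && alias[[t]] %in% names(traits))
      traits[[t]] <- traits[[alias[[t]]]]
  trait_names <- intersect(c("dw", "nc", "nup", "cc"), names(traits))
  if (!length(trait_names))
    stop_ev("ev_config_error", "traits table has no recognized trait column")
  n_dates <- max(traits$date_index)
  if (n_dates < 2)
    stop_ev("ev_samplesize_error", "need >= 2 dates for a summary")
  out <- list()
  for (tr in trait_names) {
    meth_names <- unique(methods$method)
    if (tr == "cc") meth_names <- setdiff(meth_names, "canopy_cover")
    rows <- list()
    for (m in meth_names) for (d in seq_len(n_dates)) {
      mv <- methods[methods$method == m & methods$date_index == d, ]
      tv <- traits[traits$date_index == d, c("plot_id", tr)]
      mg <- merge(mv, tv, by = "plot_id")
      res <- tryCatch(r2_and_p(mg$value, mg[[tr]]),
                      earlyvigor_error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, date_index = d,
        r2 = if (is.null(res)) NA_real_ else res$r2,
        p_value = if (is.null(res)) NA_real_ else res$p_value,
        stringsAsFactors = FALSE)
    }
    r2_tab <- do.call(rbind, rows)
    agg <- contour_aggregates[[tr]]
    contour <- if (is.null(agg)) {
      list(per_date_r2 = rep(NA_real_, n_dates), best_mean_r2 = NA_real_,
           cv_at_best = NA_real_)
    } else {
      list(per_date_r2 = agg$per_date$max_r2,
           per_date_bands = rbind(agg$per_date$band1_nm, agg$per_date$band2_nm),
           best_mean_r2 = agg$best_mean_r2, cv_at_best = agg$cv_at_best,
           best_pair = agg$best_pair)
    }
    out[[tr]] <- summarize_r2(r2_tab, contour, trait = tr, n_dates = n_dates)
  }
  structure(out, n_dates = n_dates, class = "vigor_summary")
}

#' @export
print.vigor_summary <- function(x, digits = 2, ...) {
  n_dates <- attr(x, "n_dates")
  fmt <- function(v, s = "") {
    if (is.na(v)) "  .   " else sprintf("%5.2f%-3s", round_half_up(v, digits), s)
  }
  for (tr in names(x)) {
    s <- x[[tr]]
    cat(sprintf("== trait: %s ==\n", tr))
    cat(sprintf("%-18s %s %7s %7s\n", "method",
                paste(sprintf("   D%d   ", seq_len(n_dates)), collapse = ""),
                "mean", "CV"))
    wide <- s$methods
    for (m in unique(wide$method)) {
      rowv <- wide[wide$method == m, ]
      mc <- s$mean_cv[s$mean_cv$method == m, ]
      cat(sprintf("%-18s %s %7s %7s\n", m,
                  paste(mapply(fmt, rowv$r2, rowv$stars), collapse = " "),
                  if (is.na(mc$mean_r2)) "." else sprintf("%.2f", round_half_up(mc$mean_r2)),
                  if (is.na(mc$cv_r2)) "." else sprintf("%.2f", round_half_up(mc$cv_r2))))
    }
    ct <- s$contour
    if (!all(is.na(ct$per_date_r2))) {
      cat(sprintf("%-18s %s %7s %7s\n", "contour_map",
                  paste(vapply(ct$per_date_r2, fmt, ""), collapse = " "),
                  if (is.na(ct$best_mean_r2)) "." else sprintf("%.2f", round_half_up(ct$best_mean_r2)),
                  if (is.na(ct$cv_at_best)) "." else sprintf("%.2f", round_half_up(ct$cv_at_best))))
      for (nm in c("ratio_sensor", "ratio_vi")) {
        rv <- s[[nm]]
        if (is.null(rv)) next
        lab <- if (nm == "ratio_sensor") "ratio/best sensor" else "ratio/best VI"
        cat(sprintf("%-18s %s %7s\n", lab,
                    paste(vapply(rv[seq_len(n_dates)], fmt, ""), collapse = " "),
                    if (is.na(rv[["mean"]])) "." else sprintf("%.2f", rv[["mean"]])))
      }
    }
    cat("\n")
  }
  invisible(x)
}

#' Rank sensor methods for one trait and date
#'
#' Descending by per-date R-squared; exact ties broken alphabetically;
#' methods with a missing cell rank last (alphabetically among
#' themselves).
#'
#' @param summary a [build_summary()] result.
#' @param trait trait label present in the summary.
#' @param date_index date index.
#' @return character vector of method names, best first.
#' @export
rank_methods <- function(summary, trait, date_index) {
  if (!trait %in% names(summary))
    stop_ev("ev_lookup_error", sprintf("unknown trait '%s'", trait))
  s <- summary[[trait]]$methods
  s <- s[s$date_index == date_index, ]
  if (!nrow(s))
    stop_ev("ev_lookup_error", sprintf("unknown date index %s", date_index))
  s <- s[order(-ifelse(is.na(s$r2), -Inf, s$r2), s$method), ]
  s$method
}

#' Write a summary to CSV
#'
#' Long format: one row per trait x method x date cell plus mean/CV rows.
#'
#' @param summary a [build_summary()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path) {
  rows <- list()
  for (tr in names(summary)) {
    s <- summary[[tr]]
    m <- s$methods
    m$trait <- tr
    m <- merge(m, s$mean_cv, by = "method")
    rows[[tr]] <- m[c("trait", "method", "date_index", "r2", "stars",
                      "mean_r2", "cv_r2")]
  }
  utils::write.csv(do.call(rbind, c(rows, make.row.names = FALSE)), path,
                   row.names = FALSE)
  invisible(path)
}
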