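# Exhaustive two-band normalized-difference index screening.
#
# For one trait and one date, every pairwise normalized difference index
# over the 400-1140 nm grid is correlated with the trait across plots,
# giving a symmetric matrix of squared Pearson correlations ("contour map").
# Matrices are aggregated element-wise across dates into mean and CV, the
# temporal-stability view of the band-pair screen.

#' Normalized difference index of two bands
#'
#' `(Refl[b1] - Refl[b2]) / (Refl[b1] + Refl[b2])` with nearest-band
#' lookup. Band pairs are conventionally reported ordered `b1 > b2`;
#' swapping the bands flips the sign and leaves any R-squared unchanged.
#'
#' @param spec a [spectrum()].
#' @param b1,b2 distinct nominal wavelengths in nm, both >= 400.
#' @return scalar index value.
#' @export
ndi <- function(spec, b1, b2) {
  if (b1 == b2) stop_ev("ev_config_error", "ndi requires two distinct bands")
  if (b1 < 400 || b2 < 400)
    stop_ev("ev_range_error", "bands below 400 nm are excluded (scattering)")
  nd(band(spec, b1), band(spec, b2), sprintf("ndi(%g, %g)", b1, b2))
}

#' Contour-map matrix for one trait and date
#'
#' Squared Pearson correlation between every band-pair normalized
#' difference index (computed across plots) and the trait values. Bands
#' below 400 nm are removed before screening. Pairs whose index is
#' constant across plots, or undefined (zero band sum) for any plot, give
#' an undefined (NA) entry; the diagonal is undefined.
#'
#' @param spectra list of >= 3 [spectrum()] objects on one grid, aligned
#'   with `trait_values`.
#' @param trait_values numeric trait value per plot.
#' @param trait,date labels stored on the result.
#' @return object of class `"contour_matrix"`: list with `bands` (nm),
#'   `r2` (symmetric matrix, NA where undefined), `trait`, `date`,
#'   `n_plots`.
#' @export
contour_matrix <- function(spectra, trait_values, trait = NA_character_,
                           date = NA_character_) {
  n <- length(spectra)
  if (n < 3 || length(trait_values) != n)
    stop_ev("ev_samplesize_error",
            "need >= 3 plots with aligned spectra and trait values")
  w <- spectra[[1]]$wavelengths
  for (s in spectra)
    if (!isTRUE(all.equal(s$wavelengths, w)))
      stop_ev("ev_alignment_error", "spectra are not on a common grid")
  keep <- w >= 400
  bands <- w[keep]
  R <- vapply(spectra, function(s) s$reflectance[keep], numeric(sum(keep)))
  nb <- length(bands)
  y <- as.numeric(trait_values)
  r2 <- matrix(NA_real_, nb, nb)
  y_ok <- stats::sd(y) > 0
  if (y_ok) {
    yc <- y - mean(y)
    ss_y <- sum(yc^2)
    for (i in seq_len(nb - 1)) {
      js <- (i + 1):nb
      num <- R[js, , drop = FALSE] - matrix(R[i, ], length(js), n, byrow = TRUE)
      den <- R[js, , drop = FALSE] + matrix(R[i, ], length(js), n, byrow = TRUE)
      X <- num / den                       # rows: j, cols: plots
      X[!is.finite(X)] <- NA
      ok <- rowSums(is.na(X)) == 0
      xm <- rowMeans(X)
      xc <- X - xm
      ss_x <- rowSums(xc^2)
      r <- as.vector(xc %*% yc) / sqrt(ss_x * ss_y)
      val <- r^2
      val[!ok | ss_x <= 0] <- NA_real_
      r2[i, js] <- val
      r2[js, i] <- val
    }
  }
  structure(list(bands = bands, r2 = r2, trait = trait, date = date,
                 n_plots = n),
            class = "contour_matrix")
}

#' @export
print.contour_matrix <- function(x, ...) {
  best <- best_pair_of(x$r2, x$bands)
  cat(sprintf("<contour_matrix> trait %s, date %s: %d bands, n = %d",
              x$trait, x$date, length(x$bands), x$n_plots))
  if (!is.null(best))
    cat(sprintf(", max R2 %.3f at (%g; %g) nm", best$value, best$b1, best$b2))
  cat("\n")
  invisible(x)
}

# argmax over defined entries; ties toward the closest band pair, then the
# lower second wavelength; reported ordered b1 > b2
best_pair_of <- function(m, bands) {
  if (all(is.na(m))) return(NULL)
  mx <- max(m, na.rm = TRUE)
  idx <- which(!is.na(m) & m == mx, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]   # upper triangle only
  b1 <- bands[idx[, 2]]; b2 <- bands[idx[, 1]]      # b1 > b2
  ord <- order(abs(b1 - b2), b2)
  list(b1 = b1[ord[1]], b2 = b2[ord[1]], value = mx)
}

#' Aggregate contour maps across dates
#'
#' Element-wise mean and coefficient of variation (sample SD / mean) of the
#' per-date R-squared matrices. Undefined entries are excluded
#' pairwise-complete, never imputed as zero. The best pair maximizes the
#' mean matrix (ties toward the closest bands, then the lower second
#' wavelength); `cv_at_best` is the CV of that same pair, not the minimum
#' CV.
#'
#' @param matrices list of >= 2 [contour_matrix()] objects on one grid
#'   (one per date).
#' @return object of class `"contour_aggregate"`: list with `bands`,
#'   `mean_r2`, `cv_r2`, `best_pair` (c(b1, b2), b1 > b2), `best_mean_r2`,
#'   `cv_at_best`, `per_date` (data.frame `date, max_r2, band1_nm,
#'   band2_nm` of per-date maxima), `trait`, `n_dates`.
#' @export
aggregate_contour <- function(matrices) {
  if (length(matrices) < 2)
    stop_ev("ev_samplesize_error", "need >= 2 dates to aggregate")
  bands <- matrices[[1]]$bands
  for (m in matrices)
    if (!isTRUE(all.equal(m$bands, bands)))
      stop_ev("ev_alignment_error", "contour matrices use different band grids")
  arr <- vapply(matrices, function(m) m$r2,
                matrix(0, length(bands), length(bands)))
  n_def <- apply(!is.na(arr), c(1, 2), sum)
  mean_r2 <- apply(arr, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  cv_r2 <- apply(arr, c(1, 2), function(v) cv_sample(v[!is.na(v)]))
  best <- best_pair_of(mean_r2, bands)
  per_date <- do.call(rbind, lapply(matrices, function(m) {
    b <- best_pair_of(m$r2, m$bands)
    data.frame(date = m$date,
               max_r2 = if (is.null(b)) NA_real_ else b$value,
               band1_nm = if (is.null(b)) NA_real_ else b$b1,
               band2_nm = if (is.null(b)) NA_real_ else b$b2,
               stringsAsFactors = FALSE)
  }))
  cv_best <- if (is.null(best)) NA_real_ else {
    i <- match(best$b2, bands); j <- match(best$b1, bands)
    cv_r2[i, j]
  }
  structure(list(bands = bands, mean_r2 = mean_r2, cv_r2 = cv_r2,
                 n_defined = n_def,
                 best_pair = if (is.null(best)) c(NA_real_, NA_real_)
                             else c(best$b1, best$b2),
                 best_mean_r2 = if (is.null(best)) NA_real_ else best$value,
                 cv_at_best = cv_best,
                 per_date = per_date,
                 trait = matrices[[1]]$trait, n_dates = length(matrices)),
            class = "contour_aggregate")
}

#' @export
print.contour_aggregate <- function(x, ...) {
  cat(sprintf(
    "<contour_aggregate> trait %s over %d dates: best mean R2 %.3f at (%g; %g) nm, CV %.3f\n",
    x$trait, x$n_dates, x$best_mean_r2, x$best_pair[1], x$best_pair[2],
    x$cv_at_best))
  invisible(x)
}

#' Classify a band pair into spectral groups
#'
#' Unordered group label from the three spectral regions: VIS 400-680 nm,
#' red edge 680-740 nm, NIR 740-1140 nm. The boundary values belong to the
#' lower-named region (680 is VIS, 740 is red edge).
#'
#' @param b1,b2 wavelengths in nm, both in [400, 1140].
#' @return one of `"VIS/VIS"`, `"VIS/red edge"`, `"VIS/NIR"`,
#'   `"red edge/red edge"`, `"red edge/NIR"`, `"NIR/NIR"`.
#' @export
classify_band_pair <- function(b1, b2) {
  region <- function(b) {
    if (b < 400 || b > 1140)
      stop_ev("ev_range_error", "band outside [400, 1140] nm")
    if (b <= 680) 1L else if (b <= 740) 2L else 3L
  }
  labels <- c("VIS", "red edge", "NIR")
  r <- sort(c(region(b1), region(b2)))
  paste(labels[r[1]], labels[r[2]], sep = "/")
}

#' Pairwise comparison of mean R-squared between two traits
#'
#' One row per band pair with the aggregate mean R-squared under each
#' trait and the spectral group label, the machine form of a
#' trait-versus-trait scatter of the contour-map screen.
#'
#' @param agg_a,agg_b [aggregate_contour()] results on identical grids.
#' @return data.frame `band1_nm, band2_nm (band1 > band2), mean_r2_a,
#'   mean_r2_b, group`.
#' @export
cross_trait_compare <- function(agg_a, agg_b) {
  if (!isTRUE(all.equal(agg_a$bands, agg_b$bands)))
    stop_ev("ev_alignment_error", "aggregates use different band grids")
  bands <- agg_a$bands
  ut <- which(upper.tri(agg_a$mean_r2), arr.ind = TRUE)
  b2 <- bands[ut[, 1]]; b1 <- bands[ut[, 2]]     # b1 > b2
  group <- mapply(classify_band_pair, b1, b2)
  data.frame(band1_nm = b1, band2_nm = b2,
             mean_r2_a = agg_a$mean_r2[ut], mean_r2_b = agg_b$mean_r2[ut],
             group = group, stringsAsFactors = FALSE)
}

#' Export contour-map matrices in long format
#'
#' @param x a [contour_matrix()] or [aggregate_contour()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(x, path) {
  bands <- x$bands
  ut <- which(upper.tri(diag(length(bands))), arr.ind = TRUE)
  b2 <- bands[ut[, 1]]; b1 <- bands[ut[, 2]]
  df <- if (inherits(x, "contour_matrix")) {
    data.frame(trait = x$trait, date = x$date, band1_nm = b1, band2_nm = b2,
               r2 = x$r2[ut])
  } else {
    data.frame(trait = x$trait, date = "aggregate", band1_nm = b1,
               band2_nm = b2, r2 = x$mean_r2[ut], cv_r2 = x$cv_r2[ut])
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
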