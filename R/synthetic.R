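# Synthetic four-date trial generator: trait tables, linearly mixed
# spectra and rendered quadrat images with known ground-truth cover.
#
# The generator emulates the statistical structure the downstream analysis
# assumes -- exponential dry-weight growth, near-constant-then-declining N
# content with a late DW-NC trade-off, sigmoidal canopy-cover development,
# linear soil/vegetation spectral mixing with heteroscedastic noise that is
# strongest above 1000 nm on the earliest date -- so every stage of the
# pipeline can be tested end to end without field data.

#' Trial design
#'
#' Split factorial layout of a small field trial: one block varying the
#' first nitrogen dressing over cultivars, one block varying sowing density
#' over two cultivars, three replicates each. Defaults give 36 plots per
#' sampling date over four dates spanning seedling growth to early stem
#' elongation (Zadok's stages 12-32).
#'
#' @param seed integer RNG seed driving every random draw of the trial.
#' @param dates growth-stage labels, one per sampling date.
#' @param n_levels first N dressing rates (kg N/ha) in the fertilization block.
#' @param densities sowing densities (kernels/m^2) in the density block.
#' @param cultivars cultivar labels; the density block uses the first and last.
#' @param replicates replicates per treatment combination.
#' @return object of class `"trial_design"`: list with `plots` (data.frame
#'   `plot_id, block, cultivar, density, n_level`), `dates`, `n_dates`,
#'   `n_plots`, `seed`.
#' @export
trial_design <- function(seed = 1,
                         dates = c("Z12-13", "Z21", "Z24", "Z32"),
                         n_levels = c(30, 60),
                         densities = c(150, 250, 350),
                         cultivars = c("Anapolis", "Mulan", "Hybery"),
                         replicates = 3) {
  block_n <- expand.grid(n_level = n_levels, cultivar = cultivars,
                         rep = seq_len(replicates), stringsAsFactors = FALSE)
  block_n$density <- 250
  block_n$block <- "nitrogen"
  cult_d <- unique(cultivars[c(1, length(cultivars))])
  block_d <- expand.grid(density = densities, cultivar = cult_d,
                         rep = seq_len(replicates), stringsAsFactors = FALSE)
  block_d$n_level <- n_levels[1]
  block_d$block <- "density"
  cols <- c("block", "cultivar", "density", "n_level")
  plots <- rbind(block_n[cols], block_d[cols])
  plots$plot_id <- sprintf("p%02d", seq_len(nrow(plots)))
  structure(list(plots = plots[c("plot_id", cols)], dates = dates,
                 n_dates = length(dates), n_plots = nrow(plots), seed = seed),
            class = "trial_design")
}

#' Growth model for the synthetic trial
#'
#' Date-level trait means and plot-level dispersion. Dry weight grows
#' roughly exponentially across dates; N content stays near 5% before
#' declining at the last date; canopy cover follows a sigmoid from sparse
#' seedlings (~4.5%) to near closure (~84%). Plot effects are log-normal
#' for DW (positivity) and Gaussian for NC, truncated to 2-7%. From the
#' trade-off dates on, a negative correlation between NC and DW (dilution
#' of N in fast-growing biomass) is imposed. Canopy cover is a logistic
#' function of log(DW), so cover saturates while DW keeps growing.
#'
#' @param dw_means dry weight means per date (kg/ha), strictly increasing.
#' @param nc_means N content means per date (%).
#' @param cc_means canopy cover means per date, in (0,1), non-decreasing
#'   and sigmoidal (second difference changes sign at most once).
#' @param plot_cv relative dispersion of plot effects on DW.
#' @param nc_sd plot-level SD of N content (percentage points).
#' @param nc_dw_tradeoff correlation imposed between NC and log DW on
#'   `tradeoff_dates` (negative for a dilution trade-off).
#' @param tradeoff_dates date indices where the trade-off applies.
#' @param density_response exponent of the multiplicative sowing-density
#'   effect on DW, `(density/250)^density_response`.
#' @param cc_slope slope of the logistic cover--log(DW) link per unit
#'   log DW.
#' @return object of class `"growth_model"` (a list of the above).
#' @export
growth_model <- function(dw_means = c(73, 213, 621, 1812),
                         nc_means = c(5.0, 5.0, 5.0, 4.6),
                         cc_means = c(0.045, 0.18, 0.45, 0.84),
                         plot_cv = 0.30, nc_sd = 0.35,
                         nc_dw_tradeoff = -0.6, tradeoff_dates = c(3, 4),
                         density_response = 0.5, cc_slope = 1.0) {
  if (any(diff(dw_means) <= 0))
    stop_ev("ev_config_error", "dw_means must be strictly increasing")
  if (any(cc_means <= 0 | cc_means >= 1) || any(diff(cc_means) < 0))
    stop_ev("ev_config_error", "cc_means must be non-decreasing within (0, 1)")
  if (length(cc_means) >= 3) {
    d2 <- diff(diff(cc_means))
    d2 <- d2[d2 != 0]
    if (length(d2) > 1 && sum(diff(sign(d2)) != 0) > 1)
      stop_ev("ev_config_error", "cc_means is not sigmoidal")
  }
  if (!all(lengths(list(nc_means, cc_means)) == length(dw_means)))
    stop_ev("ev_config_error", "trait means must share one length")
  if (plot_cv < 0 || nc_sd < 0)
    stop_ev("ev_config_error", "dispersion parameters must be >= 0")
  structure(list(dw_means = dw_means, nc_means = nc_means, cc_means = cc_means,
                 plot_cv = plot_cv, nc_sd = nc_sd,
                 nc_dw_tradeoff = nc_dw_tradeoff,
                 tradeoff_dates = tradeoff_dates,
                 density_response = density_response, cc_slope = cc_slope),
            class = "growth_model")
}

#' Simulate one mixed canopy spectrum
#'
#' Linear two-endmember mixture `cover * vegetation + (1 - cover) * soil`
#' plus zero-mean Gaussian noise, clipped to [0, 1]. Bands above 1000 nm
#' receive `noise_sd * nir_noise_boost`, emulating the stronger scattering
#' observed there over sparse, rough-soiled canopies.
#'
#' @param cover vegetation cover fraction in [0, 1].
#' @param endmembers an [endmember_library()].
#' @param noise_sd reflectance noise SD (default 0.005).
#' @param nir_noise_boost multiplier on `noise_sd` above 1000 nm (default 1).
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param plot_id,date labels attached to the spectrum.
#' @return a [spectrum()].
#' @export
generate_spectrum <- function(cover, endmembers, noise_sd = 0.005,
                              nir_noise_boost = 1, seed = NULL,
                              plot_id = NA_character_, date = NA_character_) {
  if (!is.finite(cover) || cover < 0 || cover > 1)
    stop_ev("ev_domain_error", "cover must lie in [0, 1]")
  if (noise_sd < 0)
    stop_ev("ev_domain_error", "noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  w <- endmembers$wavelengths
  mix <- cover * endmembers$vegetation + (1 - cover) * endmembers$soil
  if (noise_sd > 0) {
    sdv <- noise_sd * ifelse(w > 1000, nir_noise_boost, 1)
    mix <- mix + stats::rnorm(length(w), 0, sdv)
  }
  spectrum(w, pmin(pmax(mix, 0), 1), plot_id = plot_id, date = date)
}

#' Render a synthetic quadrat image with known green fraction
#'
#' Paints elongated elliptical green blades (hue jittered within the plant
#' HSV window, brightness varying per blade and per pixel) over a textured
#' brown soil background. Blades are added until the requested cover is
#' reached; the last blade is trimmed pixel-wise, so the returned
#' `true_cover` equals the exact rendered green-pixel fraction and differs
#' from `target_cover` by less than one pixel in the raster.
#'
#' @param target_cover requested green fraction in [0, 1].
#' @param width,height image size in pixels, both >= 64.
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return list with `image` (height x width x 3 array, 0..255) and
#'   `true_cover` (exact green-pixel fraction).
#' @export
render_canopy_image <- function(target_cover, width = 600, height = 600,
                                seed = NULL) {
  if (!is.finite(target_cover) || target_cover < 0 || target_cover > 1)
    stop_ev("ev_domain_error", "target_cover must lie in [0, 1]")
  if (width < 64 || height < 64)
    stop_ev("ev_size_error", "image must be at least 64 x 64 pixels")
  if (!is.null(seed)) set.seed(seed)
  n <- width * height
  target_px <- round(target_cover * n)
  shape_id <- matrix(0L, height, width)
  painted <- 0L
  n_shapes <- 0L
  iter <- 0L
  while (painted < target_px && iter < 50000L) {
    iter <- iter + 1L
    remaining <- target_px - painted
    area <- stats::runif(1, 0.5, 1) * min(max(remaining, 40), 0.02 * n)
    aspect <- stats::runif(1, 2.5, 7)
    a <- sqrt(area * aspect / pi); b <- a / aspect
    theta <- stats::runif(1, 0, pi)
    cx <- stats::runif(1, 1, width); cy <- stats::runif(1, 1, height)
    x0 <- max(1L, floor(cx - a)); x1 <- min(width, ceiling(cx + a))
    y0 <- max(1L, floor(cy - a)); y1 <- min(height, ceiling(cy + a))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    dx <- outer(rep(1, length(ys)), xs - cx)
    dy <- outer(ys - cy, rep(1, length(xs)))
    u <- (dx * cos(theta) + dy * sin(theta)) / a
    v <- (-dx * sin(theta) + dy * cos(theta)) / b
    inside <- u * u + v * v <= 1
    sub <- shape_id[ys, xs, drop = FALSE]
    new_px <- which(inside & sub == 0L)
    if (!length(new_px)) next
    if (length(new_px) > remaining)
      new_px <- sample(new_px, remaining)
    n_shapes <- n_shapes + 1L
    sub[new_px] <- n_shapes
    shape_id[ys, xs] <- sub
    painted <- painted + length(new_px)
  }
  true_cover <- painted / n
  img <- paint_canopy(shape_id, n_shapes)
  list(image = img, true_cover = true_cover)
}

# color a shape-id raster: brown textured soil, per-blade green tones
paint_canopy <- function(shape_id, n_shapes) {
  h <- nrow(shape_id); w <- ncol(shape_id); n <- h * w
  base_soil <- c(125, 92, 58)
  bright <- pmin(pmax(stats::rnorm(n, 1, 0.12), 0.7), 1.3)
  img <- array(0, dim = c(h, w, 3))
  for (k in 1:3)
    img[, , k] <- base_soil[k] * bright + stats::rnorm(n, 0, 4)
  green_px <- which(shape_id > 0L)
  if (length(green_px)) {
    hh <- stats::runif(n_shapes, 95, 150)
    ss <- stats::runif(n_shapes, 0.45, 0.85)
    vv <- stats::runif(n_shapes, 0.35, 0.85)
    base_rgb <- grDevices::col2rgb(grDevices::hsv(hh / 360, ss, vv))
    jit <- stats::runif(length(green_px), 0.85, 1.15)
    ids <- shape_id[green_px]
    for (k in 1:3) {
      ch <- img[, , k]
      ch[green_px] <- base_rgb[k, ids] * jit + stats::rnorm(length(green_px), 0, 3)
      img[, , k] <- ch
    }
  }
  round(pmin(pmax(img, 0), 255))
}

#' Generate a full synthetic trial
#'
#' Draws plot-level traits per date from the growth model, renders one
#' quadrat image per plot (optional), and simulates the mixed canopy
#' spectrum from the image's exact green fraction. N uptake is always
#' computed as `DW * NC / 100`, never drawn independently, and the
#' recorded `cc_true` is the exact green-pixel fraction of the rendered
#' image (or the model cover value when rendering is off).
#'
#' @param design a [trial_design()].
#' @param growth a [growth_model()].
#' @param endmembers an [endmember_library()]; its grid must span
#'   `spectral_range`.
#' @param noise_sd spectral noise SD (reflectance units).
#' @param nir_noise_boost noise multiplier above 1000 nm applied on the
#'   first date only (soil scattering over sparse canopies).
#' @param render_images render quadrat images (default TRUE); when FALSE,
#'   `cc_true` is the model cover value and `images` is NULL.
#' @param image_size rendered image side length in pixels.
#' @param spectral_range wavelength range (nm) the endmember grid must span.
#' @return object of class `"vigor_trial"`: list with `traits` (data.frame
#'   `plot_id, date, date_index, block, cultivar, density, n_level,
#'   dw_kg_ha, nc_pct, nup_kg_ha, cc_true`), `spectra` (named list of
#'   [spectrum()]), `images` (named list or NULL), plus the inputs.
#' @export
generate_trial <- function(design = trial_design(), growth = growth_model(),
                           endmembers = endmember_library(),
                           noise_sd = 0.005, nir_noise_boost = 4,
                           render_images = TRUE, image_size = 600,
                           spectral_range = c(300, 1140)) {
  w <- endmembers$wavelengths
  step <- mean(diff(w))
  # the nominal range need only be covered to within one grid step
  if (w[1] > spectral_range[1] + step || w[length(w)] < spectral_range[2] - step)
    stop_ev("ev_config_error",
            "endmember grid does not span the requested spectral range")
  if (length(growth$dw_means) != design$n_dates)
    stop_ev("ev_config_error", "growth means must be supplied for every date")
  set.seed(design$seed)
  plots <- design$plots
  np <- design$n_plots
  sdlog <- sqrt(log(1 + growth$plot_cv^2))
  traits <- list(); spectra <- list(); images <- if (render_images) list() else NULL
  for (d in seq_len(design$n_dates)) {
    mult <- (plots$density / 250)^growth$density_response
    z <- stats::rnorm(np)
    dw <- growth$dw_means[d] * mult * exp(sdlog * z - sdlog^2 / 2)
    ldw <- log(dw)
    z_dw <- if (stats::sd(ldw) > 0) as.numeric(scale(ldw)) else rep(0, np)
    rho <- if (d %in% growth$tradeoff_dates) growth$nc_dw_tradeoff else 0
    e <- stats::rnorm(np)
    nc <- growth$nc_means[d] +
      growth$nc_sd * (rho * z_dw + sqrt(1 - rho^2) * e)
    nc <- pmin(pmax(nc, 2), 7)
    cc_model <- stats::plogis(stats::qlogis(growth$cc_means[d]) +
                                growth$cc_slope * (ldw - mean(ldw)))
    boost <- if (d == 1) nir_noise_boost else 1
    for (i in seq_len(np)) {
      key <- sprintf("d%d_%s", d, plots$plot_id[i])
      if (render_images) {
        rc <- render_canopy_image(cc_model[i], image_size, image_size)
        images[[key]] <- rc$image
        cc_true <- rc$true_cover
      } else {
        cc_true <- cc_model[i]
      }
      spectra[[key]] <- generate_spectrum(cc_true, endmembers, noise_sd,
                                          boost, plot_id = plots$plot_id[i],
                                          date = design$dates[d])
      traits[[key]] <- data.frame(
        plot_id = plots$plot_id[i], date = design$dates[d], date_index = d,
        block = plots$block[i], cultivar = plots$cultivar[i],
        density = plots$density[i], n_level = plots$n_level[i],
        dw_kg_ha = dw[i], nc_pct = nc[i], nup_kg_ha = dw[i] * nc[i] / 100,
        cc_true = cc_true, stringsAsFactors = FALSE)
    }
  }
  structure(list(traits = do.call(rbind, c(traits, make.row.names = FALSE)),
                 spectra = spectra, images = images, design = design,
                 growth = growth, endmembers = endmembers,
                 noise_sd = noise_sd, nir_noise_boost = nir_noise_boost),
            class = "vigor_trial")
}

#' @export
print.vigor_trial <- function(x, ...) {
  cat(sprintf("<vigor_trial> %d dates x %d plots (%d records)%s\n",
              x$design$n_dates, x$design$n_plots, nrow(x$traits),
              if (is.null(x$images)) ", no images" else ""))
  agg <- stats::aggregate(cbind(dw_kg_ha, nc_pct, nup_kg_ha, cc_true) ~ date_index,
                          data = x$traits, FUN = mean)
  print(format(agg, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Write a synthetic trial to disk
#'
#' Writes `traits.csv` (`plot_id, date, cultivar, density, n_level,
#' dw_kg_ha, nc_pct, nup_kg_ha, cc_true`), one wide spectra CSV per date,
#' the endmember library, and (when present) one PNG per plot under
#' `images/`.
#'
#' @param trial a [generate_trial()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cols <- c("plot_id", "date", "cultivar", "density", "n_level",
            "dw_kg_ha", "nc_pct", "nup_kg_ha", "cc_true")
  utils::write.csv(trial$traits[cols], file.path(dir, "traits.csv"),
                   row.names = FALSE)
  write_endmembers_csv(trial$endmembers, file.path(dir, "endmembers.csv"))
  for (d in seq_len(trial$design$n_dates)) {
    keys <- sprintf("d%d_%s", d, trial$design$plots$plot_id)
    write_spectra_csv(trial$spectra[keys],
                      file.path(dir, sprintf("spectra_date%d.csv", d)))
  }
  if (!is.null(trial$images)) {
    img_dir <- file.path(dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (key in names(trial$images))
      write_rgb_image(trial$images[[key]], file.path(img_dir, paste0(key, ".png")))
  }
  invisible(dir)
}
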