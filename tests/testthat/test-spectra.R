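# Spectral data model, nearest-band lookup and vegetation indices.

test_that("nearest-band lookup picks the closest grid band, ties toward lower", {
  s <- spectrum(c(668.0, 671.3), c(0.1, 0.2))
  expect_equal(band(s, 670), 0.2)             # 1.3 nm beats 2.0 nm
  expect_equal(band(s, 668.0), 0.1)           # exact grid wavelength
  s2 <- spectrum(c(700, 706), c(0.3, 0.4))
  expect_equal(band(s2, 703), 0.3)            # exact tie -> lower wavelength
  expect_error(band(s, 900), class = "ev_range_error")
  expect_error(band(s, 300), class = "ev_range_error")
})

test_that("spectrum constructor validates its invariants", {
  expect_error(spectrum(c(500, 400), c(0.1, 0.2)), class = "ev_config_error")
  expect_error(spectrum(c(400, 500), c(0.1)), class = "ev_config_error")
  expect_error(spectrum(c(400, 500), c(0.1, NaN)), class = "ev_config_error")
  expect_error(spectrum(c(400, 500), c(-0.1, 0.2)), class = "ev_config_error")
  expect_true(spectrum(c(400, 500), c(1.2, 0.2))$overshoot)  # calibration overshoot flagged
})

test_that("index formulas reproduce hand-computed examples", {
  g <- spectral_grid()
  # NDVI from two-level step spectrum: R864 = 0.5, R671 = 0.05
  step <- spectrum(g, ifelse(g < 700, 0.05, 0.5))
  expect_equal(compute_index(step, vi_definitions("NDVI")[[1]]),
               (0.5 - 0.05) / (0.5 + 0.05), tolerance = 1e-12)
  # REIP with fixed four-band values
  r <- rep(0.1, length(g))
  r[band_index(g, 668)] <- 0.05; r[band_index(g, 778)] <- 0.45
  r[band_index(g, 698)] <- 0.08; r[band_index(g, 738)] <- 0.35
  reip <- compute_index(spectrum(g, r), vi_definitions("REIP")[[1]])
  expect_equal(reip, 700 + 40 * ((0.25 - 0.08) / (0.35 - 0.08)), tolerance = 1e-12)
  expect_equal(reip, 725.185185185, tolerance = 1e-8)
})

test_that("flat spectra are fixed points: ND indices 0, WBI 1", {
  flat <- flat_spectrum(0.3)
  for (nm in c("NDVI", "NDRE", "PRI"))
    expect_equal(compute_index(flat, vi_definitions(nm)[[1]]), 0)
  expect_equal(compute_index(flat, vi_definitions("WBI")[[1]]), 1)
  expect_equal(greenseeker_ndvi(flat), 0)
})

test_that("zero denominators raise a classed undefined-value error with the index name", {
  g <- spectral_grid()
  r <- rep(0.2, length(g))
  r[band_index(g, 738)] <- 0.08; r[band_index(g, 698)] <- 0.08
  expect_error(compute_index(spectrum(g, r), vi_definitions("REIP")[[1]]),
               class = "ev_undefined_value")
  e <- tryCatch(compute_index(spectrum(g, r), vi_definitions("REIP")[[1]]),
                ev_undefined_value = identity)
  expect_equal(e$index, "REIP")
  expect_equal(e$reason, "zero_denominator")
  r2 <- rep(0.2, length(g))
  r2[band_index(g, 710)] <- 0.15; r2[band_index(g, 680)] <- 0.15
  expect_error(compute_index(spectrum(g, r2), vi_definitions("MTCI")[[1]]),
               class = "ev_undefined_value")
})

test_that("normalized-difference indices stay in [-1, 1] for nonnegative reflectance", {
  set.seed(11)
  g <- spectral_grid()
  for (i in 1:20) {
    s <- spectrum(g, runif(length(g), 0, 1))
    for (nm in c("NDVI", "NDRE", "PRI")) {
      v <- compute_index(s, vi_definitions(nm)[[1]])
      expect_gte(v, -1); expect_lte(v, 1)
    }
  }
})

test_that("REIP lies in [700, 740] when the midpoint is bracketed", {
  set.seed(12)
  g <- spectral_grid()
  for (i in 1:50) {
    r <- runif(length(g), 0.05, 0.6)
    R698 <- r[band_index(g, 698)]; R738 <- r[band_index(g, 738)]
    mid <- (r[band_index(g, 668)] + r[band_index(g, 778)]) / 2
    if (R738 > R698 && mid >= R698 && mid <= R738) {
      v <- compute_index(spectrum(g, r), vi_definitions("REIP")[[1]])
      expect_gte(v, 700); expect_lte(v, 740)
    }
  }
})

test_that("the emulated two-band sensor reduces to two-value NDVI on a step spectrum", {
  g <- spectral_grid()
  step <- spectrum(g, ifelse(g < 700, 0.05, 0.5))
  expect_equal(greenseeker_ndvi(step), (0.5 - 0.05) / (0.5 + 0.05),
               tolerance = 1e-12)
  # on the vegetation endmember the boxcar sensor tracks narrow-band NDVI
  lib <- endmember_library()
  veg <- spectrum(lib$wavelengths, lib$vegetation)
  expect_lt(abs(greenseeker_ndvi(veg) -
                  compute_index(veg, vi_definitions("NDVI")[[1]])), 0.02)
  expect_error(greenseeker_ndvi(flat_spectrum(0.2, seq(400, 500, 10))),
               class = "ev_range_error")
})

test_that("index_table is dense, with reasons for undefined cells", {
  g <- spectral_grid()
  s1 <- spectrum(g, seq(0.1, 0.5, length.out = length(g)),
                 plot_id = "p1", date = "D1")
  r <- rep(0.2, length(g))
  r[band_index(g, 738)] <- 0.08; r[band_index(g, 698)] <- 0.08
  s2 <- spectrum(g, r, plot_id = "p2", date = "D1")
  tab <- index_table(list(s1, s2))
  expect_equal(nrow(tab), 18)                     # 2 spectra x 9 indices
  bad <- tab[tab$plot_id == "p2" & tab$method == "REIP", ]
  expect_true(is.na(bad$value))
  expect_equal(bad$missing_reason, "zero_denominator")
  expect_true(all(!is.na(tab$value[tab$plot_id == "p1"])))
})

test_that("NDVI increases monotonically along a noiseless mixture series", {
  lib <- endmember_library()
  covers <- c(0, 0.25, 0.5, 0.75, 1)
  ndvi <- vapply(covers, function(cv)
    compute_index(generate_spectrum(cv, lib, noise_sd = 0),
                  vi_definitions("NDVI")[[1]]), numeric(1))
  expect_true(all(diff(ndvi) > 0))
})

test_that("spectra CSV round-trips", {
  g <- seq(400, 700, by = 10)
  sp <- list(spectrum(g, runif(length(g)), plot_id = "p01"),
             spectrum(g, runif(length(g)), plot_id = "p02"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(sp, f)
  back <- read_spectra_csv(f, date = "D1")
  expect_equal(names(back), c("p01", "p02"))
  expect_equal(back$p02$reflectance, sp[[2]]$reflectance, tolerance = 1e-9)
  expect_equal(back$p01$date, "D1")
})
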