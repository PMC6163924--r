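# Synthetic trial generator: mixing, traits, determinism, rendering.

test_that("pure endmembers and noiseless midpoints mix exactly", {
  lib <- toy_library()
  expect_equal(generate_spectrum(1, lib, noise_sd = 0)$reflectance,
               lib$vegetation, tolerance = 1e-12)
  expect_equal(generate_spectrum(0, lib, noise_sd = 0)$reflectance,
               lib$soil, tolerance = 1e-12)
  expect_equal(generate_spectrum(0.5, lib, noise_sd = 0)$reflectance,
               (lib$soil + lib$vegetation) / 2, tolerance = 1e-12)
  expect_error(generate_spectrum(1.2, lib), class = "ev_domain_error")
  expect_error(generate_spectrum(-0.1, lib), class = "ev_domain_error")
})

test_that("noise above 1000 nm is boosted on request", {
  lib <- endmember_library()
  set.seed(31)
  reps <- replicate(200, {
    s <- generate_spectrum(0.5, lib, noise_sd = 0.005, nir_noise_boost = 4)
    mix <- 0.5 * (lib$soil + lib$vegetation)
    resid <- s$reflectance - mix
    c(lo = sd(resid[lib$wavelengths <= 1000]),
      hi = sd(resid[lib$wavelengths > 1000]))
  })
  ratio <- mean(reps["hi", ]) / mean(reps["lo", ])
  expect_gt(ratio, 3); expect_lt(ratio, 5)
})

test_that("unmixing recovers the cover used to generate a noisy spectrum", {
  lib <- endmember_library()
  est <- vapply(1:50, function(i)
    fit_unmixing(generate_spectrum(0.3, lib, 0.005, seed = i), lib)$cover_estimate,
    numeric(1))
  expect_lt(max(abs(est - 0.3)), 0.02)
})

test_that("trait tables are reproducible and conserve N uptake", {
  d <- trial_design(seed = 4)
  a <- generate_trial(d, render_images = FALSE)
  b <- generate_trial(d, render_images = FALSE)
  expect_identical(a$traits, b$traits)          # bit-identical given one seed
  expect_identical(a$spectra[[10]]$reflectance, b$spectra[[10]]$reflectance)
  expect_equal(a$traits$nup_kg_ha,
               a$traits$dw_kg_ha * a$traits$nc_pct / 100, tolerance = 0)
})

test_that("zero dispersion yields identical plots within a date", {
  g0 <- growth_model(plot_cv = 0, nc_sd = 0, density_response = 0)
  tr <- generate_trial(trial_design(seed = 2), g0, render_images = FALSE)
  for (d in 1:4) {
    s <- tr$traits[tr$traits$date_index == d, ]
    expect_equal(length(unique(s$dw_kg_ha)), 1)
    expect_equal(length(unique(s$nc_pct)), 1)
    expect_equal(length(unique(s$cc_true)), 1)
  }
})

test_that("per-date trait means track the growth model at default n", {
  gm <- growth_model()
  trials <- lapply(c(1, 2, 3), function(s)
    generate_trial(trial_design(seed = s), render_images = FALSE))
  # averaged over a few seeds, every per-date mean sits within 10% of the
  # growth model; 36 plots per date leave ~5% Monte-Carlo error per seed
  for (d in 1:4) {
    m <- rowMeans(vapply(trials, function(tr) {
      s <- tr$traits[tr$traits$date_index == d, ]
      c(dw = mean(s$dw_kg_ha), nc = mean(s$nc_pct), cc = mean(s$cc_true))
    }, numeric(3)))
    expect_lt(abs(m[["dw"]] / gm$dw_means[d] - 1), 0.10)
    expect_lt(abs(m[["nc"]] / gm$nc_means[d] - 1), 0.10)
    expect_lt(abs(m[["cc"]] / gm$cc_means[d] - 1), 0.10)
  }
  # seedling stage sparse, early stem elongation near closure (seed 1)
  tr1 <- trials[[1]]
  expect_lt(abs(mean(tr1$traits$cc_true[tr1$traits$date_index == 1]) - 0.045),
            0.0045)
  expect_lt(abs(mean(tr1$traits$cc_true[tr1$traits$date_index == 4]) - 0.84),
            0.084)
  expect_equal(nrow(tr1$traits), 144)
})

test_that("cover tracks dry weight within every date", {
  tr <- generate_trial(trial_design(seed = 3), render_images = FALSE)
  for (d in 1:4) {
    s <- tr$traits[tr$traits$date_index == d, ]
    expect_gte(cor(s$dw_kg_ha, s$cc_true, method = "spearman"), 0.8)
  }
})

test_that("the NC-DW trade-off materializes only on the trade-off dates", {
  tr <- generate_trial(trial_design(seed = 5), render_images = FALSE)
  for (d in 3:4) {
    s <- tr$traits[tr$traits$date_index == d, ]
    expect_lt(cor(s$nc_pct, log(s$dw_kg_ha)), -0.3)
  }
  no_tr <- generate_trial(trial_design(seed = 5),
                          growth_model(nc_dw_tradeoff = 0),
                          render_images = FALSE)
  for (d in 3:4) {
    s <- no_tr$traits[no_tr$traits$date_index == d, ]
    expect_lt(abs(cor(s$nc_pct, log(s$dw_kg_ha))), 0.45)
  }
})

test_that("growth model rejects non-monotone or non-sigmoidal means", {
  expect_error(growth_model(dw_means = c(73, 60, 621, 1812)),
               class = "ev_config_error")
  expect_error(growth_model(cc_means = c(0.045, 0.5, 0.3, 0.84)),
               class = "ev_config_error")
  expect_error(growth_model(cc_means = c(0.045, 0.18, 0.45, 1.1)),
               class = "ev_config_error")
  expect_error(generate_trial(trial_design(), growth_model(),
                              endmember_library(seq(500, 900, 10))),
               class = "ev_config_error")  # grid does not span the range
})

test_that("rendered images honor target cover with exact ground truth", {
  rc <- render_canopy_image(0, 100, 100, seed = 1)
  expect_equal(rc$true_cover, 0)
  expect_equal(dim(rc$image), c(100, 100, 3))
  rc4 <- render_canopy_image(0.40, 200, 200, seed = 7)
  expect_gte(rc4$true_cover, 0.38); expect_lte(rc4$true_cover, 0.42)
  # blade trimming makes the rendered fraction hit the target exactly
  expect_equal(rc4$true_cover, 0.40)
  expect_equal(segment_green(rc4$image)$canopy_cover, rc4$true_cover,
               tolerance = 0.01)
  expect_error(render_canopy_image(0.5, 32, 200), class = "ev_size_error")
  expect_error(render_canopy_image(1.5, 100, 100), class = "ev_domain_error")
})

test_that("a trial round-trips through its on-disk CSV form", {
  tr <- generate_trial(trial_design(seed = 8), render_images = TRUE,
                       image_size = 64)
  dir <- withr::local_tempdir()
  write_trial(tr, dir)
  traits <- read.csv(file.path(dir, "traits.csv"))
  expect_equal(nrow(traits), 144)
  sp <- read_spectra_csv(file.path(dir, "spectra_date2.csv"))
  expect_length(sp, 36)
  expect_equal(sp$p05$reflectance, tr$spectra[["d2_p05"]]$reflectance,
               tolerance = 1e-9)
  img <- read_rgb_image(file.path(dir, "images", "d1_p01.png"))
  expect_equal(img, tr$images[["d1_p01"]], tolerance = 1e-9)
})
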