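# Exhaustive band-pair screening: NDI, matrices, aggregation, grouping.

toy_spectra <- function(n_plots, bands, seed) {
  set.seed(seed)
  lapply(seq_len(n_plots), function(i)
    spectrum(bands, runif(length(bands), 0.05, 0.8),
             plot_id = sprintf("p%02d", i)))
}

test_that("ndi matches direct substitution and is antisymmetric", {
  s <- spectrum(c(500, 600, 700), c(0.1, 0.1, 0.4))
  expect_equal(ndi(s, 700, 600), 0.6)
  expect_equal(ndi(s, 600, 500), 0)
  expect_equal(ndi(s, 600, 700), -ndi(s, 700, 600))
  expect_error(ndi(s, 600, 600), class = "ev_config_error")
  expect_error(ndi(s, 390, 600), class = "ev_range_error")
  z <- spectrum(c(500, 600), c(0, 0))
  expect_error(ndi(z, 600, 500), class = "ev_undefined_value")
})

test_that("contour matrix equals the brute-force oracle to 1e-12", {
  bands <- seq(450, 900, by = 50)               # 10 bands
  sp <- toy_spectra(20, bands, seed = 101)
  y <- vapply(sp, function(s) band(s, 700) * 3 + rnorm(1, 0, 0.1), numeric(1))
  cm <- contour_matrix(sp, y, trait = "toy", date = "1")
  oracle <- brute_force_r2(sp, y)
  expect_equal(cm$bands, oracle$bands)
  expect_equal(cm$r2, oracle$r2, tolerance = 1e-12)
  expect_true(all(is.na(diag(cm$r2))))
  expect_equal(cm$r2, t(cm$r2))
  defined <- cm$r2[!is.na(cm$r2)]
  expect_true(all(defined >= 0 & defined <= 1))
})

test_that("full aggregation pipeline equals the oracle across three dates", {
  bands <- seq(450, 900, by = 50)
  mats <- list(); oracles <- list()
  for (d in 1:3) {
    sp <- toy_spectra(20, bands, seed = 200 + d)
    y <- vapply(sp, function(s) band(s, 550) - band(s, 800), numeric(1))
    mats[[d]] <- contour_matrix(sp, y, trait = "toy", date = as.character(d))
    oracles[[d]] <- brute_force_r2(sp, y)$r2
  }
  agg <- aggregate_contour(mats)
  arr <- simplify2array(oracles)
  expect_equal(agg$mean_r2, apply(arr, c(1, 2), mean), tolerance = 1e-12)
  expect_equal(agg$cv_r2, apply(arr, c(1, 2), function(v) sd(v) / mean(v)),
               tolerance = 1e-12)
  # best pair of the mean matrix, reported b1 > b2
  mx <- apply(arr, c(1, 2), mean)
  idx <- which(mx == max(mx, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_equal(sort(agg$best_pair),
               sort(bands[c(idx[1], idx[2])]))
  expect_equal(agg$best_mean_r2, max(mx, na.rm = TRUE), tolerance = 1e-12)
  expect_equal(agg$cv_at_best,
               agg$cv_r2[match(agg$best_pair[2], bands),
                         match(agg$best_pair[1], bands)])
})

test_that("constructed perfect predictors and degenerate traits behave", {
  bands <- c(450, 600, 800)
  set.seed(33)
  sp <- toy_spectra(5, bands, seed = 33)
  y <- vapply(sp, function(s) 2 * ndi(s, 800, 450) + 1, numeric(1))
  cm <- contour_matrix(sp, y)
  expect_equal(cm$r2[match(800, cm$bands), match(450, cm$bands)], 1,
               tolerance = 1e-12)
  # constant trait -> all entries undefined
  cm0 <- contour_matrix(sp, rep(2, 5))
  expect_true(all(is.na(cm0$r2)))
  expect_error(contour_matrix(sp[1:2], y[1:2]), class = "ev_samplesize_error")
})

test_that("temporal aggregates: hand values, zero CV, tie-breaks", {
  vals <- c(0.31, 0.75, 0.75, 0.61)
  expect_equal(mean(vals), 0.605)
  expect_equal(sd(vals) / mean(vals), 0.3428839, tolerance = 1e-6)
  bands <- c(500, 600, 700)
  base <- matrix(c(NA, .2, .4, .2, NA, .6, .4, .6, NA), 3, 3)
  mk <- function(m, d) structure(list(bands = bands, r2 = m, trait = "t",
                                      date = d, n_plots = 5),
                                 class = "contour_matrix")
  agg_same <- aggregate_contour(list(mk(base, "1"), mk(base, "2")))
  expect_true(all(agg_same$cv_r2[!is.na(agg_same$cv_r2)] == 0))
  # tie on the mean: prefer the closer band pair
  tie <- matrix(c(NA, .6, .6, .6, NA, .6, .6, .6, NA), 3, 3)
  agg_tie <- aggregate_contour(list(mk(tie, "1"), mk(tie, "2")))
  expect_equal(agg_tie$best_pair, c(600, 500))
  expect_error(aggregate_contour(list(mk(base, "1"))),
               class = "ev_samplesize_error")
})

test_that("no output references bands below 400 nm", {
  g <- spectral_grid()
  set.seed(55)
  sp <- lapply(1:5, function(i) spectrum(g, runif(length(g), 0.05, 0.6)))
  cm <- contour_matrix(sp, rnorm(5))
  expect_true(all(cm$bands >= 400))
  expect_lt(length(cm$bands), length(g))
})

test_that("band pairs classify into VIS / red edge / NIR groups", {
  expect_equal(classify_band_pair(792, 736), "red edge/NIR")
  expect_equal(classify_band_pair(584, 582), "VIS/VIS")
  expect_equal(classify_band_pair(680, 740), "VIS/red edge")  # boundary rule
  expect_equal(classify_band_pair(740, 1100), "red edge/NIR")
  expect_equal(classify_band_pair(500, 1100), "VIS/NIR")
  expect_error(classify_band_pair(300, 500), class = "ev_range_error")
})

test_that("cross-trait comparison reports one labeled row per pair", {
  bands <- seq(450, 900, by = 50)
  mats_a <- list(); mats_b <- list()
  for (d in 1:2) {
    sp <- toy_spectra(10, bands, seed = 400 + d)
    ya <- vapply(sp, function(s) band(s, 700), numeric(1))
    mats_a[[d]] <- contour_matrix(sp, ya, trait = "a", date = as.character(d))
    mats_b[[d]] <- contour_matrix(sp, ya, trait = "b", date = as.character(d))
  }
  cmp <- cross_trait_compare(aggregate_contour(mats_a), aggregate_contour(mats_b))
  expect_equal(nrow(cmp), choose(length(bands), 2))
  expect_true(all(cmp$band1_nm > cmp$band2_nm))
  expect_equal(cmp$mean_r2_a, cmp$mean_r2_b)       # identical traits
  expect_true(all(cmp$group %in% c("VIS/VIS", "VIS/red edge", "VIS/NIR",
                                   "red edge/red edge", "red edge/NIR",
                                   "NIR/NIR")))
})

test_that("correlated traits give near-identical screening profiles", {
  # N uptake = DW x NC with near-constant NC: per-pair mean R2 for the two
  # traits should agree closely across the whole screen
  tr <- generate_trial(trial_design(seed = 10), render_images = FALSE)
  aggs <- contour_screen(tr, traits = c("dw", "nup"))
  cmp <- cross_trait_compare(aggs$dw, aggs$nup)
  ok <- complete.cases(cmp[c("mean_r2_a", "mean_r2_b")])
  expect_gt(cor(cmp$mean_r2_a[ok], cmp$mean_r2_b[ok]), 0.95)
})
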