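# Fixtures built in code: tiny grids, toy libraries, flat spectra.

# coarse toy endmember library for fast exact-recovery checks
toy_library <- function() {
  w <- seq(400, 1100, by = 50)
  soil <- seq(0.10, 0.30, length.out = length(w))
  veg <- ifelse(w < 680, 0.05, ifelse(w > 760, 0.45,
                0.05 + 0.40 * (w - 680) / 80))
  endmember_library(w, soil, veg)
}

flat_spectrum <- function(value = 0.2, wavelengths = spectral_grid()) {
  spectrum(wavelengths, rep(value, length(wavelengths)))
}

# a uniform solid-color image array
solid_image <- function(r, g, b, h = 64, w = 64) {
  img <- array(0, dim = c(h, w, 3))
  img[, , 1] <- r; img[, , 2] <- g; img[, , 3] <- b
  img
}
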