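# Independent oracles: brute-force reimplementations sharing no code with
# the package internals they check.

# naive double-loop band-pair screen
brute_force_r2 <- function(spectra, y) {
  w <- spectra[[1]]$wavelengths
  keep <- which(w >= 400)
  R <- sapply(spectra, function(s) s$reflectance[keep])
  nb <- length(keep)
  m <- matrix(NA_real_, nb, nb)
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    if (i == j) next
    x <- (R[i, ] - R[j, ]) / (R[i, ] + R[j, ])
    if (any(!is.finite(x)) || sd(x) == 0 || sd(y) == 0) next
    m[i, j] <- cor(x, y)^2
  }
  list(bands = w[keep], r2 = m)
}

# literal transcriptions of the nine index formulas, with their own
# nearest-band rule (sort by distance, first = lower wavelength on ties)
oracle_refl <- function(w, r, nm) {
  d <- abs(w - nm)
  r[which(d == min(d))[1]]
}

oracle_indices <- function(w, r) {
  b <- function(nm) oracle_refl(w, r, nm)
  c(ATSAVI = 1.22 * (b(800) - 1.22 * b(670) - 0.03) /
      (1.22 * b(800) + b(670) + 0.23),
    EPVI = (b(750) - b(670)) / b(862),
    MCARI = ((b(700) - b(670)) - 0.2 * (b(700) - b(550))) * (b(700) / b(670)),
    MTCI = (b(750) - b(710)) / (b(710) - b(680)),
    NDRE = (b(790) - b(720)) / (b(790) + b(720)),
    NDVI = (b(864) - b(671)) / (b(864) + b(671)),
    PRI = (b(531) - b(570)) / (b(531) + b(570)),
    REIP = 700 + 40 * ((b(668) + b(778)) / 2 - b(698)) / (b(738) - b(698)),
    WBI = b(900) / b(970))
}
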