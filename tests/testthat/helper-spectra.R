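# shared fixture builders (everything generated in code; no stored spectra)

# single Gaussian peak spectrum on a given grid
gaussian_spectrum <- function(center = 285, fwhm = 1.1, height = 1,
                              grid = seq(280, 294, by = 0.05), baseline = 0) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  xps_spectrum(grid, baseline + height * exp(-(grid - center)^2 / (2 * sigma^2)))
}

# trapezoid integral
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# forward-construct an exact Shirley step on top of a known peak:
# B(E) = b_lo + (b_hi - b_lo) * cumint(peak)/totint(peak)
shirley_fixture <- function(peak_spec, b_lo, b_hi) {
  e <- peak_spec$energy; p <- peak_spec$intensity
  cum <- cumsum(c(0, diff(e) * (head(p, -1) + tail(p, -1)) / 2))
  b <- b_lo + (b_hi - b_lo) * cum / cum[length(cum)]
  list(spectrum = xps_spectrum(e, p + b), background = b)
}

# random valid protein sequence under a fixed-seeded RNG stream
random_sequence <- function(n, seed) {
  codes <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
             "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  set.seed(seed)
  protein_sequence(sample(codes, n, replace = TRUE), id = paste0("rnd", seed))
}

write_temp_fasta <- function(records) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}
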