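# Small phantom used across tests: 12 slices of 64x64, five regular nuclei
small_phantom_spec <- function(rng_seed = 42L, n_cells = 5L, ...) {
  synthetic_spec(shape = c(12L, 64L, 64L), n_cells = n_cells,
                 radius_range = c(1.0, 1.6), nucleus_mode = "regular",
                 rng_seed = rng_seed, ...)
}

# histogram whose bins are (rounded) exact samples of a Gaussian,
# optionally contaminated with a small far mode (a fraction of all pixels)
gaussian_histogram <- function(A, mu, sigma, contaminant_at = NULL,
                               contaminant_frac = 0.01) {
  q <- 0:255
  counts <- round(A * exp(-(q - mu)^2 / (2 * sigma^2)))
  if (!is.null(contaminant_at)) {
    total <- sum(counts)
    c2 <- round(contaminant_frac * total *
                  exp(-(q - contaminant_at)^2 / 8) / sqrt(2 * pi * 4))
    counts <- counts + c2
  }
  structure(list(counts = counts, n_pixels = sum(counts)),
            class = "intensity_histogram")
}
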