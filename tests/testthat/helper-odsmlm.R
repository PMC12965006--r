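# shared fixtures: a default instrument, the dye pair, and small helpers

test_config <- function(...) optical_config(...)

test_spectra <- function() {
  list(AF647 = make_dye_spectrum("AF647"),
       CF660C = make_dye_spectrum("CF660C"))
}

# monochromatic line spectrum (delta function on the grid)
delta_spectrum <- function(lambda_nm, grid = seq(620, 750, by = 1)) {
  i <- which.min(abs(grid - lambda_nm))
  dens <- rep(0, length(grid))
  dens[i] <- 1
  out <- tibble::tibble(wavelength_nm = grid, intensity = dens)
  attr(out, "centroid_nm") <- grid[i]
  class(out) <- c("emission_spectrum", class(out))
  out
}

# simulate one frame and hand it to the public localizers (baseline included)
sim_one <- function(x_nm, y_nm, z_nm = 0, method = "od", n_signal = 3000,
                    n_background = 0, dye = "AF647", cfg = test_config(),
                    spectra = test_spectra(), noise = FALSE, seed = NULL) {
  em <- tibble::tibble(x_nm = x_nm, y_nm = y_nm, z_nm = z_nm, dye = dye,
                       n_signal = n_signal, n_background = n_background)
  fr <- simulate_frame(em, method, spectra, cfg, seed = seed, noise = noise)
  if (!noise) fr$images <- lapply(fr$images, function(m) m + cfg$baseline)
  fr
}

# event table for repeated single-emitter simulations
single_emitter_events <- function(n, photons = 3000, background = 10000,
                                  z_nm = 0, dye = "AF647", seed = 1) {
  set.seed(seed)
  tibble::tibble(frame = seq_len(n),
                 x_nm = stats::runif(n, 0, 100),
                 y_nm = stats::runif(n, 0, 100),
                 z_nm = z_nm, dye = dye, n_signal = photons,
                 n_background = background)
}
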