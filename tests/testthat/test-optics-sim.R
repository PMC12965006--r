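cfg <- test_config()

test_that("PSF width follows the defocus law", {
  expect_equal(psf_sigma(0, cfg), cfg$psf_sigma0_nm)
  expect_equal(psf_sigma(cfg$psf_depth_scale_nm, cfg),
               cfg$psf_sigma0_nm * sqrt(2))
  z <- runif(20, -800, 800)
  expect_equal(psf_sigma(z, cfg), psf_sigma(-z, cfg))
  expect_true(all(diff(psf_sigma(seq(0, 800, by = 50), cfg)) >= 0))
})

test_that("a monochromatic emitter at the reference wavelength is undispersed", {
  img <- disperse(15.5, 14.2, 0, 1000, delta_spectrum(cfg$lambda_ref_nm),
                  axis = "x", config = cfg)
  ref <- disperse(15.5, 14.2, 0, 1000, NULL, axis = "x", config = cfg)
  expect_equal(unclass(img), unclass(ref), tolerance = 1e-12,
               ignore_attr = TRUE)
  # a line at lambda_ref + 10 d is the same PSF shifted exactly 10 pixels
  shifted <- disperse(5.5, 14.2, 0, 1000,
                      delta_spectrum(cfg$lambda_ref_nm +
                                       10 * cfg$dispersion_nm_per_px),
                      axis = "x", config = cfg)
  expect_equal(unclass(shifted)[, 11:26], unclass(ref)[, 11:26],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("dispersed image centroid sits at position + (centroid - ref)/d", {
  spec <- make_dye_spectrum("AF647")
  cfg2 <- optical_config(roi_px = 48)
  x0 <- 10.3
  img <- disperse(x0, 24.0, 0, 1e5, spec, axis = "x", config = cfg2)
  colsum <- colSums(img)
  got <- sum((seq_along(colsum) - 1) * colsum) / sum(colsum)
  # brute-force oracle: dense numerical integration of the spectrum-weighted
  # Gaussian mean along the dispersion axis
  lam <- spec$wavelength_nm
  pos <- x0 + (lam - cfg2$lambda_ref_nm) / cfg2$dispersion_nm_per_px
  oracle <- sum(spec$intensity * pos) / sum(spec$intensity)
  expect_equal(got, oracle, tolerance = 1e-2)
  expect_equal(got, x0 + (attr(spec, "centroid_nm") - cfg2$lambda_ref_nm) /
                 cfg2$dispersion_nm_per_px, tolerance = 1e-2)
})

test_that("dispersion shifts are confined to the dispersion axis", {
  spec1 <- delta_spectrum(660)
  spec2 <- delta_spectrum(672)   # +12 nm = +2 px at 6 nm/px
  img1 <- disperse(12, 15, 0, 1000, spec1, axis = "x", config = cfg)
  img2 <- disperse(12, 15, 0, 1000, spec2, axis = "x", config = cfg)
  r1 <- rowSums(img1); r2 <- rowSums(img2)
  c1 <- colSums(img1); c2 <- colSums(img2)
  expect_equal(r1, r2, tolerance = 1e-9)             # non-dispersed axis fixed
  expect_equal(c1[5:26], c2[7:28], tolerance = 1e-9) # dispersed axis: 2 px
})

test_that("photon budget is conserved across both channels of every method", {
  spectra <- test_spectra()
  for (m in c("od", "sd", "ssmlm")) {
    cfgm <- optical_config(roi_px = 64,
                           split_ratio = if (m == "ssmlm") 0.25 else 0.5)
    em <- tibble::tibble(x_nm = 2200, y_nm = 3200, z_nm = 0, dye = "AF647",
                         n_signal = 4000, n_background = 0)
    fr <- simulate_frame(em, m, spectra, cfgm, noise = FALSE)
    expect_lt(abs(sum(fr$images$A) + sum(fr$images$B) - 4000), 0.01 * 4000)
    share <- sum(fr$images$A) / 4000
    expect_lt(abs(share - cfgm$split_ratio), 0.01)
  }
})

test_that("camera noise model has Poisson + read-noise statistics and is seeded", {
  cfgz <- optical_config(read_noise_e = 0, baseline = 7)
  zero <- matrix(0, 8, 8)
  expect_equal(add_camera_noise(zero, cfgz, seed = 1), matrix(7, 8, 8))
  expect_error(add_camera_noise(matrix(-1, 2, 2), cfg), "negative")

  # Monte-Carlo oracle: per-pixel variance = mean + read_noise^2
  cfgn <- optical_config(read_noise_e = 2, baseline = 0)
  img <- matrix(20, 1, 1)
  set.seed(11)
  draws <- replicate(10000, add_camera_noise(img, cfgn,
                                             background_per_px = 5)[1, 1])
  expect_equal(mean(draws), 25, tolerance = 0.05)
  expect_equal(var(draws), 25 + 4, tolerance = 0.05)

  n1 <- add_camera_noise(matrix(10, 5, 5), cfg, seed = 99)
  n2 <- add_camera_noise(matrix(10, 5, 5), cfg, seed = 99)
  expect_identical(n1, n2)
})

test_that("frame geometries put position on the non-dispersive axes", {
  spectra <- test_spectra()
  cfg2 <- optical_config(roi_px = 60)
  x0 <- 3010; y0 <- 3030
  em <- tibble::tibble(x_nm = x0, y_nm = y0, z_nm = 0, dye = "AF647",
                       n_signal = 5000, n_background = 0)

  fr <- simulate_frame(em, "od", spectra, cfg2, noise = FALSE)
  centroid <- function(v) (sum((seq_along(v) - 1) * v) / sum(v))
  # channel A: y is non-dispersed; channel B: x is non-dispersed
  expect_lt(abs(centroid(rowSums(fr$images$A)) * 100 - y0), 0.5)
  expect_lt(abs(centroid(colSums(fr$images$B)) * 100 - x0), 0.5)

  # symmetric dispersion: the mean of the two mirrored centroids is the true
  # position regardless of the spectrum
  frs <- simulate_frame(em, "sd", spectra, cfg2, noise = FALSE)
  ca <- centroid(colSums(frs$images$A))
  cb <- centroid(colSums(frs$images$B))
  expect_lt(abs((ca + cb) / 2 * 100 - x0), 0.6)
  expect_gt(abs(ca - cb), 1)   # the spectral offset itself is nonzero

  expect_error(simulate_frame(dplyr::mutate(em, dye = "dyeX"), "od", spectra,
                              cfg2), "spectrum for dye")
})

test_that("sSMLM 1:3 photon allocation holds on average over noisy frames", {
  spectra <- test_spectra()
  cfg3 <- optical_config(roi_px = 48, split_ratio = 0.25, baseline = 0,
                         read_noise_e = 1.6)
  em <- tibble::tibble(x_nm = 1200, y_nm = 2400, z_nm = 0, dye = "AF647",
                       n_signal = 2000, n_background = 0)
  set.seed(5)
  sums <- t(replicate(300, {
    fr <- simulate_frame(em, "ssmlm", spectra, cfg3)
    c(sum(fr$images$A), sum(fr$images$B))
  }))
  expect_equal(mean(sums[, 1]) / mean(sums[, 2]), 1 / 3, tolerance = 0.02)
})

test_that("biplane defocus makes one channel narrow while the other widens", {
  spectra <- test_spectra()
  widths <- sapply(c(-250, 0, 250), function(z) {
    fr <- sim_one(1600, 1600, z_nm = z, cfg = optical_config(roi_px = 56),
                  n_signal = 2e4)
    c(h = fit_gaussian_1d(rowSums(fr$images$A - 100))$fwhm,
      v = fit_gaussian_1d(colSums(fr$images$B - 100))$fwhm)
  })
  # at the H focal plane the H channel is at its narrowest, V widest
  expect_lt(widths["h", 1], widths["h", 3])
  expect_gt(widths["v", 1], widths["v", 3])
  # z = 0 is symmetric between the two channels
  expect_equal(unname(widths["h", 2]), unname(widths["v", 2]),
               tolerance = 0.02)
})
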