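test_that("dye spectra are normalized and behave like skew-normals", {
  sym <- make_dye_spectrum("sym", peak_nm = 670, width_nm = 10, skew = 0)
  step <- diff(sym$wavelength_nm)[1]
  expect_equal(sum(sym$intensity * step), 1, tolerance = 1e-9)
  expect_equal(spectrum_centroid(sym), 670, tolerance = 1e-6)

  af <- make_dye_spectrum("AF647")
  expect_equal(sum(af$intensity * step), 1, tolerance = 1e-9)
  expect_gt(spectrum_centroid(af), 668)
  # quadrature oracle: mean of the same skew-normal density computed by
  # adaptive integration on a fine independent grid
  dens <- function(x) 2 / 18 * dnorm((x - 668) / 18) * pnorm(3 * (x - 668) / 18)
  norm <- integrate(dens, 620, 750)$value
  mean_oracle <- integrate(function(x) x * dens(x), 620, 750)$value / norm
  expect_equal(spectrum_centroid(af), mean_oracle, tolerance = 1e-3)

  expect_error(make_dye_spectrum("NotADye"), "unknown dye")
})

test_that("spectrum CSV round-trips through renormalization", {
  af <- make_dye_spectrum("AF647")
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(af, path)
  af2 <- read_spectrum_csv(path)
  expect_equal(af2$intensity, af$intensity, tolerance = 1e-6)
})

test_that("spectral centroid handles point masses, symmetry and shifts", {
  prof <- spectral_profile(0:20, c(rep(0, 10), 5, rep(0, 10)),
                           seq(660, 680, by = 1))
  expect_equal(spectral_centroid(prof), 670)

  sym_counts <- dnorm(0:30, 15, 4)
  prof2 <- spectral_profile(0:30, sym_counts, seq(660, 690, by = 1))
  expect_equal(spectral_centroid(prof2), 675, tolerance = 1e-9)

  # shift equivariance: moving the wavelength axis moves the centroid exactly
  prof3 <- spectral_profile(0:30, sym_counts, seq(660, 690, by = 1) + 7.3)
  expect_equal(spectral_centroid(prof3, band_nm = c(620, 760)),
               675 + 7.3, tolerance = 1e-9)

  expect_error(spectral_centroid(spectral_profile(0:5, rep(0, 6),
                                                  seq(660, 665, 1))),
               "positive counts")
})

test_that("background subtraction uses out-of-band bins and never clips", {
  lam <- seq(560, 800, by = 2)
  counts <- 50 + dnorm(lam, 670, 10) * 1000
  prof <- subtract_profile_background(spectral_profile(seq_along(lam) - 1,
                                                       counts, lam))
  expect_equal(attr(prof, "background"), 50, tolerance = 1)
  expect_true(any(prof$counts < 0) || min(prof$counts) >= -1e-9)
})

test_that("two-channel averaging keeps identical inputs and reduces noise", {
  lam <- seq(640, 700, by = 1)
  clean <- dnorm(lam, 670, 9) * 3000
  prof <- spectral_profile(seq_along(lam) - 1, clean, lam)
  avg <- average_spectra(prof, prof)
  expect_equal(avg$counts, clean, tolerance = 1e-9)
  expect_equal(spectral_centroid(avg, c(620, 750)),
               spectral_centroid(prof, c(620, 750)), tolerance = 1e-9)

  disjoint <- spectral_profile(seq_along(lam) - 1, clean, lam + 200)
  expect_error(average_spectra(prof, disjoint), "disjoint")

  # Monte-Carlo oracle: averaging two independent equal-variance channels
  # shrinks the centroid scatter by ~1/sqrt(2)
  set.seed(42)
  n_rep <- 400
  cents <- t(replicate(n_rep, {
    y1 <- rpois(length(lam), clean)
    y2 <- rpois(length(lam), clean)
    p1 <- spectral_profile(seq_along(lam) - 1, y1, lam)
    p2 <- spectral_profile(seq_along(lam) - 1, y2, lam)
    c(one = spectral_centroid(p1, c(620, 750)),
      avg = spectral_centroid(average_spectra(p1, p2), c(620, 750)))
  }))
  ratio <- sd(cents[, "avg"]) / sd(cents[, "one"])
  expect_lt(sd(cents[, "avg"]), sd(cents[, "one"]))
  expect_equal(ratio, 1 / sqrt(2), tolerance = 0.1)
})
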