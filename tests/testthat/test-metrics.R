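test_that("precision estimators recover known scatter", {
  locs <- tibble::tibble(x_nm = rep(5, 60), y_nm = rep(7, 60),
                         z_nm = rep(1, 60), valid = TRUE)
  p <- localization_precision(locs)
  expect_equal(c(p$sigma_x_nm, p$sigma_y_nm, p$sigma_z_nm), c(0, 0, 0))

  set.seed(16)
  locs2 <- tibble::tibble(x_nm = rnorm(1000, 0, 10), y_nm = rnorm(1000, 0, 10),
                          valid = TRUE)
  p2 <- localization_precision(locs2, truth = list(x_nm = 0, y_nm = 0))
  expect_lt(abs(p2$sigma_x_nm - 10), 1)
  expect_lt(abs(p2$rmse_x_nm - 10), 1)

  expect_equal(spectral_precision(rep(670, 80))$sigma_lambda_nm, 0)
  set.seed(17)
  sp <- spectral_precision(rnorm(1000, 668, 1.1))
  expect_lt(abs(sp$sigma_lambda_nm - 1.1), 0.15)
})

test_that("the precision estimator is unbiased over repeated cohorts", {
  set.seed(18)
  ests <- replicate(100, {
    locs <- tibble::tibble(x_nm = rnorm(200, 0, 8), y_nm = rnorm(200, 0, 8),
                           valid = TRUE)
    localization_precision(locs)$sigma_x_nm
  })
  expect_lt(abs(mean(ests) - 8), 8 / sqrt(200) * 3)
})

test_that("crosstalk is permutation-aligned and validates input", {
  truth <- c(0L, 0L, 1L, 1L)
  expect_equal(crosstalk(c(0L, 0L, 1L, 1L), truth), 0)
  expect_equal(crosstalk(c(1L, 1L, 0L, 0L), truth), 0)   # global swap
  expect_equal(crosstalk(c(0L, 1L, 1L, 1L), truth), 25)
  expect_error(crosstalk(c(0L, 1L), truth), "length")
})

test_that("rendering conserves counts in both modes", {
  locs <- tibble::tibble(x_nm = c(15, 101, 57), y_nm = c(22, 88, 30),
                         valid = TRUE)
  img <- render(locs, render_pixel_nm = 10, mode = "histogram")
  expect_equal(sum(img), 3)
  one <- render(locs[1, ], render_pixel_nm = 10)
  expect_equal(sum(one > 0), 1)
  # generous extent: splatted kernels must stay inside the image
  g <- render(locs, render_pixel_nm = 10, mode = "gaussian", sigma_nm = 15,
              extent_nm = c(-100, 220, -100, 220))
  expect_equal(sum(g), 3, tolerance = 0.01)
  empty <- render(locs[0, ], render_pixel_nm = 10)
  expect_equal(sum(empty), 0)
})

test_that("FRC equals a direct-DFT oracle and flags identical halves", {
  # identical half-images: correlation is 1 everywhere, no 1/7 crossing
  set.seed(19)
  pts <- tibble::tibble(x_nm = runif(600, 0, 2000),
                        y_nm = runif(600, 0, 2000))
  img <- render(pts, 10, extent_nm = c(0, 2000, 0, 2000))
  curve_same <- odsmlm:::frc_curve(unclass(img), unclass(img))
  expect_true(all(abs(curve_same$frc[-1] - 1) < 1e-9, na.rm = TRUE))

  # dense jittered line: package FFT ring average vs a brute-force DFT
  set.seed(20)
  n <- 4000
  locs <- tibble::tibble(
    x_nm = runif(n, 0, 1280),
    y_nm = 640 + rnorm(n, 0, 10), valid = TRUE)
  res <- frc_resolution(locs, render_pixel_nm = 10, seed = 3)
  expect_true(res$crossed)

  # oracle: same split, direct DFT on a ring grid (small image)
  set.seed(3)
  half <- sample(c(TRUE, FALSE), n, replace = TRUE)
  ext <- c(min(locs$x_nm), max(locs$x_nm) + 10, min(locs$y_nm),
           max(locs$y_nm) + 10)
  i1 <- unclass(render(locs[half, ], 10, extent_nm = ext))
  i2 <- unclass(render(locs[!half, ], 10, extent_nm = ext))
  np <- max(dim(i1))
  pad <- function(m) { o <- matrix(0, np, np); o[1:nrow(m), 1:ncol(m)] <- m; o }
  dft <- function(m) {
    # brute-force 2D DFT via explicit basis matrices (independent of fft())
    w <- exp(-2i * pi * outer(0:(np - 1), 0:(np - 1)) / np)
    w %*% m %*% w
  }
  f1 <- dft(pad(i1)); f2 <- dft(pad(i2))
  kx <- c(0:(np %/% 2), -((np - np %/% 2 - 1):1)) / np
  ring <- round(sqrt(outer(kx^2, kx^2, "+")) * np)
  num <- tapply(Re(f1 * Conj(f2)), ring, sum)
  den <- sqrt(tapply(Mod(f1)^2, ring, sum) * tapply(Mod(f2)^2, ring, sum))
  frc <- (num / den)[as.character(0:(np %/% 2))]
  below <- which(frc < 1 / 7 & (0:(np %/% 2)) > 0)
  k <- below[1]
  frac <- (frc[k - 1] - 1 / 7) / (frc[k - 1] - frc[k])
  res_oracle <- np * 10 / ((k - 2) + frac)
  expect_equal(res$resolution_nm, unname(res_oracle), tolerance = 0.05)
})

test_that("FRC resolution degrades monotonically with localization jitter", {
  set.seed(22)
  res <- sapply(c(5, 10, 20), function(s) {
    n <- 4000
    locs <- tibble::tibble(
      x_nm = runif(n, 0, 1280),
      y_nm = 640 + rnorm(n, 0, s), valid = TRUE)
    frc_resolution(locs, render_pixel_nm = 10, seed = 4)$resolution_nm
  })
  expect_true(all(diff(res) > 0))
})

test_that("line profiles recover a known filament cross-section", {
  set.seed(23)
  n <- 20000; s <- 12
  locs <- tibble::tibble(x_nm = runif(n, 0, 1000),
                         y_nm = 250 + rnorm(n, 0, s), valid = TRUE)
  img <- render(locs, 5, extent_nm = c(0, 1000, 0, 500))
  prof <- line_profile_fwhm(img, p0_nm = c(500, 0), p1_nm = c(500, 500),
                            width_px = 160)
  expect_equal(prof$fwhm_nm, 2 * sqrt(2 * log(2)) * s, tolerance = 0.05)
  flat <- render(tibble::tibble(x_nm = runif(500, 0, 1000),
                                y_nm = runif(500, 0, 500), valid = TRUE),
                 5, extent_nm = c(0, 1000, 0, 500))
  expect_error(line_profile_fwhm(flat, c(500, 0), c(500, 500), 160),
               "no fittable peak")
})
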