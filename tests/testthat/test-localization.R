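test_that("closed-form refinement reproduces both sign-case formulas exactly", {
  # the two published sign cases, written out independently
  case_lo <- function(xh, yh, xv, yv) {     # xh < xv, yv < yh
    dl <- ((xv - xh) + (yh - yv)) / 2
    list(x = (xh + dl + xv) / 2, y = (yv + dl + yh) / 2)
  }
  case_hi <- function(xh, yh, xv, yv) {     # xh > xv, yv > yh
    dl <- ((xh - xv) + (yv - yh)) / 2
    list(x = (xh - dl + xv) / 2, y = (yv - dl + yh) / 2)
  }
  set.seed(7)
  n <- 10000
  xh <- rnorm(n, 50, 10); yh <- rnorm(n, 50, 10)
  xv <- rnorm(n, 50, 10); yv <- rnorm(n, 50, 10)
  ref <- refine_position(list(xh = xh, yh = yh, xv = xv, yv = yv))
  lo <- case_lo(xh, yh, xv, yv)
  hi <- case_hi(xh, yh, xv, yv)
  expect_lt(max(abs(lo$x - ref$x)), 1e-10)
  expect_lt(max(abs(lo$y - ref$y)), 1e-10)
  expect_lt(max(abs(hi$x - ref$x)), 1e-10)
  expect_lt(max(abs(hi$y - ref$y)), 1e-10)
})

test_that("refinement cancels a common spectral shift to machine precision", {
  expect_equal(refine_position(list(xh = 0, yh = 0, xv = 0, yv = 0))[1:3],
               tibble::tibble(x = 0, y = 0, delta_lambda_px = 0))
  # hand-checked worked example: common 5 px offset
  r <- refine_position(list(xh = 105, yh = 200, xv = 100, yv = 205))
  expect_identical(r$x, 100)
  expect_identical(r$y, 200)
  expect_identical(r$delta_lambda_px, 5)
  expect_false(r$mixed_sign)

  set.seed(8)
  for (i in 1:200) {
    base <- rnorm(4, 30, 5)
    shift <- runif(1, -10, 10)
    r0 <- refine_position(list(xh = base[1], yh = base[2],
                               xv = base[3], yv = base[4]))
    r1 <- refine_position(list(xh = base[1] + shift, yh = base[2],
                               xv = base[3], yv = base[4] + shift))
    expect_equal(r0$x, r1$x, tolerance = 1e-12)
    expect_equal(r0$y, r1$y, tolerance = 1e-12)
  }
})

test_that("refined-position variance matches the linear-combination closed form", {
  set.seed(9)
  sigma <- 0.2
  n <- 100000
  xh <- rnorm(n, 0, sigma); yh <- rnorm(n, 0, sigma)
  xv <- rnorm(n, 0, sigma); yv <- rnorm(n, 0, sigma)
  r <- refine_position(list(xh = xh, yh = yh, xv = xv, yv = yv))
  # var((3 xv + xh + yh - yv)/4) = 12 sigma^2 / 16
  expect_equal(var(r$x), 12 * sigma^2 / 16, tolerance = 0.02)
  expect_equal(var(r$y), 12 * sigma^2 / 16, tolerance = 0.02)
})

test_that("noiseless orthogonal channels measure the four raw coordinates", {
  # mid-band reference wavelength so the monochromatic test line sits well
  # inside the centroid window
  cfg <- optical_config(roi_px = 52, lambda_ref_nm = 670)
  x0 <- 1630; y0 <- 1770
  # monochromatic at lambda_ref: no spectral offset anywhere
  fr <- sim_one(x0, y0, cfg = cfg, n_signal = 2e4,
                spectra = list(AF647 = delta_spectrum(cfg$lambda_ref_nm)))
  m <- measure_channels(fr, cfg)
  expect_true(m$ok)
  expect_lt(abs(m$xh * 100 - x0), 0.2)
  expect_lt(abs(m$xv * 100 - x0), 0.2)
  expect_lt(abs(m$yh * 100 - y0), 0.2)
  expect_lt(abs(m$yv * 100 - y0), 0.2)

  # line at lambda_ref + 5 d: only the dispersed coordinates shift, by 5 px
  d <- cfg$dispersion_nm_per_px
  fr2 <- sim_one(x0, y0, cfg = cfg, n_signal = 2e4,
                 spectra = list(AF647 = delta_spectrum(cfg$lambda_ref_nm + 5 * d)))
  m2 <- measure_channels(fr2, cfg)
  expect_lt(abs(m2$xh - (m$xh + 5)), 5e-3)
  expect_lt(abs(m2$yv - (m$yv + 5)), 5e-3)
  expect_lt(abs(m2$xv - m$xv), 2e-3)
  expect_lt(abs(m2$yh - m$yh), 2e-3)

  # and the refinement recovers the true position under the shift
  r2 <- refine_position(m2)
  expect_lt(abs(r2$x * 100 - x0), 0.3)
  expect_lt(abs(r2$y * 100 - y0), 0.3)
  expect_lt(abs(r2$delta_lambda_px - 5), 1e-2)
})

test_that("dispersed-axis coordinates are noisier than non-dispersed ones", {
  cfg <- optical_config(roi_px = 46)
  spectra <- test_spectra()
  set.seed(10)
  M <- purrr::map_dfr(1:250, function(i) {
    fr <- sim_one(1230, 1240, cfg = cfg, n_signal = 3000,
                  n_background = 10000, noise = TRUE)
    measure_channels(fr, cfg)[, 1:7]
  })
  ok <- M[M$ok, ]
  expect_gt(var(ok$xh), 1.5 * var(ok$xv))
  expect_gt(var(ok$yv), 1.5 * var(ok$yh))
})

test_that("symmetric-dispersion localization is exact without noise", {
  cfg <- optical_config(roi_px = 70)
  x0 <- 3530; y0 <- 3540
  fr <- sim_one(x0, y0, method = "sd", cfg = cfg, n_signal = 2e4)
  loc <- localize_sdsmlm(fr, cfg)
  expect_true(loc$valid)
  expect_lt(abs(loc$x_px * 100 - x0), 0.5)
  expect_lt(abs(loc$y_px * 100 - y0), 0.2)
  # the mirrored separation maps back to the spectrum centroid
  af_centroid <- attr(make_dye_spectrum("AF647"), "centroid_nm")
  expect_lt(abs(loc$lambda_c_nm - af_centroid), 0.5)
  expect_lt(abs(cfg$lambda_ref_nm + loc$delta_lambda_nm - af_centroid), 0.5)
})

test_that("conventional sSMLM recovers position and centroid without noise", {
  cfg <- optical_config(roi_px = 52, split_ratio = 0.25)
  x0 <- 1210; y0 <- 2610
  fr <- sim_one(x0, y0, method = "ssmlm", cfg = cfg, n_signal = 2e4)
  loc <- localize_ssmlm(fr, cfg)
  expect_true(loc$valid)
  expect_lt(abs(loc$x_px * 100 - x0), 0.2)
  expect_lt(abs(loc$y_px * 100 - y0), 0.2)
  af_centroid <- attr(make_dye_spectrum("AF647"), "centroid_nm")
  expect_lt(abs(loc$lambda_c_nm - af_centroid), 0.5)
})

test_that("sSMLM anchor error propagates into the centroid as dx * d", {
  cfg <- optical_config(roi_px = 52, split_ratio = 0.25)
  fr <- sim_one(1210, 2610, method = "ssmlm", cfg = cfg, n_signal = 2e4)
  base <- localize_ssmlm(fr, cfg)
  # inject a known zeroth-order shift: translate channel A by 2 pixels
  shifted <- fr
  img <- fr$images$A
  img2 <- img
  img2[] <- cfg$baseline
  img2[, 3:ncol(img)] <- img[, 1:(ncol(img) - 2)]
  shifted$images$A <- img2
  loc2 <- localize_ssmlm(shifted, cfg)
  expect_lt(abs(loc2$x_px - (base$x_px + 2)), 5e-3)
  expect_lt(abs(loc2$lambda_c_nm -
                  (base$lambda_c_nm - 2 * cfg$dispersion_nm_per_px)), 0.3)
})

test_that("channel registration recovers a known similarity transform", {
  set.seed(12)
  pts <- cbind(runif(20, 0, 40), runif(20, 0, 40))
  ang <- 0.05; s <- 1.02; tr <- c(1.5, -0.7)
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  moved <- t(apply(pts, 1, function(p) (t(R) %*% (p - tr)) / s))
  reg <- estimate_channel_registration(pts, moved)
  expect_equal(reg$scale, s, tolerance = 1e-6)
  expect_equal(reg$rotation, R, tolerance = 1e-6)
  back <- apply_channel_registration(moved, reg)
  expect_equal(back, pts, tolerance = 1e-6, ignore_attr = TRUE)
})
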