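# Internal vector kernels. The exported tibble-facing functions wrap these,
# and the per-event benchmark loop calls them directly: one event touches a
# kernel a dozen times, so they avoid any per-call data-frame construction.

# background estimate for a dispersion-axis profile: median of the bins
# outside the emission band, falling back to the outer 20% of bins.
.profile_background <- function(counts, lam, band) {
  out_band <- lam < band[1] | lam > band[2]
  if (sum(out_band) >= 4) return(stats::median(counts[out_band]))
  n <- length(counts)
  k <- max(1L, floor(0.2 * n / 2))
  stats::median(counts[c(seq_len(k), seq(n - k + 1L, n))])
}

# intensity-weighted centroid over the emission band, negative bins excluded
.profile_centroid <- function(counts, lam, band) {
  sel <- lam >= band[1] & lam <= band[2] & counts > 0
  s <- sum(counts[sel])
  if (!any(sel) || s <= 0) return(NA_real_)
  sum(lam[sel] * counts[sel]) / s
}

# analyze one dispersed axis: wavelength mapping anchored at `anchor_px`,
# background subtraction, band-limited centroid. Returns the raw pixel
# centroid as well (anchor-independent: the mapping is linear).
.spec_axis <- function(counts, anchor_px, sign, cfg) {
  j <- seq_along(counts) - 1
  lam <- cfg$lambda_ref_nm + sign * (j - anchor_px) * cfg$dispersion_nm_per_px
  bg <- .profile_background(counts, lam, cfg$spectral_band_nm)
  cnt <- counts - bg
  lc <- .profile_centroid(cnt, lam, cfg$spectral_band_nm)
  list(pixel = j, counts = cnt, background = bg, lambda_c = lc,
       px_centroid = anchor_px +
         sign * (lc - cfg$lambda_ref_nm) / cfg$dispersion_nm_per_px,
       ok = is.finite(lc))
}

# pointwise mean of two profiles on the overlap of their wavelength grids
.avg_profiles <- function(lam1, cnt1, lam2, cnt2) {
  lo <- max(min(lam1), min(lam2))
  hi <- min(max(lam1), max(lam2))
  if (lo >= hi) return(NULL)
  step <- min(min(abs(diff(lam1))), min(abs(diff(lam2))))
  grid <- seq(lo, hi, by = step)
  i1 <- stats::approx(lam1, cnt1, xout = grid)$y
  i2 <- stats::approx(lam2, cnt2, xout = grid)$y
  list(lam = grid, counts = (i1 + i2) / 2)
}

# 1D profiles of a channel image: non-dispersed marginal and the spectral
# trace restricted to a row band around the fitted non-dispersed center.
# `dispersion` = 1 means dispersion runs along columns (x).
.channel_profiles <- function(img, dispersion_x, row_center, row_halfwidth) {
  if (!dispersion_x) img <- t(img)
  nd <- rowSums(img)
  rows <- seq_len(nrow(img)) - 1
  sel <- abs(rows - row_center) <= row_halfwidth
  if (!any(sel)) sel <- rep(TRUE, nrow(img))
  list(nd = nd, spec = colSums(img[sel, , drop = FALSE]))
}

# expected-photon images of one emitter in both channels of a method
.sim_event_expected <- function(method, x_px, y_px, z_nm, n_signal, spectrum,
                                cfg) {
  geom <- method_geometry(method, cfg)
  lapply(geom, function(ch) {
    disperse(x_px, y_px, z_nm, n_signal * ch$share,
             spectrum = if (is.na(ch$axis)) NULL else spectrum,
             axis = if (is.na(ch$axis)) "x" else ch$axis,
             dispersion_sign = ch$sign, plane_offset_nm = ch$plane,
             config = cfg, warn_truncation = FALSE)
  })
}

# noisy event images (uses the current RNG stream)
.sim_event <- function(method, x_px, y_px, z_nm, n_signal, n_background,
                       spectrum, cfg) {
  imgs <- .sim_event_expected(method, x_px, y_px, z_nm, n_signal, spectrum, cfg)
  bg <- n_background / (32 * 32)
  lapply(imgs, function(m) {
    matrix(stats::rpois(length(m), m + bg) +
             stats::rnorm(length(m), 0, cfg$read_noise_e),
           nrow = nrow(m))
  })
}

.loc_names <- c("x_px", "y_px", "lambda_c_nm", "delta_lambda_px",
                "fwhm_a_nm", "fwhm_b_nm", "mixed_sign", "valid")

.loc_bad <- stats::setNames(rep(NA_real_, 8), .loc_names)

# orthogonal-dispersion localizer kernel (images are baseline-free)
.loc_od <- function(imgs, cfg, keep_profile = FALSE) {
  fit_h <- fit_gaussian_1d(rowSums(imgs$A))
  fit_v <- fit_gaussian_1d(colSums(imgs$B))
  if (!fit_h$ok || !fit_v$ok) return(.loc_bad)
  yh <- fit_h$center; xv <- fit_v$center

  ph <- .channel_profiles(imgs$A, TRUE, yh, row_halfwidth_px(fit_h$sigma))$spec
  pv <- .channel_profiles(imgs$B, FALSE, xv, row_halfwidth_px(fit_v$sigma))$spec
  sh <- .spec_axis(ph, xv, 1, cfg)
  sv <- .spec_axis(pv, yh, 1, cfg)
  if (!sh$ok || !sv$ok) return(.loc_bad)
  xh <- sh$px_centroid; yv <- sv$px_centroid

  x <- (3 * xv + xh + yh - yv) / 4
  y <- (3 * yh + yv + xv - xh) / 4
  dl <- (abs(xh - xv) + abs(yv - yh)) / 2
  avg <- .avg_profiles(
    cfg$lambda_ref_nm + (sh$pixel - x) * cfg$dispersion_nm_per_px, sh$counts,
    cfg$lambda_ref_nm + (sv$pixel - y) * cfg$dispersion_nm_per_px, sv$counts)
  lc <- if (is.null(avg)) NA_real_ else
    .profile_centroid(avg$counts, avg$lam, cfg$spectral_band_nm)
  out <- c(x_px = x, y_px = y, lambda_c_nm = lc, delta_lambda_px = dl,
           fwhm_a_nm = fit_h$fwhm * cfg$pixel_size_nm,
           fwhm_b_nm = fit_v$fwhm * cfg$pixel_size_nm,
           mixed_sign = as.numeric(sign(xh - xv) * sign(yv - yh) < 0),
           valid = as.numeric(is.finite(lc)))
  if (keep_profile) attr(out, "profile") <- avg
  out
}

# symmetric-dispersion localizer kernel
.loc_sd <- function(imgs, cfg, keep_profile = FALSE) {
  fit_a <- fit_gaussian_1d(rowSums(imgs$A))
  fit_b <- fit_gaussian_1d(rowSums(imgs$B))
  if (!fit_a$ok || !fit_b$ok) return(.loc_bad)
  y <- (fit_a$center + fit_b$center) / 2

  pa <- .channel_profiles(imgs$A, TRUE, fit_a$center,
                          row_halfwidth_px(fit_a$sigma))$spec
  pb <- .channel_profiles(imgs$B, TRUE, fit_b$center,
                          row_halfwidth_px(fit_b$sigma))$spec
  sm <- function(v) as.numeric(stats::filter(v, rep(1 / 3, 3), sides = 2))
  anchor <- (which.max(sm(pa)) + which.max(sm(pb))) / 2 - 1
  sa <- .spec_axis(pa, anchor, 1, cfg)
  sb <- .spec_axis(pb, anchor, -1, cfg)
  if (!sa$ok || !sb$ok) return(.loc_bad)
  x <- (sa$px_centroid + sb$px_centroid) / 2
  dl <- (sa$px_centroid - sb$px_centroid) / 2

  avg <- .avg_profiles(
    cfg$lambda_ref_nm + (sa$pixel - x) * cfg$dispersion_nm_per_px, sa$counts,
    cfg$lambda_ref_nm - (sb$pixel - x) * cfg$dispersion_nm_per_px, sb$counts)
  lc <- if (is.null(avg)) NA_real_ else
    .profile_centroid(avg$counts, avg$lam, cfg$spectral_band_nm)
  out <- c(x_px = x, y_px = y, lambda_c_nm = lc, delta_lambda_px = dl,
           fwhm_a_nm = fit_a$fwhm * cfg$pixel_size_nm,
           fwhm_b_nm = fit_b$fwhm * cfg$pixel_size_nm,
           mixed_sign = NA_real_, valid = as.numeric(is.finite(lc)))
  if (keep_profile) attr(out, "profile") <- avg
  out
}

# conventional sSMLM localizer kernel
.loc_ssmlm <- function(imgs, cfg, keep_profile = FALSE) {
  fit_x <- fit_gaussian_1d(colSums(imgs$A))
  fit_y <- fit_gaussian_1d(rowSums(imgs$A))
  fit_b <- fit_gaussian_1d(rowSums(imgs$B))
  if (!fit_x$ok || !fit_y$ok || !fit_b$ok) return(.loc_bad)

  pb <- .channel_profiles(imgs$B, TRUE, fit_b$center,
                          row_halfwidth_px(fit_b$sigma))$spec
  sb <- .spec_axis(pb, fit_x$center, 1, cfg)
  if (!sb$ok) return(.loc_bad)
  out <- c(x_px = fit_x$center, y_px = fit_y$center, lambda_c_nm = sb$lambda_c,
           delta_lambda_px = sb$px_centroid - fit_x$center,
           fwhm_a_nm = (fit_x$fwhm + fit_y$fwhm) / 2 * cfg$pixel_size_nm,
           fwhm_b_nm = fit_b$fwhm * cfg$pixel_size_nm,
           mixed_sign = NA_real_, valid = 1)
  if (keep_profile) attr(out, "profile") <-
    list(lam = cfg$lambda_ref_nm +
           (sb$pixel - fit_x$center) * cfg$dispersion_nm_per_px,
         counts = sb$counts)
  out
}

.loc_kernel <- function(method) {
  switch(method, od = .loc_od, sd = .loc_sd, ssmlm = .loc_ssmlm)
}
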