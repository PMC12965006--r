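row_halfwidth_px <- function(sigma_px) 3.5 * sigma_px

# wrap a kernel profile (list lam/counts) as a spectral_profile tibble
wrap_profile <- function(p) {
  if (is.null(p)) return(NULL)
  spectral_profile(seq_along(p$lam) - 1L, p$counts, p$lam)
}

#' Measure the four raw coordinates of an orthogonally dispersed frame
#'
#' For the horizontally dispersed channel the image is integrated along the
#' dispersion direction and the resulting profile fitted with a 1D Gaussian,
#' giving the uncorrupted coordinate `yh` and its FWHM; the spectral signal
#' is then integrated over a band of +/- 3.5 fitted sigma around `yh`,
#' background-subtracted, and its centroid along the dispersion axis gives
#' `xh`, which carries the emitter position plus the spectral offset. The
#' vertically dispersed channel yields `xv` (clean) and `yv` (spectrally
#' offset) symmetrically. Each channel's centroid window is anchored at the
#' other channel's clean coordinate, so no ground truth enters the
#' measurement.
#'
#' @param frame A `frame_set` with `method == "od"`.
#' @param config An [optical_config()].
#' @param registration Optional channel registration (see
#'   [estimate_channel_registration()]) mapping channel B coordinates into
#'   channel A's frame; `NULL` means the channels are already registered.
#' @return One-row tibble: `xh`, `yh`, `xv`, `yv` (pixels), `fwhm_h_nm`,
#'   `fwhm_v_nm`, `ok`, and list-columns `profile_h`, `profile_v` holding the
#'   background-subtracted spectral profiles (wavelengths anchored at the
#'   clean coordinates).
#' @export
measure_channels <- function(frame, config = frame$config, registration = NULL) {
  stopifnot(inherits(frame, "frame_set"))
  if (frame$method != "od")
    stop("measure_channels() expects the orthogonal-dispersion geometry", call. = FALSE)
  imgA <- frame$images$A - config$baseline
  imgB <- frame$images$B - config$baseline
  bad <- tibble::tibble(xh = NA_real_, yh = NA_real_, xv = NA_real_,
                        yv = NA_real_, fwhm_h_nm = NA_real_,
                        fwhm_v_nm = NA_real_, ok = FALSE,
                        profile_h = list(NULL), profile_v = list(NULL))

  fit_h <- fit_gaussian_1d(rowSums(imgA))
  fit_v <- fit_gaussian_1d(colSums(imgB))
  if (!fit_h$ok || !fit_v$ok) return(bad)
  yh <- fit_h$center
  xv <- fit_v$center
  yv_raw <- NULL
  if (!is.null(registration)) {
    # map the B-channel clean coordinate into the A frame before combining
    mapped <- apply_channel_registration(cbind(xv, yh), registration)
    xv <- mapped[1]
  }

  ph <- .channel_profiles(imgA, TRUE, yh, row_halfwidth_px(fit_h$sigma))$spec
  pv <- .channel_profiles(imgB, FALSE, xv, row_halfwidth_px(fit_v$sigma))$spec
  sh <- .spec_axis(ph, xv, 1, config)
  sv <- .spec_axis(pv, yh, 1, config)
  if (!sh$ok || !sv$ok) return(bad)

  tibble::tibble(
    xh = sh$px_centroid, yh = yh, xv = xv, yv = sv$px_centroid,
    fwhm_h_nm = fit_h$fwhm * config$pixel_size_nm,
    fwhm_v_nm = fit_v$fwhm * config$pixel_size_nm,
    ok = TRUE,
    profile_h = list(spectral_profile(sh$pixel, sh$counts,
      config$lambda_ref_nm + (sh$pixel - xv) * config$dispersion_nm_per_px)),
    profile_v = list(spectral_profile(sv$pixel, sv$counts,
      config$lambda_ref_nm + (sv$pixel - yh) * config$dispersion_nm_per_px)))
}

#' Refine the lateral position from the four raw coordinates
#'
#' The spectral offset corrupts `xh` and `yv` by the same amount, so the
#' per-axis offsets `dlx = |xh - xv|` and `dly = |yv - yh|` estimate one
#' common quantity; their average `dl` is the per-molecule spectral shift in
#' pixels. Substituting the averaged offset back into either sign case
#' collapses to a single closed form, used unconditionally:
#' `x = (3 xv + xh + yh - yv) / 4`, `y = (3 yh + yv + xv - xh) / 4`.
#' A common shift applied to (`xh`, `yv`) leaves (`x`, `y`) exactly
#' unchanged — the heterogeneity cancellation at the core of the orthogonal
#' geometry. Mixed-sign quadruples (possible under noise, covered by neither
#' sign case) are flagged in `mixed_sign` and use the same closed form.
#'
#' @param meas One-row tibble from [measure_channels()] (or any list with
#'   `xh`, `yh`, `xv`, `yv` in a common pixel frame). Vectorized.
#' @return Tibble with `x`, `y`, `delta_lambda_px`, `mixed_sign`.
#' @export
refine_position <- function(meas) {
  xh <- meas$xh; yh <- meas$yh; xv <- meas$xv; yv <- meas$yv
  dlx <- abs(xh - xv)
  dly <- abs(yv - yh)
  tibble::tibble(
    x = (3 * xv + xh + yh - yv) / 4,
    y = (3 * yh + yv + xv - xh) / 4,
    delta_lambda_px = (dlx + dly) / 2,
    mixed_sign = sign(xh - xv) * sign(yv - yh) < 0)
}

# kernel result (named numeric vector) -> one-row localization tibble
kernel_to_tibble <- function(k, cfg, calibration, keep_profile) {
  z <- NA_real_
  if (!is.null(calibration) && is.finite(k[["fwhm_a_nm"]]))
    z <- estimate_z(k[["fwhm_a_nm"]], k[["fwhm_b_nm"]], calibration)$z_nm
  out <- tibble::tibble(
    x_px = k[["x_px"]], y_px = k[["y_px"]], z_nm = z,
    lambda_c_nm = k[["lambda_c_nm"]],
    delta_lambda_px = k[["delta_lambda_px"]],
    delta_lambda_nm = k[["delta_lambda_px"]] * cfg$dispersion_nm_per_px,
    fwhm_a_nm = k[["fwhm_a_nm"]], fwhm_b_nm = k[["fwhm_b_nm"]],
    mixed_sign = if (is.na(k[["mixed_sign"]])) NA else k[["mixed_sign"]] > 0,
    valid = isTRUE(k[["valid"]] > 0))
  if (keep_profile) out$profile <- list(wrap_profile(attr(k, "profile")))
  out
}

#' Localize one frame
#'
#' Dispatches to the engine matching the frame's channel geometry:
#' * **od** — [measure_channels()]-style analysis plus the closed-form
#'   refinement; the spectral centroid comes from the two-channel averaged
#'   spectrum (profiles re-anchored at the refined position).
#' * **sd** — the two channels carry mirror-image spectra about the emitter,
#'   so the midpoint of the two spectral centroids recovers the
#'   dispersion-axis position for any spectrum and half their signed
#'   separation maps to the spectral centroid; the non-dispersed coordinate
#'   is the mean of the two 1D Gaussian centers.
#' * **ssmlm** — lateral position from marginal Gaussian fits of the
#'   undispersed zeroth order; the dispersed channel's wavelength axis is
#'   anchored at the *fitted* position, so spatial error propagates into the
#'   centroid as `dx * d`.
#'
#' All engines also report the two channel FWHMs and, given a calibration
#' curve, the biplane axial estimate.
#'
#' @param frame A `frame_set`.
#' @param config An [optical_config()].
#' @param calibration Optional [build_calibration()] result.
#' @param keep_profile Attach the analyzed spectral profile as a `profile`
#'   list-column.
#' @param registration Optional channel registration (od only).
#' @return One-row localization tibble: `x_px`, `y_px`, `z_nm`,
#'   `lambda_c_nm`, `delta_lambda_px`, `delta_lambda_nm`, `fwhm_a_nm`,
#'   `fwhm_b_nm`, `mixed_sign`, `valid` (+ `profile`).
#' @export
localize_frame <- function(frame, config = frame$config, calibration = NULL,
                           keep_profile = FALSE, registration = NULL) {
  stopifnot(inherits(frame, "frame_set"))
  imgs <- lapply(frame$images, function(m) m - config$baseline)
  if (!is.null(registration) && frame$method == "od") {
    loc <- localize_od_registered(frame, config, calibration, keep_profile,
                                  registration)
    return(loc)
  }
  k <- .loc_kernel(frame$method)(imgs, config, keep_profile)
  kernel_to_tibble(k, config, calibration, keep_profile)
}

# registration-aware od path built on measure_channels()
localize_od_registered <- function(frame, config, calibration, keep_profile,
                                   registration) {
  meas <- measure_channels(frame, config, registration)
  if (!meas$ok) {
    out <- kernel_to_tibble(.loc_bad, config, NULL, keep_profile)
    return(out)
  }
  ref <- refine_position(meas)
  ph <- meas$profile_h[[1]]
  pv <- meas$profile_v[[1]]
  ph$wavelength_nm <- config$lambda_ref_nm +
    (ph$pixel - ref$x) * config$dispersion_nm_per_px
  pv$wavelength_nm <- config$lambda_ref_nm +
    (pv$pixel - ref$y) * config$dispersion_nm_per_px
  avg <- average_spectra(ph, pv)
  lambda_c <- tryCatch(spectral_centroid(avg, config$spectral_band_nm),
                       error = function(e) NA_real_)
  z <- if (is.null(calibration)) NA_real_ else
    estimate_z(meas$fwhm_h_nm, meas$fwhm_v_nm, calibration)$z_nm
  out <- tibble::tibble(
    x_px = ref$x, y_px = ref$y, z_nm = z, lambda_c_nm = lambda_c,
    delta_lambda_px = ref$delta_lambda_px,
    delta_lambda_nm = ref$delta_lambda_px * config$dispersion_nm_per_px,
    fwhm_a_nm = meas$fwhm_h_nm, fwhm_b_nm = meas$fwhm_v_nm,
    mixed_sign = ref$mixed_sign, valid = is.finite(lambda_c))
  if (keep_profile) out$profile <- list(avg)
  out
}

#' @rdname localize_frame
#' @export
localize_od <- function(frame, config = frame$config, calibration = NULL,
                        keep_profile = FALSE, registration = NULL) {
  if (frame$method != "od")
    stop("localize_od() expects the orthogonal-dispersion geometry", call. = FALSE)
  localize_frame(frame, config, calibration, keep_profile, registration)
}

#' @rdname localize_frame
#' @export
localize_sdsmlm <- function(frame, config = frame$config, calibration = NULL,
                            keep_profile = FALSE) {
  if (frame$method != "sd")
    stop("localize_sdsmlm() expects the symmetric-dispersion geometry", call. = FALSE)
  localize_frame(frame, config, calibration, keep_profile)
}

#' @rdname localize_frame
#' @export
localize_ssmlm <- function(frame, config = frame$config, calibration = NULL,
                           keep_profile = FALSE) {
  if (frame$method != "ssmlm")
    stop("localize_ssmlm() expects the conventional sSMLM geometry", call. = FALSE)
  localize_frame(frame, config, calibration, keep_profile)
}

#' Similarity registration between the two channels
#'
#' Estimates the shift + isotropic scale + rotation mapping channel B
#' fiducial coordinates onto channel A (least squares over matched points,
#' e.g. multicolor beads imaged in both channels). The full
#' misalignment-calibration workflow of a real instrument is out of scope;
#' this provides the plumbing needed to bring both channels into one frame
#' before the coordinates are combined.
#'
#' @param ref_xy,mov_xy n x 2 matrices of matched fiducial coordinates
#'   (reference = channel A, moving = channel B).
#' @return A `channel_registration` list with `rotation` (2 x 2), `scale`,
#'   `translation` (length 2).
#' @export
estimate_channel_registration <- function(ref_xy, mov_xy) {
  ref_xy <- as.matrix(ref_xy); mov_xy <- as.matrix(mov_xy)
  stopifnot(ncol(ref_xy) == 2, all(dim(ref_xy) == dim(mov_xy)), nrow(ref_xy) >= 2)
  mr <- colMeans(ref_xy); mm <- colMeans(mov_xy)
  A <- sweep(ref_xy, 2, mr); B <- sweep(mov_xy, 2, mm)
  sv <- svd(crossprod(A, B))
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
  s <- sum(diag(c(1, d)) %*% diag(sv$d)) / sum(B^2)
  t_vec <- mr - s * as.vector(R %*% mm)
  structure(list(rotation = R, scale = s, translation = t_vec),
            class = "channel_registration")
}

#' @rdname estimate_channel_registration
#' @param xy n x 2 matrix of channel B coordinates to map into channel A.
#' @param registration A `channel_registration`.
#' @export
apply_channel_registration <- function(xy, registration) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  out <- registration$scale * xy %*% t(registration$rotation)
  sweep(out, 2, registration$translation, "+")
}
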