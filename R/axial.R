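#' Build the biplane FWHM calibration curve
#'
#' Simulates a noiseless in-ROI emitter at each depth of `z_grid`, measures
#' the non-dispersion-axis Gaussian FWHM in both channels exactly as the
#' localizers do (so pixelation enters the calibration the same way it enters
#' the measurements), and stores the two FWHM-vs-z curves. Because the two
#' channels focus at different planes, the pair (FWHM_A, FWHM_B) is
#' single-valued in z over the calibration range and encodes the axial
#' position.
#'
#' @param config An [optical_config()].
#' @param z_grid_nm Depth samples (nm); default -500..500 in 25 nm steps,
#'   the range over which the curve pair stays axially resolvable.
#' @param spectrum Emission spectrum of the calibration emitter (bead-like
#'   broadband default: the AF647-like dye).
#' @return A `calibration_curve`: tibble with `z_nm`, `fwhm_h_nm`,
#'   `fwhm_v_nm`; attributes `config_hash` and `z_range`.
#' @export
build_calibration <- function(config, z_grid_nm = seq(-500, 500, by = 25),
                              spectrum = make_dye_spectrum("AF647")) {
  validate_optical_config(config)
  if (min(z_grid_nm) < -500 || max(z_grid_nm) > 500)
    stop("calibration grid must stay within -500..500 nm", call. = FALSE)
  mid <- (config$roi_px - 1) / 2 * config$pixel_size_nm
  rows <- lapply(z_grid_nm, function(z) {
    fr <- simulate_frame(
      tibble::tibble(x_nm = mid, y_nm = mid, z_nm = z, dye = "cal",
                     n_signal = 1e5, n_background = 0),
      method = "od", spectra = list(cal = spectrum), config = config,
      noise = FALSE)
    fit_h <- integrate_and_fit(fr$images$A, "non_dispersion", "x")
    fit_v <- integrate_and_fit(fr$images$B, "non_dispersion", "y")
    if (!fit_h$ok || !fit_v$ok)
      stop("calibration fit failed at z = ", z, " nm", call. = FALSE)
    c(fwhm_h = fit_h$fwhm * config$pixel_size_nm,
      fwhm_v = fit_v$fwhm * config$pixel_size_nm)
  })
  fw <- do.call(rbind, rows)
  out <- tibble::tibble(z_nm = z_grid_nm, fwhm_h_nm = fw[, "fwhm_h"],
                        fwhm_v_nm = fw[, "fwhm_v"])
  # the usable encoding is the difference branch; it must be monotone
  if (any(diff(out$fwhm_h_nm - out$fwhm_v_nm) *
          sign(config$plane_offset_v_nm - config$plane_offset_h_nm) < 0))
    stop("calibration is not axially resolvable on this grid ",
         "(non-monotone FWHM difference)", call. = FALSE)
  attr(out, "config_hash") <- config_hash(config)
  attr(out, "z_range") <- range(z_grid_nm)
  class(out) <- c("calibration_curve", class(out))
  out
}

#' Estimate axial position from a biplane FWHM pair
#'
#' Matches a measured FWHM pair against the calibration curves by minimizing
#' `(sqrt(Fh) - sqrt(Fh_cal(z)))^2 + (sqrt(Fv) - sqrt(Fv_cal(z)))^2` over a
#' densely interpolated z grid, then refines the minimum with a local
#' quadratic fit. The square-root metric equalizes the weight of the focused
#' (narrow, well-determined) and defocused (wide) channels. Queries whose
#' cost minimum sits at the grid boundary are flagged invalid rather than
#' extrapolated.
#'
#' @param fwhm_h_nm,fwhm_v_nm Measured FWHMs (nm); vectorized.
#' @param calibration A [build_calibration()] result.
#' @param step_nm Interpolation step of the dense search grid.
#' @return Tibble with `z_nm` (NA when invalid) and `valid`.
#' @export
estimate_z <- function(fwhm_h_nm, fwhm_v_nm, calibration, step_nm = 1) {
  stopifnot(inherits(calibration, "calibration_curve"),
            length(fwhm_h_nm) == length(fwhm_v_nm))
  zr <- attr(calibration, "z_range")
  zz <- seq(zr[1], zr[2], by = step_nm)
  sh <- stats::spline(calibration$z_nm, sqrt(calibration$fwhm_h_nm), xout = zz)$y
  sv <- stats::spline(calibration$z_nm, sqrt(calibration$fwhm_v_nm), xout = zz)$y

  n <- length(fwhm_h_nm)
  z_out <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!is.finite(fwhm_h_nm[i]) || !is.finite(fwhm_v_nm[i])) next
    cost <- (sqrt(fwhm_h_nm[i]) - sh)^2 + (sqrt(fwhm_v_nm[i]) - sv)^2
    k <- which.min(cost)
    if (k == 1 || k == length(zz)) next
    # quadratic refinement through the minimum and its neighbors
    c0 <- cost[k - 1]; c1 <- cost[k]; c2 <- cost[k + 1]
    denom <- c0 - 2 * c1 + c2
    delta <- if (denom > 0) 0.5 * (c0 - c2) / denom else 0
    z_out[i] <- zz[k] + delta * step_nm
    valid[i] <- TRUE
  }
  tibble::tibble(z_nm = z_out, valid = valid)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %d depths over %g..%g nm (config %s)\n",
              nrow(x), attr(x, "z_range")[1], attr(x, "z_range")[2],
              attr(x, "config_hash")))
  NextMethod()
}
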