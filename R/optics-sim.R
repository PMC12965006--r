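#' Defocused PSF width
#'
#' Gaussian PSF standard deviation at defocus `z`, following the Lorentzian
#' beam-waist law \eqn{\sigma(z) = \sigma_0\sqrt{1+(z/z_R)^2}}. This captures
#' the monotone FWHM-vs-defocus behavior that biplane axial calibration
#' relies on, while remaining analytically checkable.
#'
#' @param z_nm Defocus (nm), relative to the channel's focal plane; vector ok.
#' @param config An [optical_config()].
#' @return PSF standard deviation(s) in nm.
#' @examples
#' cfg <- optical_config()
#' psf_sigma(0, cfg)                       # in focus: sigma0
#' psf_sigma(cfg$psf_depth_scale_nm, cfg)  # sigma0 * sqrt(2)
#' @export
psf_sigma <- function(z_nm, config) {
  validate_optical_config(config)
  config$psf_sigma0_nm * sqrt(1 + (z_nm / config$psf_depth_scale_nm)^2)
}

# Pixel-integrated Gaussian line profile at pixel centers 0..n-1.
# mu, sigma in pixel units; returns the fraction of a unit Gaussian falling
# into each pixel (sums to ~1 when the Gaussian is well inside the ROI).
gauss_pixel_profile <- function(n, mu, sigma) {
  edges <- seq(-0.5, n - 0.5, by = 1)
  diff(stats::pnorm(edges, mean = mu, sd = sigma))
}

#' Expected dispersed image of a single emitter
#'
#' Forward model for one detection channel: the emitter's emission spectrum is
#' mapped to a line of displaced PSFs along the dispersion axis (linear
#' wavelength-to-pixel mapping, `dispersion_sign` selects the spectral order
#' direction) and convolved with the defocused Gaussian PSF of that channel's
#' focal plane. Because the PSF is separable the image is the outer product of
#' a dispersed profile along the dispersion axis and a plain Gaussian profile
#' along the other axis. Expected photons are conserved up to truncation at
#' the ROI border; more than 1% loss raises a truncation warning.
#'
#' @param x_px,y_px Emitter position in ROI pixel coordinates (pixel centers
#'   at integers, origin at the ROI corner).
#' @param z_nm Emitter axial position (nm).
#' @param n_photons Expected signal photons in this channel.
#' @param spectrum An `emission_spectrum` ([make_dye_spectrum()]); `NULL`
#'   gives an undispersed (zeroth-order) PSF.
#' @param axis Dispersion axis: `"x"` (horizontal) or `"y"` (vertical).
#' @param dispersion_sign `+1` or `-1`: direction of increasing wavelength
#'   along the axis (the mirrored order of symmetric dispersion uses `-1`).
#' @param plane_offset_nm Focal-plane offset of this channel (nm).
#' @param config An [optical_config()].
#' @param warn_truncation Warn when > 1% of the photons fall outside the ROI.
#' @return `roi_px` x `roi_px` matrix of expected photon counts
#'   (rows = y, columns = x), with a `captured_fraction` attribute.
#' @export
disperse <- function(x_px, y_px, z_nm, n_photons, spectrum, axis = c("x", "y"),
                     dispersion_sign = 1, plane_offset_nm = 0, config,
                     warn_truncation = TRUE) {
  axis <- match.arg(axis)
  n <- config$roi_px
  sigma_px <- psf_sigma(z_nm - plane_offset_nm, config) / config$pixel_size_nm

  along <- if (axis == "x") x_px else y_px
  across <- if (axis == "x") y_px else x_px

  if (is.null(spectrum)) {
    p_along <- gauss_pixel_profile(n, along, sigma_px)
  } else {
    lam <- spectrum$wavelength_nm
    step <- c(diff(lam), diff(lam)[length(lam) - 1])
    w <- spectrum$intensity * step
    w <- w / sum(w)
    centers <- along + dispersion_sign * (lam - config$lambda_ref_nm) /
      config$dispersion_nm_per_px
    edges <- seq(-0.5, n - 0.5, by = 1)
    # (n+1) x L cumulative Gaussian table -> per-pixel mass per wavelength
    cum <- stats::pnorm(outer(edges, centers, "-") / sigma_px)
    p_along <- as.vector((cum[-1, , drop = FALSE] -
                            cum[-(n + 1), , drop = FALSE]) %*% w)
  }
  p_across <- gauss_pixel_profile(n, across, sigma_px)

  img <- n_photons * (p_across %o% p_along)
  if (axis == "y") img <- t(img)
  captured <- sum(img) / n_photons
  attr(img, "captured_fraction") <- captured
  if (warn_truncation && captured < 0.99)
    warning(sprintf("dispersed image truncated at ROI border (%.1f%% captured)",
                    100 * captured), call. = FALSE)
  img
}

#' Apply the camera noise model to an expected-photon image
#'
#' Per-pixel Poisson shot noise on (expected signal + uniform background),
#' then additive Gaussian read noise, then the camera baseline. Unit gain
#' (1 count per photo-electron) is assumed. The same seed reproduces the
#' image bit-for-bit.
#'
#' @param image Matrix of expected photons (>= 0).
#' @param config An [optical_config()].
#' @param seed Integer seed for this draw; `NULL` uses the current RNG state.
#' @param background_per_px Expected background photons per pixel.
#' @return Noisy image matrix (counts, baseline included).
#' @export
add_camera_noise <- function(image, config, seed = NULL, background_per_px = 0) {
  if (any(image < 0)) stop("expected-photon image has negative values", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lam <- image + background_per_px
  noisy <- stats::rpois(length(lam), lam) +
    stats::rnorm(length(lam), 0, config$read_noise_e) + config$baseline
  matrix(noisy, nrow = nrow(image))
}

# Per-channel geometry for the three methods. Channel A / B entries give the
# dispersion axis (NA = undispersed zeroth order), the spectral-order sign,
# the focal-plane offset and the share of the photon budget.
method_geometry <- function(method, config) {
  switch(method,
    od = list(
      A = list(axis = "x", sign = 1, plane = config$plane_offset_h_nm,
               share = config$split_ratio),
      B = list(axis = "y", sign = 1, plane = config$plane_offset_v_nm,
               share = 1 - config$split_ratio)),
    sd = list(
      A = list(axis = "x", sign = 1, plane = config$plane_offset_h_nm,
               share = config$split_ratio),
      B = list(axis = "x", sign = -1, plane = config$plane_offset_v_nm,
               share = 1 - config$split_ratio)),
    ssmlm = list(
      A = list(axis = NA_character_, sign = 1, plane = config$plane_offset_h_nm,
               share = config$split_ratio),
      B = list(axis = "x", sign = 1, plane = config$plane_offset_v_nm,
               share = 1 - config$split_ratio)),
    stop("unknown method `", method, "`", call. = FALSE)
  )
}

#' Simulate one camera frame pair
#'
#' Renders every emitter into the two detection channels of the chosen
#' geometry and applies the camera noise model:
#' * `od` — channel A horizontally dispersed at the H focal plane, channel B
#'   vertically dispersed at the V plane; photons split by `split_ratio`
#'   (1:1 by default).
#' * `sd` — both channels dispersed along x with opposite spectral-order
#'   signs (mirror images), 1:1 split, distinct focal planes.
#' * `ssmlm` — channel A is the undispersed zeroth-order PSF receiving
#'   `split_ratio` of the photons (set `split_ratio = 0.25` for the
#'   conventional 1:3 allocation), channel B the dispersed first order.
#'
#' The per-event background budget `n_background` is interpreted as photons
#' over a reference 32 x 32 ROI and converted to a per-pixel rate applied in
#' *each* channel (diffuse sample background fills every camera region), so
#' the background density depends neither on the simulated ROI size nor on
#' the signal split ratio.
#'
#' @param emitters Tibble/data frame with columns `x_nm`, `y_nm`, `z_nm`,
#'   `dye`, `n_signal`, `n_background` (positions in frame coordinates;
#'   pixel centers at integer multiples of `pixel_size_nm`).
#' @param method `"od"`, `"sd"` or `"ssmlm"`.
#' @param spectra Named list of `emission_spectrum`, keyed by dye.
#' @param config An [optical_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param noise Set `FALSE` for the noiseless expected image (no baseline).
#' @return A `frame_set`: list with `method`, `images` (list `A`, `B`),
#'   `geometry`, `config`, `truth`.
#' @export
simulate_frame <- function(emitters, method = c("od", "sd", "ssmlm"), spectra,
                           config, seed = NULL, noise = TRUE) {
  method <- match.arg(method)
  validate_optical_config(config)
  emitters <- tibble::as_tibble(emitters)
  need <- c("x_nm", "y_nm", "z_nm", "dye", "n_signal", "n_background")
  missing_cols <- setdiff(need, names(emitters))
  if (length(missing_cols) > 0)
    stop("emitters lack columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  bad_dye <- setdiff(unique(emitters$dye), names(spectra))
  if (length(bad_dye) > 0)
    stop("no emission spectrum for dye(s): ", paste(bad_dye, collapse = ", "),
         call. = FALSE)

  geom <- method_geometry(method, config)
  n <- config$roi_px
  if (!is.null(seed)) set.seed(seed)

  images <- lapply(geom, function(ch) {
    expected <- matrix(0, n, n)
    bg <- 0
    for (i in seq_len(nrow(emitters))) {
      e <- emitters[i, ]
      spec <- if (is.na(ch$axis)) NULL else spectra[[e$dye]]
      expected <- expected + disperse(
        x_px = e$x_nm / config$pixel_size_nm,
        y_px = e$y_nm / config$pixel_size_nm,
        z_nm = e$z_nm, n_photons = e$n_signal * ch$share,
        spectrum = spec,
        axis = if (is.na(ch$axis)) "x" else ch$axis,
        dispersion_sign = ch$sign, plane_offset_nm = ch$plane,
        config = config, warn_truncation = FALSE)
      bg <- bg + e$n_background / (32 * 32)
    }
    if (noise) add_camera_noise(expected, config, seed = NULL,
                                background_per_px = bg)
    else expected
  })

  structure(list(method = method, images = images, geometry = geom,
                 config = config, truth = emitters),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> method %s, %d x %d px, %d emitter(s)\n",
              x$method, nrow(x$images$A), ncol(x$images$A), nrow(x$truth)))
  invisible(x)
}
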