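# Per-event ROI geometry. The analysis ROI is sized so the dispersed
# spectrum of the configured emission band fits with margins, and the
# emitter's design position inside the ROI mimics how a detection box is
# cropped around a candidate in a real pipeline.
roi_geometry <- function(method, config) {
  span <- ceiling(diff(config$spectral_band_nm) / config$dispersion_nm_per_px)
  margin <- 12L
  switch(method,
    od = {
      roi <- span + 2L * margin
      list(roi_px = roi, x0 = margin, y0 = margin)
    },
    sd = {
      roi <- 2L * span + 2L * margin
      list(roi_px = roi, x0 = span + margin, y0 = roi %/% 2)
    },
    ssmlm = {
      roi <- span + 2L * margin
      list(roi_px = roi, x0 = margin, y0 = roi %/% 2)
    },
    stop("unknown method `", method, "`", call. = FALSE))
}

#' Simulate and localize a stream of blinking events
#'
#' The workhorse behind every benchmark: each event is rendered into its own
#' analysis ROI (the emitter sits at the method's design position plus its
#' true sub-pixel offset, exactly as a detection crop would place it), noise
#' is applied, the method's localizer runs, and the recovered coordinates are
#' mapped back to the global sample frame. Ground-truth columns are carried
#' along for evaluation.
#'
#' @param events Blink-stream tibble ([sample_blinks()] format: `frame`,
#'   `x_nm`, `y_nm`, `z_nm`, `dye`, `n_signal`, `n_background`).
#' @param method `"od"`, `"sd"` or `"ssmlm"`.
#' @param config An [optical_config()]; `roi_px` is overridden by the
#'   method/dispersion-specific ROI and `split_ratio` should already reflect
#'   the method's photon allocation.
#' @param spectra Named list of emission spectra keyed by dye.
#' @param seed RNG seed for the whole stream.
#' @param calibration Optional calibration curve for axial recovery.
#' @param keep_profiles Keep each localization's averaged spectral profile as
#'   a list-column (memory-heavy; off by default).
#' @return Localization tibble: `frame`, `x_nm`, `y_nm`, `z_nm`,
#'   `lambda_c_nm`, `delta_lambda_nm`, `dye` (truth), `n_photons`, `valid`,
#'   plus truth columns `true_x_nm`, `true_y_nm`, `true_z_nm`.
#' @export
localize_events <- function(events, method = c("od", "sd", "ssmlm"), config,
                            spectra, seed = 1, calibration = NULL,
                            keep_profiles = FALSE) {
  method <- match.arg(method)
  validate_optical_config(config)
  bad_dye <- setdiff(unique(events$dye), names(spectra))
  if (length(bad_dye) > 0)
    stop("no emission spectrum for dye(s): ", paste(bad_dye, collapse = ", "),
         call. = FALSE)
  geom <- roi_geometry(method, config)
  cfg <- config
  cfg$roi_px <- geom$roi_px
  kernel <- .loc_kernel(method)
  set.seed(seed)
  n <- nrow(events)
  K <- matrix(NA_real_, n, length(.loc_names),
              dimnames = list(NULL, .loc_names))
  profs <- if (keep_profiles) vector("list", n) else NULL
  px <- cfg$pixel_size_nm
  xg <- events$x_nm / px
  yg <- events$y_nm / px
  fx <- xg - floor(xg)
  fy <- yg - floor(yg)
  for (i in seq_len(n)) {
    imgs <- .sim_event(method, geom$x0 + fx[i], geom$y0 + fy[i],
                       events$z_nm[i], events$n_signal[i],
                       events$n_background[i], spectra[[events$dye[i]]], cfg)
    k <- kernel(imgs, cfg, keep_profiles)
    K[i, ] <- k
    if (keep_profiles) profs[[i]] <- wrap_profile(attr(k, "profile"))
  }
  z <- rep(NA_real_, n)
  if (!is.null(calibration)) {
    zt <- estimate_z(K[, "fwhm_a_nm"], K[, "fwhm_b_nm"], calibration)
    z <- zt$z_nm
  }
  res <- tibble::tibble(
    frame = events$frame %||% seq_len(n),
    x_nm = events$x_nm + (K[, "x_px"] - geom$x0 - fx) * px,
    y_nm = events$y_nm + (K[, "y_px"] - geom$y0 - fy) * px,
    z_nm = z,
    lambda_c_nm = K[, "lambda_c_nm"],
    delta_lambda_nm = K[, "delta_lambda_px"] * cfg$dispersion_nm_per_px,
    dye = events$dye, n_photons = events$n_signal,
    valid = !is.na(K[, "valid"]) & K[, "valid"] > 0,
    true_x_nm = events$x_nm, true_y_nm = events$y_nm, true_z_nm = events$z_nm)
  if (keep_profiles) res$profile <- profs
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-emitter repeat stream at fixed conditions
repeat_events <- function(n_rep, photons, background, z_nm, dye = "AF647",
                          seed = 1) {
  set.seed(seed)
  tibble::tibble(frame = seq_len(n_rep),
                 x_nm = stats::runif(n_rep, 0, 100),
                 y_nm = stats::runif(n_rep, 0, 100),
                 z_nm = z_nm, dye = dye, n_signal = photons,
                 n_background = background)
}

method_config <- function(config, method) {
  config$split_ratio <- if (method == "ssmlm") 0.25 else 0.5
  config
}

#' Localization- and spectral-precision sweeps
#'
#' Repeats single-emitter localizations while sweeping depth, photon budget
#' or spectral dispersion, and reports per-axis localization precision and
#' spectral precision at each point. Conventional sSMLM runs with the 1:3
#' photon allocation (`split_ratio = 0.25`); the symmetric and orthogonal
#' geometries with 1:1.
#'
#' @param config Base [optical_config()].
#' @param vary One of `"depth"`, `"photons"`, `"dispersion"`.
#' @param values Sweep grid (nm for depth, photons, or nm/px).
#' @param methods Methods to compare.
#' @param n_rep Repeats per point.
#' @param photons Total signal photon budget (fixed unless swept).
#' @param background Background photons per event.
#' @param z_nm Depth (fixed unless swept).
#' @param seed RNG seed.
#' @param axial Also build a calibration and report `sigma_z_nm`.
#' @return Tibble: `method`, `vary`, `value`, `sigma_x_nm`, `sigma_y_nm`,
#'   `sigma_z_nm`, `sigma_lambda_nm`, `n_valid`.
#' @export
run_precision_sweep <- function(config = optical_config(),
                                vary = c("depth", "photons", "dispersion"),
                                values, methods = c("od", "sd", "ssmlm"),
                                n_rep = 200, photons = 3000,
                                background = 10000, z_nm = 0, seed = 1,
                                axial = FALSE) {
  vary <- match.arg(vary)
  spectra <- list(AF647 = make_dye_spectrum("AF647"))
  grid <- tidyr::expand_grid(method = methods, value = values)
  purrr::pmap_dfr(grid, function(method, value) {
    cfg <- method_config(config, method)
    p <- photons; z <- z_nm
    if (vary == "dispersion") cfg$dispersion_nm_per_px <- value
    if (vary == "photons") p <- value
    if (vary == "depth") z <- value
    calib <- if (axial) build_calibration(cfg) else NULL
    ev <- repeat_events(n_rep, p, background, z,
                        seed = seed + 17 * round(value) + nchar(method))
    locs <- localize_events(ev, method, cfg, spectra,
                            seed = seed + 31 * round(value) + nchar(method),
                            calibration = calib)
    ok <- locs[locs$valid, ]
    # precision = spread of the residuals (emitter positions are re-drawn per
    # repeat to average over sub-pixel phase)
    tibble::tibble(method = method, vary = vary, value = value,
                   sigma_x_nm = stats::sd(ok$x_nm - ok$true_x_nm),
                   sigma_y_nm = stats::sd(ok$y_nm - ok$true_y_nm),
                   sigma_z_nm = if (axial)
                     stats::sd((ok$z_nm - ok$true_z_nm)[is.finite(ok$z_nm)])
                   else NA_real_,
                   sigma_lambda_nm = stats::sd(ok$lambda_c_nm),
                   n_valid = nrow(ok))
  })
}

#' Dual-dye crosstalk across a dispersion sweep
#'
#' Simulates blinking events of two spectrally adjacent dyes at each
#' dispersion, classifies every localization by its spectral centroid
#' (threshold at the midpoint of the two dye centroid means), and reports
#' the misclassified percentage per method and dispersion.
#'
#' @param config Base [optical_config()].
#' @param dispersions Dispersion grid (nm/px).
#' @param methods Methods to compare.
#' @param n_events_per_dye Events per dye per point.
#' @param photons,background Per-event photon budgets.
#' @param photon_cv Lognormal CV of the per-event signal photons.
#' @param seed RNG seed.
#' @return Tibble: `method`, `dispersion_nm_per_px`, `crosstalk_pct`,
#'   `threshold_nm`, `n_valid`.
#' @export
run_crosstalk_sweep <- function(config = optical_config(),
                                dispersions = c(2, 4, 6, 8, 10),
                                methods = c("od", "sd", "ssmlm"),
                                n_events_per_dye = 1000, photons = 5000,
                                background = 10000, photon_cv = 0.3,
                                seed = 1) {
  spectra <- list(AF647 = make_dye_spectrum("AF647"),
                  CF660C = make_dye_spectrum("CF660C"))
  grid <- tidyr::expand_grid(method = methods, d = dispersions)
  purrr::pmap_dfr(grid, function(method, d) {
    cfg <- method_config(config, method)
    cfg$dispersion_nm_per_px <- d
    set.seed(seed + round(100 * d) + nchar(method))
    n2 <- 2 * n_events_per_dye
    sdl <- sqrt(log(1 + photon_cv^2))
    sig <- if (photon_cv > 0)
      stats::rlnorm(n2, log(photons) - sdl^2 / 2, sdl) else rep(photons, n2)
    ev <- tibble::tibble(
      frame = seq_len(n2),
      x_nm = stats::runif(n2, 0, 100), y_nm = stats::runif(n2, 0, 100),
      z_nm = 0,
      dye = rep(c("AF647", "CF660C"), each = n_events_per_dye),
      n_signal = sig, n_background = background)
    locs <- localize_events(ev, method, cfg, spectra,
                            seed = seed + round(10 * d) + nchar(method))
    ok <- locs[locs$valid & is.finite(locs$lambda_c_nm), ]
    mu <- tapply(ok$lambda_c_nm, ok$dye, mean)
    thr <- mean(mu)
    labels <- classify_by_centroid(ok$lambda_c_nm, thr)
    truth <- as.integer(ok$dye == "CF660C")
    tibble::tibble(method = method, dispersion_nm_per_px = d,
                   crosstalk_pct = crosstalk(labels, truth),
                   threshold_nm = thr, n_valid = nrow(ok))
  })
}

#' Dual-color phantom: localization, classification, FRC
#'
#' Builds the dual-color phantom (microtubule-like filaments labeled with
#' the AF647-like dye, punctate blob shells with the CF660C-like dye),
#' samples a blinking-event stream at the configured photon budget, runs the
#' requested localization engines over the same events, and computes the FRC
#' resolution of each reconstruction.
#'
#' @param config Base [optical_config()].
#' @param methods Methods to benchmark.
#' @param n_filaments,n_blobs Phantom composition.
#' @param fov_nm Field of view (nm).
#' @param frames,sparsity Blinking stream length and mean events/frame.
#' @param photons,background,photon_cv Per-event photon budget model.
#' @param render_pixel_nm FRC rendering pixel.
#' @param seed RNG seed.
#' @return List with `events`, `localizations` (named by method), and
#'   `frc` (tibble `method`, `frc_nm`, `crossed`, `n_locs`).
#' @export
run_frc_benchmark <- function(config = optical_config(), methods = c("od", "sd"),
                              n_filaments = 4, n_blobs = 8, fov_nm = 5000,
                              frames = 3500, sparsity = 4, photons = 5000,
                              background = 10000, photon_cv = 0.3,
                              render_pixel_nm = 10, seed = 1) {
  fil <- make_filaments(n_filaments, fov_nm = fov_nm, seed = seed)
  # denser blob site grid keeps the two colors' event counts comparable
  blb <- make_blobs(n_blobs, fov_nm = fov_nm, seed = seed + 1,
                    spacing_nm = 2.5)
  sites <- dplyr::bind_rows(fil, blb)
  ev <- sample_blinks(sites, frames = frames, mean_signal = photons,
                      mean_background = background, sparsity = sparsity,
                      seed = seed + 2, photon_cv = photon_cv)
  spectra <- list(AF647 = make_dye_spectrum("AF647"),
                  CF660C = make_dye_spectrum("CF660C"))
  locs <- lapply(stats::setNames(methods, methods), function(m) {
    localize_events(ev, m, method_config(config, m), spectra,
                    seed = seed + 3 + nchar(m))
  })
  frc <- purrr::imap_dfr(locs, function(lc, m) {
    ok <- lc[lc$valid, ]
    r <- frc_resolution(ok, render_pixel_nm = render_pixel_nm, seed = seed + 5)
    tibble::tibble(method = m, frc_nm = r$resolution_nm, crossed = r$crossed,
                   n_locs = nrow(ok))
  })
  list(events = ev, localizations = locs, frc = frc)
}

#' Line-profile resolution across a reconstructed straight filament
#'
#' Samples dense blinking events on a single straight filament, localizes
#' them with the requested engine, renders the reconstruction, and fits a
#' Gaussian to the intensity profile across the filament (averaged along a
#' central section).
#'
#' @param config Base [optical_config()] (set `dispersion_nm_per_px`
#'   beforehand to benchmark a specific dispersion).
#' @param method Localization engine.
#' @param n_events Number of blinking events on the filament.
#' @param photons,background,photon_cv Photon budget model.
#' @param render_pixel_nm Rendering pixel (nm).
#' @param profile_len_nm Length of the averaged filament section.
#' @param seed RNG seed.
#' @return One-row tibble: `method`, `fwhm_nm`, `n_locs`.
#' @export
run_line_profile_benchmark <- function(config = optical_config(),
                                       method = "od", n_events = 3000,
                                       photons = 5000, background = 10000,
                                       photon_cv = 0.3, render_pixel_nm = 5,
                                       profile_len_nm = 1000, seed = 1) {
  fov <- 3000
  sites <- make_straight_filament(fov_nm = fov)
  ev <- sample_blinks(sites, frames = n_events, mean_signal = photons,
                      mean_background = background, sparsity = 1,
                      seed = seed, photon_cv = photon_cv)
  spectra <- list(AF647 = make_dye_spectrum("AF647"))
  locs <- localize_events(ev, method, method_config(config, method), spectra,
                          seed = seed + 1)
  ok <- locs[locs$valid, ]
  # render a band around the filament and profile across it
  ext <- c(fov / 2 - profile_len_nm / 2, fov / 2 + profile_len_nm / 2,
           fov / 2 - 200, fov / 2 + 200)
  img <- render(ok, render_pixel_nm, "histogram", extent_nm = ext)
  prof <- line_profile_fwhm(
    img,
    p0_nm = c(fov / 2, ext[3]), p1_nm = c(fov / 2, ext[4]),
    width_px = round(profile_len_nm / render_pixel_nm))
  tibble::tibble(method = method, fwhm_nm = prof$fwhm_nm, n_locs = nrow(ok))
}
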