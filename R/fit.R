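#' Fit a 1D Gaussian with offset to a profile
#'
#' Damped Gauss-Newton least squares for the model
#' `a * exp(-(t - mu)^2 / (2 sigma^2)) + c`, initialized from moments.
#' This is the workhorse behind every non-dispersion-axis position estimate
#' and behind the FWHM measurements that feed biplane axial localization, so
#' it is implemented as a tight fixed-size solver (4 parameters, analytic
#' Jacobian) rather than through a general optimizer: a localization run
#' performs it tens of thousands of times.
#'
#' Convergence: relative parameter change below `tol` (default 1e-8), at most
#' `max_iter` iterations. A fit is rejected (`ok = FALSE`) when it fails to
#' produce a finite positive width, when the center leaves the profile
#' support, when the fitted width falls outside `sigma_bounds` (a
#' sub-sample-spacing spike or a ridge wider than the support is never a
#' real single-emitter profile), or when the fitted amplitude does not
#' exceed `min_snr` times the residual noise level (flat or signal-free
#' profiles).
#'
#' @param y Profile values.
#' @param t Positions (defaults to `0:(length(y)-1)`, pixel centers).
#' @param tol Convergence tolerance on the relative parameter step.
#' @param max_iter Maximum iterations.
#' @param min_snr Amplitude / residual-sd rejection threshold.
#' @param sigma_bounds Plausible width range in units of the sample spacing.
#' @return List with `center`, `sigma`, `fwhm` (= 2.3548 sigma), `amplitude`,
#'   `offset`, `ok`, `iterations`.
#' @export
fit_gaussian_1d <- function(y, t = seq_along(y) - 1, tol = 1e-8,
                            max_iter = 100, min_snr = 3,
                            sigma_bounds = c(0.5, length(y) / 3)) {
  stopifnot(length(y) == length(t), length(y) >= 5)
  reject <- list(center = NA_real_, sigma = NA_real_, fwhm = NA_real_,
                 amplitude = NA_real_, offset = NA_real_, ok = FALSE,
                 iterations = 0L)

  # peak-localized moment start values: smooth, take the highest bump, and
  # estimate width from the mass in a window around it (a global moment init
  # degenerates on long background-dominated profiles)
  spacing0 <- stats::median(diff(t))
  ks <- min(5L, length(y))
  sm <- stats::filter(y, rep(1 / ks, ks), sides = 2)
  sm[is.na(sm)] <- y[is.na(sm)]
  c0 <- stats::median(sm)
  pk <- which.max(sm)
  a0 <- max(y[pk] - c0, sm[pk] - c0)
  if (!is.finite(a0) || a0 <= 0) return(reject)
  win <- abs(t - t[pk]) <= 6 * spacing0
  w <- pmax(y[win] - c0, 0)
  if (sum(w) <= 0) return(reject)
  mu0 <- sum(w * t[win]) / sum(w)
  s0 <- sqrt(sum(w * (t[win] - mu0)^2) / sum(w))
  if (!is.finite(s0) || s0 <= 0) s0 <- spacing0
  s0 <- min(max(s0, spacing0), 5 * spacing0)
  theta <- c(a0, mu0, s0, c0)

  lambda <- 1e-3
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    a <- theta[1]; mu <- theta[2]; s <- theta[3]; cc <- theta[4]
    u <- (t - mu) / s
    e <- exp(-u^2 / 2)
    r <- y - (a * e + cc)
    J <- cbind(e, a * e * u / s, a * e * u^2 / s, 1)
    JTJ <- crossprod(J)
    g <- crossprod(J, r)
    step <- tryCatch(
      solve(JTJ + lambda * diag(diag(JTJ) + 1e-12), g),
      error = function(err) NULL)
    if (is.null(step)) {
      lambda <- lambda * 10
      if (lambda > 1e8) return(reject)
      next
    }
    theta_new <- theta + as.vector(step)
    # keep width positive; dampen on divergence
    if (!is.finite(theta_new[3]) || theta_new[3] <= 0) {
      lambda <- lambda * 10
      if (lambda > 1e8) return(reject)
      next
    }
    u2 <- (t - theta_new[2]) / theta_new[3]
    r_new <- y - (theta_new[1] * exp(-u2^2 / 2) + theta_new[4])
    if (sum(r_new^2) <= sum(r^2)) {
      rel <- max(abs(theta_new - theta) / (abs(theta) + 1e-12))
      theta <- theta_new
      lambda <- max(lambda / 5, 1e-12)
      if (rel < tol) break
    } else {
      lambda <- lambda * 10
      if (lambda > 1e8) break
    }
  }

  a <- theta[1]; mu <- theta[2]; s <- abs(theta[3]); cc <- theta[4]
  res_sd <- stats::sd(y - (a * exp(-((t - mu) / s)^2 / 2) + cc))
  spacing <- stats::median(diff(t))
  ok <- is.finite(mu) && is.finite(s) && s > 0 &&
    s >= sigma_bounds[1] * spacing && s <= sigma_bounds[2] * spacing &&
    mu >= min(t) && mu <= max(t) &&
    is.finite(a) && a > 0 && (res_sd == 0 || a > min_snr * res_sd)
  if (!ok) return(modifyList(reject, list(iterations = iter)))
  list(center = mu, sigma = s, fwhm = 2 * sqrt(2 * log(2)) * s,
       amplitude = a, offset = cc, ok = TRUE, iterations = iter)
}

#' Integrate a channel image and fit / extract a 1D profile
#'
#' Collapses a single-emitter channel image to a 1D profile and analyzes it:
#' * `axis = "non_dispersion"` — sums across the dispersion axis and fits a
#'   1D Gaussian, returning the center and FWHM; this is the coordinate the
#'   dispersion cannot corrupt.
#' * `axis = "dispersion"` — sums across the non-dispersion axis (restricted
#'   to a band of rows around `row_center` when given, which keeps the
#'   out-of-band background from entering the spectral profile) and returns
#'   the raw [spectral_profile()] in pixel coordinates (no wavelength
#'   assignment yet).
#'
#' @param image Channel image matrix (rows = y, columns = x), baseline
#'   already removed.
#' @param axis `"non_dispersion"` or `"dispersion"`.
#' @param dispersion_axis Which image axis carries the dispersion:
#'   `"x"` or `"y"`.
#' @param row_center,row_halfwidth Optional extraction band (pixels) along
#'   the non-dispersion axis used when `axis = "dispersion"`.
#' @return For `"non_dispersion"`, the [fit_gaussian_1d()] result; for
#'   `"dispersion"`, a `spectral_profile` with `wavelength_nm = NA`.
#' @export
integrate_and_fit <- function(image, axis = c("non_dispersion", "dispersion"),
                              dispersion_axis = c("x", "y"),
                              row_center = NULL, row_halfwidth = NULL) {
  axis <- match.arg(axis)
  dispersion_axis <- match.arg(dispersion_axis)
  # orient so dispersion runs along columns
  if (dispersion_axis == "y") image <- t(image)

  if (axis == "non_dispersion") {
    prof <- rowSums(image)
    return(fit_gaussian_1d(prof))
  }

  if (!is.null(row_center) && !is.null(row_halfwidth)) {
    rows <- seq_len(nrow(image)) - 1
    sel <- abs(rows - row_center) <= row_halfwidth
    if (!any(sel)) sel <- rep(TRUE, nrow(image))
    counts <- colSums(image[sel, , drop = FALSE])
  } else {
    counts <- colSums(image)
  }
  spectral_profile(seq_along(counts) - 1L, counts,
                   rep(NA_real_, length(counts)))
}
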