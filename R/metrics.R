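#' Localization precision of repeated single-emitter localizations
#'
#' Per-axis standard deviation (the headline statistic) and RMSE about the
#' ground truth (which additionally counts bias) of repeated localizations of
#' one emitter. Invalid localizations are excluded; when more than half are
#' rejected the estimate is flagged.
#'
#' @param locs Localization tibble with `x_nm`, `y_nm`, optional `z_nm`,
#'   `valid`.
#' @param truth Optional list/row with true `x_nm`, `y_nm`, `z_nm` (needed
#'   for the RMSE columns).
#' @return One-row tibble: `sigma_x_nm`, `sigma_y_nm`, `sigma_z_nm`,
#'   `rmse_x_nm`, `rmse_y_nm`, `n`, `n_rejected`, `flagged`.
#' @export
localization_precision <- function(locs, truth = NULL) {
  ok <- if ("valid" %in% names(locs)) locs$valid & is.finite(locs$x_nm) else
    is.finite(locs$x_nm)
  n_rej <- sum(!ok)
  use <- locs[ok, ]
  if (nrow(use) < 2) stop("need at least 2 valid localizations", call. = FALSE)
  rmse <- function(v, t0) if (is.null(truth)) NA_real_ else
    sqrt(mean((v - t0)^2))
  tibble::tibble(
    sigma_x_nm = stats::sd(use$x_nm),
    sigma_y_nm = stats::sd(use$y_nm),
    sigma_z_nm = if ("z_nm" %in% names(use) && any(is.finite(use$z_nm)))
      stats::sd(use$z_nm[is.finite(use$z_nm)]) else NA_real_,
    rmse_x_nm = rmse(use$x_nm, truth$x_nm),
    rmse_y_nm = rmse(use$y_nm, truth$y_nm),
    n = nrow(use), n_rejected = n_rej,
    flagged = n_rej > nrow(locs) / 2)
}

#' Spectral precision
#'
#' Standard deviation of repeated spectral-centroid estimates (nm).
#'
#' @param centroids_nm Recovered centroids.
#' @return One-row tibble: `sigma_lambda_nm`, `n`.
#' @export
spectral_precision <- function(centroids_nm) {
  v <- centroids_nm[is.finite(centroids_nm)]
  if (length(v) < 2) stop("need at least 2 centroids", call. = FALSE)
  tibble::tibble(sigma_lambda_nm = stats::sd(v), n = length(v))
}

#' Color crosstalk
#'
#' Percentage of molecules assigned to the wrong color channel, after
#' aligning predicted labels to truth by the best label permutation (so a
#' globally swapped labeling counts as 0% crosstalk).
#'
#' @param labels Predicted integer labels.
#' @param truth_labels Ground-truth labels (same length).
#' @return Crosstalk percentage (0-100). `NA` labels count as misclassified.
#' @export
crosstalk <- function(labels, truth_labels) {
  if (length(labels) != length(truth_labels))
    stop("label vectors differ in length", call. = FALSE)
  lv <- sort(unique(truth_labels))
  perms <- function(v) if (length(v) <= 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  best <- Inf
  for (p in perms(lv)) {
    mapped <- p[match(labels, lv)]
    mis <- sum(is.na(mapped) | mapped != truth_labels)
    best <- min(best, mis)
  }
  100 * best / length(labels)
}

#' Render localizations into a super-resolution image
#'
#' Histogram mode bins localization counts into `render_pixel_nm` pixels;
#' gaussian mode splats a fixed-width kernel per localization (mass
#' preserved).
#'
#' @param locs Localization tibble with `x_nm`, `y_nm` (invalid rows are
#'   dropped when a `valid` column is present).
#' @param render_pixel_nm Super-resolution pixel size (nm).
#' @param mode `"histogram"` or `"gaussian"`.
#' @param sigma_nm Kernel width for gaussian mode.
#' @param extent_nm Length-4 vector `c(xmin, xmax, ymin, ymax)`; default
#'   hugs the data.
#' @return A `rendered_image`: numeric matrix (rows = y) with attributes
#'   `render_pixel_nm` and `extent_nm`.
#' @export
render <- function(locs, render_pixel_nm = 10,
                   mode = c("histogram", "gaussian"), sigma_nm = 10,
                   extent_nm = NULL) {
  mode <- match.arg(mode)
  stopifnot(render_pixel_nm > 0)
  if ("valid" %in% names(locs)) locs <- locs[locs$valid, ]
  locs <- locs[is.finite(locs$x_nm) & is.finite(locs$y_nm), ]
  if (is.null(extent_nm)) {
    if (nrow(locs) == 0) extent_nm <- c(0, render_pixel_nm, 0, render_pixel_nm)
    else extent_nm <- c(min(locs$x_nm), max(locs$x_nm) + render_pixel_nm,
                        min(locs$y_nm), max(locs$y_nm) + render_pixel_nm)
  }
  nx <- max(1L, ceiling((extent_nm[2] - extent_nm[1]) / render_pixel_nm))
  ny <- max(1L, ceiling((extent_nm[4] - extent_nm[3]) / render_pixel_nm))
  img <- matrix(0, ny, nx)
  if (nrow(locs) > 0) {
    ix <- floor((locs$x_nm - extent_nm[1]) / render_pixel_nm) + 1L
    iy <- floor((locs$y_nm - extent_nm[3]) / render_pixel_nm) + 1L
    keep <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    if (mode == "histogram") {
      idx <- (ix[keep] - 1L) * ny + iy[keep]
      tab <- tabulate(idx, nbins = nx * ny)
      img <- matrix(tab, ny, nx)
    } else {
      s_px <- sigma_nm / render_pixel_nm
      half <- max(1L, ceiling(4 * s_px))
      kern <- stats::dnorm(seq(-half, half), sd = s_px)
      kern2 <- kern %o% kern
      kern2 <- kern2 / sum(kern2)
      pad <- matrix(0, ny + 2 * half, nx + 2 * half)
      xs <- locs$x_nm[keep]; ys <- locs$y_nm[keep]
      for (i in seq_along(xs)) {
        cx <- ix[keep][i] + half; cy <- iy[keep][i] + half
        rows <- (cy - half):(cy + half); cols <- (cx - half):(cx + half)
        pad[rows, cols] <- pad[rows, cols] + kern2
      }
      img <- pad[(half + 1):(half + ny), (half + 1):(half + nx)]
    }
  }
  structure(img, render_pixel_nm = render_pixel_nm, extent_nm = extent_nm,
            class = c("rendered_image", "matrix", "array"))
}

# ring-averaged Fourier correlation of two equally sized images
frc_curve <- function(img1, img2) {
  n <- max(dim(img1))
  pad <- function(m) {
    out <- matrix(0, n, n)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  f1 <- stats::fft(pad(img1))
  f2 <- stats::fft(pad(img2))
  kx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  kr <- sqrt(outer(kx^2, kx^2, "+"))
  ring <- round(kr * n)
  cross <- Re(f1 * Conj(f2))
  p1 <- Mod(f1)^2
  p2 <- Mod(f2)^2
  kmax <- n %/% 2
  num <- tapply(cross, ring, sum)[as.character(0:kmax)]
  d1 <- tapply(p1, ring, sum)[as.character(0:kmax)]
  d2 <- tapply(p2, ring, sum)[as.character(0:kmax)]
  tibble::tibble(ring = 0:kmax, frc = as.numeric(num / sqrt(d1 * d2)))
}

#' Fourier ring correlation resolution
#'
#' Splits the localizations into random halves (seeded), renders each half as
#' a 2D histogram, computes the ring-averaged correlation between the two
#' Fourier transforms, and reports the inverse of the spatial frequency where
#' the curve first drops below the fixed 1/7 threshold (linear interpolation
#' across the crossing). When the curve never crosses — statistically
#' identical halves — the Nyquist-limited lower bound is returned with
#' `crossed = FALSE`.
#'
#' @param locs Localization tibble (`x_nm`, `y_nm`, optional `valid`).
#' @param render_pixel_nm Rendering pixel (nm); 10 nm default.
#' @param seed Seed for the half split.
#' @param threshold Correlation threshold (fixed-1/7 criterion).
#' @return An `frc_result` list: `resolution_nm`, `crossed`, `curve`
#'   (tibble `freq_per_nm`, `frc`), `n`.
#' @export
frc_resolution <- function(locs, render_pixel_nm = 10, seed = 1,
                           threshold = 1 / 7) {
  if ("valid" %in% names(locs)) locs <- locs[locs$valid, ]
  locs <- locs[is.finite(locs$x_nm) & is.finite(locs$y_nm), ]
  if (nrow(locs) < 100) stop("need at least 100 localizations for FRC", call. = FALSE)
  set.seed(seed)
  half <- sample(c(TRUE, FALSE), nrow(locs), replace = TRUE)
  extent <- c(min(locs$x_nm), max(locs$x_nm) + render_pixel_nm,
              min(locs$y_nm), max(locs$y_nm) + render_pixel_nm)
  im1 <- render(locs[half, ], render_pixel_nm, "histogram", extent_nm = extent)
  im2 <- render(locs[!half, ], render_pixel_nm, "histogram", extent_nm = extent)
  curve <- frc_curve(unclass(im1), unclass(im2))
  n <- max(dim(im1))
  L <- n * render_pixel_nm
  curve$freq_per_nm <- curve$ring / L
  below <- which(curve$frc < threshold & curve$ring > 0)
  if (length(below) == 0) {
    res <- 2 * render_pixel_nm   # Nyquist bound
    crossed <- FALSE
  } else {
    k <- below[1]
    f0 <- curve$frc[k - 1]; f1v <- curve$frc[k]
    frac <- (f0 - threshold) / (f0 - f1v)
    kc <- (curve$ring[k - 1] + frac) / L
    res <- 1 / kc
    crossed <- TRUE
  }
  structure(list(resolution_nm = res, crossed = crossed,
                 curve = curve[, c("ring", "freq_per_nm", "frc")],
                 n = nrow(locs), threshold = threshold),
            class = "frc_result")
}

#' @export
print.frc_result <- function(x, ...) {
  cat(sprintf("<frc_result> resolution %.1f nm (%s, n = %d, threshold %.3f)\n",
              x$resolution_nm,
              if (x$crossed) "1/7 crossing" else "no crossing: Nyquist bound",
              x$n, x$threshold))
  invisible(x)
}

#' Cross-sectional resolution from a rendered line profile
#'
#' Averages intensity across the perpendicular width of a line segment drawn
#' on a rendered image, fits a 1D Gaussian to the resulting profile, and
#' returns its FWHM in nm — the standard way filament cross-sections are
#' quoted as an image-domain resolution measure.
#'
#' @param image A [render()]ed image.
#' @param p0_nm,p1_nm Segment endpoints `c(x, y)` in nm (image coordinates).
#' @param width_px Number of parallel sample lines averaged across the
#'   perpendicular direction.
#' @return One-row tibble: `fwhm_nm`, `center_offset_nm` (fitted center
#'   relative to the segment), `ok`.
#' @export
line_profile_fwhm <- function(image, p0_nm, p1_nm, width_px = 10) {
  stopifnot(inherits(image, "rendered_image"))
  px <- attr(image, "render_pixel_nm")
  ext <- attr(image, "extent_nm")
  d <- p1_nm - p0_nm
  len <- sqrt(sum(d^2))
  u <- d / len                       # along the segment (profile axis)
  v <- c(-u[2], u[1])                # perpendicular (averaging axis)
  ts <- seq(0, len, by = px / 2)
  ws <- (seq_len(width_px) - (width_px + 1) / 2) * px
  # bilinear sample of image at (x, y) nm
  sample_img <- function(x, y) {
    cx <- (x - ext[1]) / px + 0.5
    cy <- (y - ext[3]) / px + 0.5
    x0 <- floor(cx); y0 <- floor(cy)
    fx <- cx - x0; fy <- cy - y0
    get <- function(r, c) {
      out <- numeric(length(r))
      okk <- r >= 1 & r <= nrow(image) & c >= 1 & c <= ncol(image)
      out[okk] <- image[cbind(r[okk], c[okk])]
      out
    }
    (1 - fx) * (1 - fy) * get(y0, x0) + fx * (1 - fy) * get(y0, x0 + 1) +
      (1 - fx) * fy * get(y0 + 1, x0) + fx * fy * get(y0 + 1, x0 + 1)
  }
  prof <- vapply(ts, function(t0) {
    pts_x <- p0_nm[1] + t0 * u[1] + ws * v[1]
    pts_y <- p0_nm[2] + t0 * u[2] + ws * v[2]
    mean(sample_img(pts_x, pts_y))
  }, numeric(1))
  fit <- fit_gaussian_1d(prof, t = ts)
  if (!fit$ok) stop("no fittable peak in the line profile", call. = FALSE)
  tibble::tibble(fwhm_nm = fit$fwhm, center_offset_nm = fit$center - len / 2,
                 ok = TRUE)
}
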