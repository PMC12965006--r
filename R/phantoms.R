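#' Synthetic filament structures
#'
#' Generates smooth random curves spanning the field of view, emulating
#' microtubule-like filaments: each curve is a constant-speed walk whose
#' heading receives Gaussian increments (scaled by `curvature`) and is
#' steered back when it approaches the border, then resampled at
#' `spacing_nm` along the arc. Label sites drawn from these curves receive a
#' radial offset at sampling time (see [sample_blinks()]), emulating the
#' finite filament radius.
#'
#' @param n Number of filaments.
#' @param fov_nm Field-of-view side length (nm).
#' @param curvature Heading diffusion per step (0 = straight lines).
#' @param seed RNG seed.
#' @param spacing_nm Arc-length spacing of the returned sample points.
#' @param dye Dye label attached to every filament.
#' @param margin_nm Border margin the curves stay inside.
#' @return Tibble of candidate label sites: `structure_id`, `kind`, `dye`,
#'   `x_nm`, `y_nm`, `z_nm`, `tangent_x`, `tangent_y`.
#' @export
make_filaments <- function(n, fov_nm = 5000, curvature = 0.15, seed = 1,
                           spacing_nm = 5, dye = "AF647", margin_nm = 250) {
  stopifnot(n >= 1)
  set.seed(seed)
  lo <- margin_nm; hi <- fov_nm - margin_nm
  purrr::map_dfr(seq_len(n), function(i) {
    start <- stats::runif(2, lo + 0.1 * fov_nm, hi - 0.1 * fov_nm)
    theta <- stats::runif(1, 0, 2 * pi)
    n_steps <- ceiling(1.2 * fov_nm / spacing_nm)
    xs <- numeric(n_steps); ys <- numeric(n_steps)
    x <- start[1]; y <- start[2]
    dtheta <- stats::rnorm(n_steps, 0, curvature * sqrt(spacing_nm / 50))
    for (s in seq_len(n_steps)) {
      theta <- theta + dtheta[s]
      # steer back toward the interior near the border
      if (x < lo || x > hi || y < lo || y > hi) {
        target <- atan2(fov_nm / 2 - y, fov_nm / 2 - x)
        theta <- theta + 0.2 * sin(target - theta) * 2
      }
      x <- x + spacing_nm * cos(theta)
      y <- y + spacing_nm * sin(theta)
      xs[s] <- x; ys[s] <- y
    }
    keep <- xs > lo & xs < hi & ys > lo & ys < hi
    tx <- c(diff(xs), spacing_nm); ty <- c(diff(ys), 0)
    nrm <- sqrt(tx^2 + ty^2); nrm[nrm == 0] <- 1
    tibble::tibble(structure_id = i, kind = "filament", dye = dye,
                   x_nm = xs[keep], y_nm = ys[keep], z_nm = 0,
                   tangent_x = (tx / nrm)[keep], tangent_y = (ty / nrm)[keep])
  })
}

#' A single straight filament (for line-profile benchmarks)
#'
#' @param fov_nm Field of view (nm); the filament runs horizontally through
#'   the center.
#' @param length_nm Filament length (nm).
#' @param spacing_nm Site spacing along the filament.
#' @param dye Dye label.
#' @return Site tibble in the [make_filaments()] format.
#' @export
make_straight_filament <- function(fov_nm = 3000, length_nm = 2000,
                                   spacing_nm = 5, dye = "AF647") {
  xs <- seq((fov_nm - length_nm) / 2, (fov_nm + length_nm) / 2, by = spacing_nm)
  tibble::tibble(structure_id = 1L, kind = "filament", dye = dye,
                 x_nm = xs, y_nm = fov_nm / 2, z_nm = 0,
                 tangent_x = 1, tangent_y = 0)
}

#' Synthetic blob structures
#'
#' Punctate/vesicular structures (mitochondria- or clathrin-like): elliptical
#' shells or filled discs with radii drawn uniformly from `radius_range_nm`,
#' sampled at ~`spacing_nm` point spacing.
#'
#' @param n Number of blobs.
#' @param radius_range_nm Length-2 radius range (nm).
#' @param fov_nm Field-of-view side (nm).
#' @param seed RNG seed.
#' @param kind `"shell"` (labeled membrane) or `"disc"` (filled).
#' @param spacing_nm Target point spacing (nm).
#' @param dye Dye label.
#' @return Site tibble: `structure_id`, `kind`, `dye`, `x_nm`, `y_nm`,
#'   `z_nm`, `radius_nm`.
#' @export
make_blobs <- function(n, radius_range_nm = c(100, 250), fov_nm = 5000,
                       seed = 1, kind = c("shell", "disc"), spacing_nm = 5,
                       dye = "CF660C") {
  kind <- match.arg(kind)
  stopifnot(n >= 1, diff(radius_range_nm) >= 0)
  set.seed(seed)
  margin <- max(radius_range_nm) + 100
  purrr::map_dfr(seq_len(n), function(i) {
    r <- stats::runif(1, radius_range_nm[1], radius_range_nm[2])
    cx <- stats::runif(1, margin, fov_nm - margin)
    cy <- stats::runif(1, margin, fov_nm - margin)
    ecc <- stats::runif(1, 0.7, 1)     # mild ellipticity
    if (kind == "shell") {
      n_pts <- max(8, ceiling(2 * pi * r / spacing_nm))
      ang <- seq(0, 2 * pi, length.out = n_pts + 1)[-1]
      xs <- cx + r * cos(ang); ys <- cy + ecc * r * sin(ang)
    } else {
      n_pts <- max(8, ceiling(pi * r^2 / spacing_nm^2))
      rr <- r * sqrt(stats::runif(n_pts))
      ang <- stats::runif(n_pts, 0, 2 * pi)
      xs <- cx + rr * cos(ang); ys <- cy + ecc * rr * sin(ang)
    }
    tibble::tibble(structure_id = i, kind = paste0("blob_", kind), dye = dye,
                   x_nm = xs, y_nm = ys, z_nm = 0, radius_nm = r)
  })
}

#' Sample a blinking-event stream from labeled structures
#'
#' Draws stochastic blinking events from the pooled label sites (so long
#' structures emit proportionally more events), assigns them to frames with a
#' Poisson number of active emitters per frame, jitters positions by the
#' label/linker displacement, and draws per-event signal photons from a
#' lognormal with the requested mean and coefficient of variation
#' (`photon_cv = 0` gives a fixed budget). Filament sites additionally get a
#' radial offset perpendicular to the local tangent — the projection of a
#' label on the filament surface cylinder of radius `filament_radius_nm`.
#'
#' @param structures Site tibble from the `make_*` generators (rows may be
#'   concatenated across structures and dyes).
#' @param frames Number of camera frames.
#' @param mean_signal Mean signal photons per event.
#' @param mean_background Background photons per event (over the reference
#'   ROI; constant).
#' @param linker_jitter_nm Isotropic Gaussian label displacement (nm).
#' @param sparsity Mean active emitters per frame.
#' @param seed RNG seed.
#' @param photon_cv Lognormal coefficient of variation of the signal photons.
#' @param filament_radius_nm Radius of the filament surface cylinder (nm).
#' @return A blink-stream tibble: `frame`, `site_row`, `x_nm`, `y_nm`,
#'   `z_nm`, `dye`, `n_signal`, `n_background`.
#' @export
sample_blinks <- function(structures, frames, mean_signal = 5000,
                          mean_background = 10000, linker_jitter_nm = 5,
                          sparsity = 2, seed = 1, photon_cv = 0.3,
                          filament_radius_nm = 12.5) {
  if (nrow(structures) == 0) stop("no structures to sample from", call. = FALSE)
  set.seed(seed)
  per_frame <- stats::rpois(frames, sparsity)
  total <- sum(per_frame)
  if (total == 0)
    return(tibble::tibble(frame = integer(), site_row = integer(),
                          x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
                          dye = character(), n_signal = numeric(),
                          n_background = numeric()))
  idx <- sample.int(nrow(structures), total, replace = TRUE)
  sites <- structures[idx, ]
  x <- sites$x_nm + stats::rnorm(total, 0, linker_jitter_nm)
  y <- sites$y_nm + stats::rnorm(total, 0, linker_jitter_nm)
  is_fil <- sites$kind == "filament"
  if (any(is_fil) && filament_radius_nm > 0) {
    phi <- stats::runif(sum(is_fil), 0, 2 * pi)
    off <- filament_radius_nm * cos(phi)   # in-plane projection of the cylinder
    x[is_fil] <- x[is_fil] - sites$tangent_y[is_fil] * off
    y[is_fil] <- y[is_fil] + sites$tangent_x[is_fil] * off
  }
  if (photon_cv > 0) {
    sdl <- sqrt(log(1 + photon_cv^2))
    sig <- stats::rlnorm(total, log(mean_signal) - sdl^2 / 2, sdl)
  } else {
    sig <- rep(mean_signal, total)
  }
  tibble::tibble(frame = rep(seq_len(frames), per_frame),
                 site_row = idx,
                 x_nm = x, y_nm = y, z_nm = sites$z_nm, dye = sites$dye,
                 n_signal = sig, n_background = mean_background)
}
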