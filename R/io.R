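#' Write / read a localization table
#'
#' CSV with the frozen column set `frame, x_nm, y_nm, z_nm, lambda_c_nm,
#' dye, n_photons, valid` (ThunderSTORM-style `_nm`-suffixed coordinate
#' names, so the tables drop into standard SMLM rendering tools). Extra
#' columns present in the tibble are preserved after the frozen block.
#'
#' @param locs Localization tibble.
#' @param path Output path.
#' @return `write_localizations()` returns `path` invisibly;
#'   `read_localizations()` returns a tibble.
#' @export
write_localizations <- function(locs, path) {
  front <- c("frame", "x_nm", "y_nm", "z_nm", "lambda_c_nm", "dye",
             "n_photons", "valid")
  for (col in front) if (!col %in% names(locs)) locs[[col]] <- NA
  locs <- locs[, c(front, setdiff(names(locs), front))]
  locs <- locs[, !vapply(locs, is.list, logical(1))]
  readr::write_csv(locs, path)
  invisible(path)
}

#' @rdname write_localizations
#' @export
read_localizations <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write / read ground-truth emitter tables
#'
#' CSV columns: `frame, x_nm, y_nm, z_nm, dye, n_signal, n_background`.
#'
#' @param truth Blink-stream / emitter tibble.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  cols <- c("frame", "x_nm", "y_nm", "z_nm", "dye", "n_signal", "n_background")
  for (col in cols) if (!col %in% names(truth)) truth[[col]] <- NA
  readr::write_csv(truth[, cols], path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write a list of frames as a 16-bit multi-page TIFF
#'
#' One page per frame; the two channels of each frame pair are written to
#' separate files (`<stem>_chA.tif`, `<stem>_chB.tif`). Counts are clamped
#' to the 16-bit range.
#'
#' @param frames List of `frame_set`s (all the same size).
#' @param stem Output path stem (without extension).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_frame_tiff <- function(frames, stem) {
  stopifnot(length(frames) >= 1)
  to16 <- function(m) pmin(pmax(m, 0), 65535) / 65535
  pages_a <- lapply(frames, function(f) to16(f$images$A))
  pages_b <- lapply(frames, function(f) to16(f$images$B))
  pa <- paste0(stem, "_chA.tif")
  pb <- paste0(stem, "_chB.tif")
  tiff::writeTIFF(pages_a, pa, bits.per.sample = 16)
  tiff::writeTIFF(pages_b, pb, bits.per.sample = 16)
  invisible(c(pa, pb))
}

#' @rdname write_frame_tiff
#' @param path A TIFF written by [write_frame_tiff()].
#' @return `read_frame_tiff()` returns a list of count matrices.
#' @export
read_frame_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) p * 65535)
}

#' Write a rendered image as 32-bit TIFF
#'
#' @param image A [render()]ed image.
#' @param path Output path.
#' @export
write_render_tiff <- function(image, path) {
  m <- unclass(image)
  attributes(m) <- list(dim = dim(m))
  tiff::writeTIFF(m / max(m, 1), path, bits.per.sample = 32)
  invisible(path)
}

#' Run manifest
#'
#' JSON provenance stamp written next to simulation outputs: configuration
#' hash, seed, method, event count and package version.
#'
#' @param config An [optical_config()].
#' @param seed RNG seed of the run.
#' @param method Method id.
#' @param n_events Number of events.
#' @param path Output path.
#' @export
write_manifest <- function(config, seed, method, n_events, path) {
  jsonlite::write_json(
    list(config_hash = config_hash(config), seed = seed, method = method,
         n_events = n_events,
         package_version = as.character(utils::packageVersion("odsmlm"))),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Emit an evaluation report as JSON
#'
#' @param report One-row metrics tibble (precision / crosstalk / FRC fields).
#' @param path Output path.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(as.list(report), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
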