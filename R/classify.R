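#' Classify localizations by spectral-centroid threshold
#'
#' Deterministic two-color assignment: label 0 when the centroid lies below
#' the threshold, 1 otherwise. The standard threshold for a dye pair is the
#' midpoint of the two population centroid means.
#'
#' @param centroids_nm Per-localization spectral centroids (nm).
#' @param threshold_nm Decision boundary (nm).
#' @return Integer labels (0/1), `NA` for non-finite centroids.
#' @export
classify_by_centroid <- function(centroids_nm, threshold_nm) {
  if (length(centroids_nm) == 0) stop("no centroids to classify", call. = FALSE)
  out <- ifelse(centroids_nm < threshold_nm, 0L, 1L)
  out[!is.finite(centroids_nm)] <- NA_integer_
  out
}

#' Assemble a spectral dataset from per-localization profiles
#'
#' Resamples every profile onto a common wavelength grid, giving the
#' localizations x wavelength-bins intensity matrix used by the
#' dimensionality-reduction classifier.
#'
#' @param profiles List of `spectral_profile`s.
#' @param grid_nm Common wavelength grid (nm).
#' @return List with `matrix` (rows = localizations), `grid_nm`,
#'   `centroids_nm` (per-row band centroids on the grid).
#' @export
build_spectral_dataset <- function(profiles, grid_nm = seq(620, 750, by = 2)) {
  stopifnot(length(profiles) >= 1)
  mat <- t(vapply(profiles, function(p) {
    v <- stats::approx(p$wavelength_nm, p$counts, xout = grid_nm, rule = 2)$y
    v
  }, numeric(length(grid_nm))))
  cent <- apply(mat, 1, function(v) {
    w <- pmax(v, 0)
    if (sum(w) <= 0) return(NA_real_)
    sum(grid_nm * w) / sum(w)
  })
  list(matrix = mat, grid_nm = grid_nm, centroids_nm = cent)
}

#' Classify single-molecule spectra by PCA + k-means
#'
#' Rows are L2-normalized (removing per-molecule intensity variation),
#' projected onto the leading principal components, and clustered by k-means
#' with a fixed seed and multiple restarts. Cluster indices are mapped to
#' dye labels by ascending mean spectral centroid of the cluster members, so
#' label 0 is always the bluer dye and downstream metrics are invariant to
#' k-means label switching.
#'
#' @param dataset A [build_spectral_dataset()] result (or a bare matrix).
#' @param n_components Number of principal components retained.
#' @param k Number of clusters (2 for dual-color).
#' @param seed RNG seed for the k-means restarts.
#' @return Integer labels `0..k-1`, ordered by cluster mean centroid.
#' @export
classify_pca_kmeans <- function(dataset, n_components = 3, k = 2, seed = 1) {
  mat <- if (is.list(dataset) && !is.null(dataset$matrix)) dataset$matrix else as.matrix(dataset)
  if (nrow(mat) < k) stop("need at least k spectra", call. = FALSE)
  if (n_components < 1) stop("`n_components` must be >= 1", call. = FALSE)
  norms <- sqrt(rowSums(mat^2))
  if (any(norms == 0)) stop("all-zero spectra cannot be classified", call. = FALSE)
  nm <- mat / norms
  sds <- apply(nm, 2, stats::sd)
  if (all(sds < 1e-12))
    stop("degenerate spectral matrix: no variance across spectra", call. = FALSE)
  pc <- stats::prcomp(nm, center = TRUE, scale. = FALSE)
  ncomp <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(ncomp), drop = FALSE]
  set.seed(seed)
  km <- stats::kmeans(scores, centers = k, nstart = 10)
  if (length(unique(km$cluster)) < k)
    warning("k-means collapsed to fewer than k clusters", call. = FALSE)
  # order clusters by the centroid of their mean spectrum
  grid <- if (is.list(dataset) && !is.null(dataset$grid_nm)) dataset$grid_nm
          else seq_len(ncol(mat))
  cluster_cent <- vapply(seq_len(k), function(j) {
    m <- colMeans(mat[km$cluster == j, , drop = FALSE])
    w <- pmax(m, 0)
    sum(grid * w) / sum(w)
  }, numeric(1))
  remap <- order(cluster_cent)
  labels <- match(km$cluster, remap) - 1L
  labels
}
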