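#' Principal component analysis of C-alpha fluctuations
#'
#' Superposes the ensemble onto its mean structure, forms the covariance
#' matrix of the C-alpha coordinates (unbiased, F-1 normalization), and
#' diagonalizes it.  The leading eigenvector is the essential mode of the
#' ensemble; projections are centered so each PC has zero mean.
#'
#' @param ens An [ensemble()] with at least two frames.
#' @param fit_mask Atom index vector for the superposition fit; default all
#'   C-alpha atoms.
#' @param superpose Set `FALSE` if the frames are already superposed.
#' @return Object of class `pca_result`: `values` (eigenvalues, A^2,
#'   descending), `vectors` (orthonormal columns), `projections` (`F x k`),
#'   `var_fraction`, `total_variance`.
#' @export
compute_pca <- function(ens, fit_mask = NULL, superpose = TRUE) {
  if (nrow(ens$xyz) < 2) abort("PCA needs at least 2 frames")
  sup <- if (superpose) superpose_ensemble(ens, fit_mask, reference = "mean") else ens
  cols <- xyz_cols(calpha_map(ens$topology))
  X <- sup$xyz[, cols, drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  cv <- crossprod(Xc) / (nrow(X) - 1)
  eig <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  proj <- Xc %*% eig$vectors
  structure(list(values = vals, vectors = eig$vectors, projections = proj,
                 var_fraction = vals / sum(vals), total_variance = sum(diag(cv)),
                 n_frames = nrow(X)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d frames, PC1 %.1f%%, PC2 %.1f%% of variance\n",
              x$n_frames, 100 * x$var_fraction[1], 100 * x$var_fraction[2]))
  invisible(x)
}

#' Two-dimensional conformational landscape in PC1-PC2
#'
#' @param pca A [compute_pca()] result with at least two components.
#' @param nbins Number of histogram bins per axis, default 40.
#' @return A list: `points` (`F x 2`), `x_breaks`, `y_breaks`, `density`
#'   (matrix of bin probabilities summing to 1).
#' @export
project_landscape <- function(pca, nbins = 40) {
  if (ncol(pca$projections) < 2) abort("need at least 2 principal components")
  pts <- pca$projections[, 1:2, drop = FALSE]
  colnames(pts) <- c("PC1", "PC2")
  pad <- 1e-9
  xb <- seq(min(pts[, 1]) - pad, max(pts[, 1]) + pad, length.out = nbins + 1)
  yb <- seq(min(pts[, 2]) - pad, max(pts[, 2]) + pad, length.out = nbins + 1)
  ix <- findInterval(pts[, 1], xb, rightmost.closed = TRUE)
  iy <- findInterval(pts[, 2], yb, rightmost.closed = TRUE)
  dens <- matrix(0, nbins, nbins)
  for (f in seq_len(nrow(pts))) dens[ix[f], iy[f]] <- dens[ix[f], iy[f]] + 1
  dens <- dens / nrow(pts)
  list(points = pts, x_breaks = xb, y_breaks = yb, density = dens)
}

#' Cluster the PC1-PC2 landscape and pick representative frames
#'
#' K-means in the PC1-PC2 plane with seeded multi-start initialization; the
#' representative of each cluster is the frame nearest its centroid (a mean
#' structure can be unphysical, a real frame cannot).
#'
#' @param pca A [compute_pca()] result.
#' @param K Number of clusters, default 2.
#' @param seed RNG seed for the k-means starts, default 1.
#' @param nstart Number of k-means restarts, default 25.
#' @return Object of class `cluster_result`: `labels` (per frame),
#'   `K`, `centers`, `representative` (frame index per cluster), `sizes`.
#' @export
cluster_landscape <- function(pca, K = 2, seed = 1, nstart = 25) {
  pts <- pca$projections[, 1:2, drop = FALSE]
  F <- nrow(pts)
  if (K < 1) abort("K must be >= 1")
  if (K > F) abort("K = %d exceeds the number of frames (%d)", K, F)
  km <- with_seed(seed, stats::kmeans(pts, centers = K, nstart = nstart,
                                      iter.max = 100))
  rep_frame <- vapply(seq_len(K), function(k) {
    members <- which(km$cluster == k)
    d2 <- rowSums(sweep(pts[members, , drop = FALSE], 2, km$centers[k, ])^2)
    members[which.min(d2)]
  }, integer(1))
  structure(list(labels = km$cluster, K = K, centers = km$centers,
                 representative = rep_frame, sizes = km$size, seed = seed),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("clusters: K = %d, sizes [%s], representatives [%s]\n", x$K,
              paste(x$sizes, collapse = ", "),
              paste(x$representative, collapse = ", ")))
  invisible(x)
}

#' Summarize a per-frame RMSD series by cluster
#'
#' Mirrors cluster tables reporting mean (SD) RMSD per conformational
#' cluster.
#'
#' @param clusters A [cluster_landscape()] result.
#' @param rmsd A [rmsd_series()] result (same frame order).
#' @return Data.frame with `cluster`, `n`, `rmsd_mean`, `rmsd_sd`.
#' @export
cluster_rmsd_summary <- function(clusters, rmsd) {
  stopifnot(length(clusters$labels) == nrow(rmsd))
  out <- do.call(rbind, lapply(seq_len(clusters$K), function(k) {
    v <- rmsd$rmsd[clusters$labels == k]
    data.frame(cluster = k, n = length(v), rmsd_mean = mean(v),
               rmsd_sd = stats::sd(v))
  }))
  out
}
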