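#' Pearson correlation distance between fingerprints
#'
#' Computes the sample-by-sample dissimilarity `D[i, j] = 1 - r(x_i, x_j)`
#' where `r` is the Pearson correlation between two full traces. Values range
#' over `[0, 2]`; identical traces give 0, anti-correlated ones 2.
#'
#' @param F A `fingerprint_matrix`, or a plain samples x variables matrix.
#' @return An object of class `dist_matrix`: list with `ids` and the
#'   symmetric matrix `D` (zero diagonal).
#' @export
correlation_distance <- function(F) {
  X <- if (inherits(F, "fingerprint_matrix")) F$X else as.matrix(F)
  if (nrow(X) < 2) stop("Need at least two samples.", call. = FALSE)
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow(X)))
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf(
      "Constant trace(s): %s; correlation distance undefined.",
      paste(ids[sds == 0], collapse = ", ")
    ), call. = FALSE)
  }
  D <- 1 - stats::cor(t(X))
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  structure(list(ids = ids, D = D, transform = "none"), class = "dist_matrix")
}

#' Square-root transform of a distance matrix
#'
#' Elementwise square root. Shrinks large dissimilarities relative to small
#' ones (improving dendrogram legibility) while preserving the ordering of
#' all pairwise distances.
#'
#' @param D A `dist_matrix`.
#' @return The transformed `dist_matrix`.
#' @export
sqrt_transform <- function(D) {
  stopifnot(inherits(D, "dist_matrix"))
  if (any(D$D < 0)) {
    stop("Distance matrix has negative entries; cannot take square root.",
      call. = FALSE
    )
  }
  D$D <- sqrt(D$D)
  D$transform <- paste0(D$transform, "+sqrt")
  D
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf(
    "<dist_matrix> %d samples, range [%.4g, %.4g], transform: %s\n",
    length(x$ids), min(x$D), max(x$D[upper.tri(x$D)]), x$transform
  ))
  invisible(x)
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering under Ward's minimum-variance criterion in the
#' `ward.D2` convention: the supplied dissimilarities are treated as
#' distances and the objective operates on their squares.
#'
#' @param D A `dist_matrix`.
#' @return An object of classes `linkage_tree` and `hclust` (so
#'   [stats::cutree()], [stats::cophenetic()] and plotting all apply).
#' @export
ward_linkage <- function(D) {
  stopifnot(inherits(D, "dist_matrix"))
  if (length(D$ids) < 2) stop("Need at least two samples.", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(D$D), method = "ward.D2")
  hc$labels <- D$ids
  class(hc) <- c("linkage_tree", "hclust")
  hc
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the original pairwise dissimilarities and the
#' dendrogram's cophenetic distances (the merge height of each pair's lowest
#' common ancestor). Values near 1 indicate the dendrogram faithfully
#' preserves the original distance structure.
#'
#' @param tree A `linkage_tree`.
#' @param D The `dist_matrix` the tree was built from (after any transform).
#' @return The cophenetic correlation (scalar).
#' @export
cophenetic_correlation <- function(tree, D) {
  stopifnot(inherits(tree, "hclust"), inherits(D, "dist_matrix"))
  if (!setequal(tree$labels, D$ids)) {
    stop("Tree leaves and distance-matrix ids differ.", call. = FALSE)
  }
  coph <- as.matrix(stats::cophenetic(tree))
  coph <- coph[D$ids, D$ids]
  ut <- upper.tri(D$D)
  d0 <- D$D[ut]
  dc <- coph[ut]
  if (length(d0) < 2 || stats::sd(d0) == 0 || stats::sd(dc) == 0) {
    stop("Degenerate input: zero variance among pairwise distances.",
      call. = FALSE
    )
  }
  stats::cor(d0, dc)
}

#' Hopkins clustering-tendency statistic
#'
#' Assesses whether the fingerprints show genuine cluster structure, in the
#' near-zero-is-clusterable orientation: rows are first projected onto
#' `pca_dims` principal-component scores, then `m` real points (sampled
#' without replacement) and `m` uniform points in the scores' bounding box are
#' compared through nearest-neighbour distances,
#' `H = sum(w) / (sum(w) + sum(u))`, where `w` are the real points' distances
#' to their nearest other real point and `u` the uniform points' distances to
#' the nearest real point. Tightly clustered data give `H` near 0; structure-
#' free data give `H` around 0.5.
#'
#' @param F A `fingerprint_matrix` or plain matrix with >= 10 rows.
#' @param m_fraction Fraction of rows to sample (`m = max(5, floor(m_fraction * n))`).
#' @param pca_dims Number of principal-component dimensions to embed into.
#' @param seed Sampling seed.
#' @return The Hopkins statistic, in (0, 1).
#' @export
hopkins_statistic <- function(F, m_fraction = 0.1, pca_dims = 2, seed = 1L) {
  X <- if (inherits(F, "fingerprint_matrix")) F$X else as.matrix(F)
  n <- nrow(X)
  if (n < 10) stop("Need at least 10 samples.", call. = FALSE)
  m <- max(5L, floor(m_fraction * n))
  if (m < 2) stop("Sampled point count m must be >= 2.", call. = FALSE)
  if (m > n) stop("m exceeds the number of samples.", call. = FALSE)
  pca_dims <- min(pca_dims, n - 1, ncol(X))
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = pca_dims, nv = 0)
  S <- sv$u %*% diag(sv$d[seq_len(pca_dims)], pca_dims)

  lo <- apply(S, 2, min)
  hi <- apply(S, 2, max)
  with_seed(seed, {
    real_idx <- sample.int(n, m)
    U <- vapply(seq_len(ncol(S)), function(j) {
      stats::runif(m, lo[j], hi[j])
    }, numeric(m))
  })
  U <- matrix(U, nrow = m)

  nn_dist <- function(p, pts) sqrt(min(colSums((t(pts) - p)^2)))
  w <- vapply(real_idx, function(i) {
    nn_dist(S[i, ], S[-i, , drop = FALSE])
  }, numeric(1))
  u <- vapply(seq_len(m), function(i) nn_dist(U[i, ], S), numeric(1))
  sum(w) / (sum(w) + sum(u))
}

#' Cut a dendrogram into k clusters
#'
#' @param tree A `linkage_tree`.
#' @param k Number of clusters (default 2, one per species).
#' @return A tibble with columns `sample_id` and `cluster`.
#' @export
cut_clusters <- function(tree, k = 2L) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("`k` must lie in [1, n].", call. = FALSE)
  cl <- stats::cutree(tree, k = k)
  tibble::tibble(sample_id = names(cl), cluster = unname(cl))
}

#' Cluster-validation summary at one wavelength
#'
#' Convenience wrapper: correlation distance, optional square-root transform,
#' Ward linkage, then cophenetic correlation (against the matrix actually
#' clustered) and the Hopkins statistic.
#'
#' @param F A `fingerprint_matrix`.
#' @param sqrt_dist Apply the square-root transform before linkage?
#' @param k Number of clusters to cut.
#' @param hopkins_seed Seed for Hopkins sampling.
#' @return A list of class `cluster_validation` with fields `ccc`, `hopkins`,
#'   `wavelength_nm`, `tree`, `clusters`, `distance`.
#' @export
validate_clustering <- function(F, sqrt_dist = TRUE, k = 2L,
                                hopkins_seed = 1L) {
  D <- correlation_distance(F)
  if (sqrt_dist) D <- sqrt_transform(D)
  tree <- ward_linkage(D)
  structure(
    list(
      ccc = cophenetic_correlation(tree, D),
      hopkins = hopkins_statistic(F, seed = hopkins_seed),
      wavelength_nm = if (inherits(F, "fingerprint_matrix")) F$wavelength_nm else NA_integer_,
      tree = tree,
      clusters = cut_clusters(tree, k),
      distance = D
    ),
    class = "cluster_validation"
  )
}

#' @export
print.cluster_validation <- function(x, ...) {
  cat(sprintf(
    "<cluster_validation> %s nm: CCC = %.3f, Hopkins = %.3f, k = %d clusters\n",
    x$wavelength_nm, x$ccc, x$hopkins, max(x$clusters$cluster)
  ))
  invisible(x)
}
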