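# Independent oracles used to cross-check the package's implementations.
# These deliberately take different computational routes than the code under
# test (Krylov projection instead of NIPALS, naive Lance-Williams recursion
# instead of hclust, merge-table traversal instead of stats::cophenetic).

# PLS1 fitted values via the Krylov-subspace characterisation: the A-component
# PLS fit is the least-squares projection of y onto span{X s, X (X'X) s, ...},
# s = X' y (Helland's formulation).
krylov_pls_fit <- function(X, y, A) {
  Xc <- sweep(X, 2, colMeans(X))
  yc <- y - mean(y)
  s <- drop(crossprod(Xc, yc))
  K <- matrix(0, ncol(Xc), A)
  v <- s
  for (a in seq_len(A)) {
    K[, a] <- v
    v <- drop(crossprod(Xc, Xc %*% v))
  }
  Z <- Xc %*% K
  drop(Z %*% qr.coef(qr(Z), yc)) + mean(y)
}

# Ward (ward.D2 convention) agglomeration by the naive Lance-Williams
# recursion on squared dissimilarities, recomputing the full matrix at every
# step. Returns merge-step membership sets and heights.
ward_oracle <- function(D) {
  n <- nrow(D)
  d2 <- D^2
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  merges <- list()
  heights <- numeric(0)
  while (length(active) > 1) {
    m <- length(active)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) {
      for (j in seq((i + 1), m)) {
        if (d2[i, j] < best[1]) best <- c(d2[i, j], i, j)
      }
    }
    i <- best[2]
    j <- best[3]
    heights <- c(heights, sqrt(best[1]))
    merges[[length(merges) + 1]] <- sort(c(active[[i]], active[[j]]))
    ni <- sizes[i]
    nj <- sizes[j]
    new_d2 <- numeric(m)
    for (k in seq_len(m)) {
      if (k == i || k == j) next
      nk <- sizes[k]
      new_d2[k] <- ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] -
        nk * d2[i, j]) / (ni + nj + nk)
    }
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d2[keep, keep, drop = FALSE], new_d2[keep]),
      c(new_d2[keep], 0)
    )
    active <- c(active[keep], list(sort(c(merges[[length(merges)]]))))
    sizes <- c(sizes[keep], ni + nj)
  }
  list(merges = merges, heights = heights)
}

# membership sets of an hclust merge table, in merge order
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    grab <- function(id) if (id < 0) -id else sets[[id]]
    sets[[i]] <- sort(c(grab(hc$merge[i, 1]), grab(hc$merge[i, 2])))
  }
  sets
}

# cophenetic distance matrix by direct merge-table traversal: the height of
# the first merge uniting each leaf pair
cophenetic_oracle <- function(hc) {
  n <- length(hc$labels)
  sets <- hclust_merge_sets(hc)
  coph <- matrix(0, n, n)
  for (i in seq_along(sets)) {
    left <- if (hc$merge[i, 1] < 0) -hc$merge[i, 1] else sets[[hc$merge[i, 1]]]
    right <- if (hc$merge[i, 2] < 0) -hc$merge[i, 2] else sets[[hc$merge[i, 2]]]
    for (a in left) {
      for (b in right) {
        coph[a, b] <- coph[b, a] <- hc$height[i]
      }
    }
  }
  dimnames(coph) <- list(hc$labels, hc$labels)
  coph
}

# wrap a plain symmetric matrix as the package's dist_matrix class
as_dist_matrix <- function(M, ids = NULL) {
  if (is.null(ids)) ids <- rownames(M)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow(M)))
  dimnames(M) <- list(ids, ids)
  structure(list(ids = ids, D = M, transform = "none"), class = "dist_matrix")
}

# random valid correlation-style distance matrix (symmetric, zero diagonal)
random_dist <- function(n, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * 6), n)
  M <- 1 - cor(t(X))
  diag(M) <- 0
  as_dist_matrix(M)
}
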