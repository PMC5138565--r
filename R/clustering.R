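# Normalized spectral clustering of the standardized feature matrix,
# exposing original-space cluster centers for query-time pruning.

#' Gaussian similarity matrix
#'
#' `W[i, j] = exp(-||x_i - x_j||^2 / (2 * delta^2))`: symmetric with unit
#' diagonal.
#'
#' @param X Numeric matrix (rows = samples) or feature tibble.
#' @param delta Similarity bandwidth, > 0.
#' @return An `n x n` similarity matrix.
#' @export
similarity_matrix <- function(X, delta) {
  if (delta <= 0) abort("delta must be positive")
  m <- feature_matrix(X)
  if (nrow(m) < 2) abort("need at least 2 samples")
  d2 <- as.matrix(stats::dist(m))^2
  W <- exp(-d2 / (2 * delta^2))
  (W + t(W)) / 2
}

#' Normalized graph Laplacian
#'
#' `L = D^(-1/2) (D - W) D^(-1/2)` with `D` the diagonal matrix of row sums
#' of `W`. Symmetric positive semidefinite; `D^(1/2) * 1` spans its null
#' space for a connected graph.
#'
#' @param W Symmetric nonnegative similarity matrix with positive row sums.
#' @return The normalized Laplacian matrix.
#' @export
normalized_laplacian <- function(W) {
  if (!isSymmetric(unname(W), tol = 1e-8)) abort("W must be symmetric")
  if (any(W < 0)) abort("W must be nonnegative")
  dsum <- rowSums(W)
  if (any(dsum <= 0)) abort("W has a zero row sum")
  dinv <- 1 / sqrt(dsum)
  L <- -W * outer(dinv, dinv)
  diag(L) <- diag(L) + 1
  (L + t(L)) / 2
}

# median pairwise distance of a seeded subsample; the default similarity
# bandwidth when none is supplied
default_delta <- function(X, seed = 1L, max_points = 200L) {
  m <- feature_matrix(X)
  idx <- if (nrow(m) > max_points) {
    withr::with_seed(seed, sample.int(nrow(m), max_points))
  } else {
    seq_len(nrow(m))
  }
  d <- median(stats::dist(m[idx, , drop = FALSE]))
  if (!is.finite(d) || d <= 0) 1 else d
}

#' Spectral clustering of standardized features
#'
#' Ng-Jordan-Weiss normalized spectral clustering: builds the Gaussian
#' similarity graph, takes the `k` eigenvectors of the normalized Laplacian
#' with the smallest eigenvalues, row-normalizes the `n x k` embedding and
#' runs seeded k-means (10 restarts) on its rows. Cluster centers are then
#' recomputed as the mean **original-space** (standardized) feature vectors
#' of each cluster, because query pruning measures distances on the query's
#' features, which are never embedded.
#'
#' @param X Standardized feature matrix or feature tibble.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param delta Similarity bandwidth; default is the median pairwise distance
#'   of a seeded subsample of up to 200 rows.
#' @param seed Integer seed for k-means restarts (and the delta subsample).
#' @return An object of class `cluster_model` with fields `centers`
#'   (`k x d`), `assignments` (length `n`, values in `1..k`), `delta`, `k`,
#'   `sizes`.
#' @export
spectral_cluster <- function(X, k, delta = NULL, seed = 1L) {
  m <- feature_matrix(X)
  n <- nrow(m)
  if (k < 1 || k > n) abort("k must lie in 1..n")
  delta <- delta %||% default_delta(m, seed)
  if (k == 1) {
    assign <- rep(1L, n)
  } else if (k == n) {
    assign <- seq_len(n)
  } else {
    W <- similarity_matrix(m, delta)
    L <- normalized_laplacian(W)
    eig <- eigen(L, symmetric = TRUE)
    emb <- eig$vectors[, n - seq_len(k) + 1L, drop = FALSE]  # k smallest
    norms <- sqrt(rowSums(emb^2))
    norms[norms < 1e-12] <- 1
    emb <- emb / norms
    assign <- NULL
    for (attempt in 1:5) {
      km <- withr::with_seed(seed + attempt - 1L, try(
        kmeans(emb, centers = k, nstart = 10, iter.max = 100),
        silent = TRUE
      ))
      if (!inherits(km, "try-error") && all(tabulate(km$cluster, k) > 0)) {
        assign <- km$cluster
        break
      }
    }
    if (is.null(assign)) abort("k-means failed to produce k nonempty clusters")
  }
  centers <- do.call(rbind, lapply(seq_len(k), function(i) {
    colMeans(m[assign == i, , drop = FALSE])
  }))
  structure(
    list(centers = centers, assignments = as.integer(assign),
         delta = delta, k = as.integer(k), sizes = tabulate(assign, k)),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model: k = %d, n = %d, delta = %.3g>\n",
              x$k, length(x$assignments), x$delta))
  cat("sizes:", x$sizes, "\n")
  invisible(x)
}

#' @export
tidy.cluster_model <- function(x, ...) {
  tibble(cluster = seq_len(x$k), size = x$sizes)
}

#' @export
glance.cluster_model <- function(x, ...) {
  tibble(k = x$k, n = length(x$assignments), delta = x$delta,
         min_size = min(x$sizes), max_size = max(x$sizes))
}
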