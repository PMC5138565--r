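# Supervised hashing with kernels (KSH): r sign-thresholded Gaussian-kernel
# expansions over anchor samples, trained so that code inner products on a
# labeled sample approximate r * S for the pairwise label matrix S.

sgn_pm <- function(x) ifelse(x >= 0, 1, -1)  # sgn(0) = +1 by convention

cross_dist2 <- function(X, A) {
  d2 <- outer(rowSums(X^2), rowSums(A^2), "+") - 2 * X %*% t(A)
  pmax(d2, 0)
}

#' Gaussian kernel row of a feature vector against the anchors
#'
#' `kappa(x, anchor_j) = exp(-||x - anchor_j||^2 / (2 * sigma^2))` for each
#' anchor; entries lie in `(0, 1]`.
#'
#' @param x Standardized feature vector.
#' @param anchors Matrix of anchor vectors (rows).
#' @param sigma Kernel bandwidth, > 0.
#' @return Numeric vector with one entry per anchor.
#' @export
kernel_row <- function(x, anchors, sigma) {
  if (sigma <= 0) abort("sigma must be positive")
  x <- as.numeric(x)
  if (length(x) != ncol(anchors)) abort("dimension mismatch with anchors")
  d2 <- colSums((t(anchors) - x)^2)
  exp(-d2 / (2 * sigma^2))
}

kernel_matrix <- function(X, anchors, sigma) {
  exp(-cross_dist2(X, anchors) / (2 * sigma^2))
}

#' Pairwise label matrix
#'
#' `S[i, j] = +1` if images i and j share a benign/malignant label, `-1`
#' otherwise: the supervision target of the hashing objective. Symmetric
#' with a +1 diagonal.
#'
#' @param labels Vector of l class labels (l >= 2).
#' @return An `l x l` matrix with entries in `{-1, +1}`.
#' @export
build_label_matrix <- function(labels) {
  if (length(labels) < 2) abort("need at least 2 labels")
  outer(labels, labels, function(a, b) ifelse(a == b, 1, -1))
}

#' Hash-function bias
#'
#' `b = (1/n) * sum_i sum_j kappa(anchor_j, x_i) * a_j`, so that
#' `f(x) = sum_j kappa(anchor_j, x) * a_j - b` has exact mean zero over the
#' training vectors.
#'
#' @param training_kernel_rows `n x m_anchor` matrix of kernel rows of the
#'   training vectors.
#' @param a Coefficient column (length `m_anchor`).
#' @return The scalar bias.
#' @export
compute_bias <- function(training_kernel_rows, a) {
  mean(training_kernel_rows %*% a)
}

#' Train supervised kernel hash functions
#'
#' Learns `r` hash functions `h_k(x) = sgn(sum_j kappa(anchor_j, x) A[j,k] - b_k)`.
#' `m_anchor` anchors and `l` label-matrix samples are drawn by seeded
#' sampling without replacement; the `l x m_anchor` kernel matrix is centered
#' by the training kernel mean (which folds the bias into the model). Each
#' coefficient column is optimized greedily, one bit at a time, against the
#' residual target matrix (`r * S` minus the accumulated outer products of
#' the realized bit vectors): spectral-relaxation initialization (top
#' generalized eigenvector of the bit's residual objective) followed by
#' gradient ascent on a tanh-smoothed surrogate of the sign function, capped
#' at `max_iter` iterations and stopped when the relative objective change
#' drops below `tol`.
#'
#' @param X Standardized training feature matrix (or feature tibble).
#' @param labels Benign/malignant labels (0/1), one per training row.
#' @param r Code length in bits.
#' @param m_anchor Number of kernel anchors; must be < `l`.
#' @param l Number of label-matrix samples, `m_anchor < l <= n`; defaults to
#'   `min(1000, n)`.
#' @param sigma Kernel bandwidth; default is the median anchor distance over
#'   a seeded subsample.
#' @param seed Integer seed isolating all selection randomness.
#' @param max_iter,tol Gradient-refinement controls.
#' @return An object of class `ksh_model`: `anchors`, `A` (`m_anchor x r`),
#'   `sigma`, `bias` (length `r`), `r`, per-bit residual `trace`, final
#'   `objective` (the Frobenius objective of the trained code matrix), and
#'   the sampled index sets.
#' @export
train_ksh <- function(X, labels, r = 48L, m_anchor = 300L, l = NULL,
                      sigma = NULL, seed = 1L, max_iter = 500L, tol = 1e-6) {
  Xm <- feature_matrix(X)
  n <- nrow(Xm)
  l <- as.integer(l %||% min(1000L, n))
  if (r < 1) abort("r must be >= 1")
  if (l > n) abort("l must not exceed the number of training vectors")
  if (m_anchor >= l) abort("m_anchor must be smaller than l")
  sel <- withr::with_seed(seed, {
    list(anchor = sample.int(n, m_anchor),
         label = sample.int(n, l),
         sub = sample.int(n, min(500L, n)))
  })
  anchors <- Xm[sel$anchor, , drop = FALSE]
  if (is.null(sigma)) {
    d2 <- cross_dist2(Xm[sel$sub, , drop = FALSE], anchors)
    sigma <- median(sqrt(d2))
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  K_full <- kernel_matrix(Xm, anchors, sigma)
  mu_K <- colMeans(K_full)
  Kbar <- sweep(K_full[sel$label, , drop = FALSE], 2, mu_K)
  S <- build_label_matrix(labels[sel$label])
  R <- r * S

  # C^(-1/2) for the generalized eigenproblem of the spectral relaxation
  C <- crossprod(Kbar) + 1e-6 * diag(m_anchor)
  ec <- eigen(C, symmetric = TRUE)
  Chalf_inv <- ec$vectors %*% (t(ec$vectors) / sqrt(pmax(ec$values, 1e-12)))

  A <- matrix(0, m_anchor, r)
  bits <- matrix(0, l, r)
  trace <- numeric(r)
  smoothed_obj <- function(a) {
    phi <- tanh(Kbar %*% a)
    drop(crossprod(phi, R %*% phi))
  }
  for (kbit in seq_len(r)) {
    M <- crossprod(Kbar, R %*% Kbar)
    Ms <- Chalf_inv %*% M %*% Chalf_inv
    Ms <- (Ms + t(Ms)) / 2
    a <- drop(Chalf_inv %*% eigen(Ms, symmetric = TRUE)$vectors[, 1])
    v <- drop(Kbar %*% a)
    nv <- sqrt(sum(v^2))
    if (nv > 0) a <- a * sqrt(l) / nv

    # tanh-smoothed gradient ascent refinement
    obj <- smoothed_obj(a)
    step <- 1 / l
    for (it in seq_len(max_iter)) {
      phi <- tanh(Kbar %*% a)
      grad <- 2 * crossprod(Kbar, (R %*% phi) * (1 - phi^2))
      gn <- sqrt(sum(grad^2))
      if (gn < 1e-12) break
      improved <- FALSE
      for (bt in 1:20) {
        a_new <- a + step * grad / gn
        obj_new <- smoothed_obj(a_new)
        if (obj_new > obj) {
          improved <- TRUE
          break
        }
        step <- step / 2
      }
      if (!improved) break
      rel <- (obj_new - obj) / max(abs(obj), 1e-12)
      a <- drop(a_new)
      obj <- obj_new
      step <- step * 2
      if (rel < tol) break
    }

    # realized bit: keep whichever of {refined, spectral init} fits the
    # residual target better
    b_ref <- sgn_pm(drop(Kbar %*% a))
    fit <- drop(crossprod(b_ref, R %*% b_ref))
    b_cur <- b_ref
    if (fit < 0) {
      # degenerate refinement; fall back to the raw relaxation direction
      b_cur <- sgn_pm(v)
      if (drop(crossprod(b_cur, R %*% b_cur)) < fit) b_cur <- b_ref
    }
    A[, kbit] <- a
    bits[, kbit] <- b_cur
    R <- R - tcrossprod(b_cur)
    trace[kbit] <- sum(R^2)
  }

  structure(
    list(anchors = anchors, A = A, sigma = sigma,
         bias = drop(crossprod(A, mu_K)), r = as.integer(r),
         kernel_mean = mu_K, trace = trace, objective = trace[r],
         anchor_idx = sel$anchor, label_idx = sel$label,
         m_anchor = as.integer(m_anchor), l = l, seed = as.integer(seed)),
    class = "ksh_model"
  )
}

#' Encode feature vectors into hash codes
#'
#' Bit k of x is `sgn(sum_j kappa(anchor_j, x) A[j, k] - b_k)` with
#' `sgn(0) = +1`; deterministic.
#'
#' @param X Standardized feature matrix, feature tibble, or single vector
#'   (standardized with the *training* standardizer).
#' @param model A trained [train_ksh()] model.
#' @return An `n x r` matrix with entries in `{-1, +1}`.
#' @export
encode_features <- function(X, model) {
  stopifnot(inherits(model, "ksh_model"))
  Xm <- feature_matrix(X)
  if (ncol(Xm) != ncol(model$anchors)) {
    abort("feature dimension does not match the hash model")
  }
  K <- kernel_matrix(Xm, model$anchors, model$sigma)
  F_ <- K %*% model$A - rep(model$bias, each = nrow(Xm))
  sgn_pm(F_)
}

# Direct evaluation of the trained Frobenius objective
# || B B^T - r S ||_F^2 from the realized code matrix B on the l samples.
ksh_objective <- function(B, S, r) {
  sum((tcrossprod(B) - r * S)^2)
}

#' @export
print.ksh_model <- function(x, ...) {
  cat(sprintf("<ksh_model: r = %d bits, %d anchors, l = %d, sigma = %.3g>\n",
              x$r, x$m_anchor, x$l, x$sigma))
  cat(sprintf("final objective ||BB' - rS||_F^2 = %.4g\n", x$objective))
  invisible(x)
}

#' @export
tidy.ksh_model <- function(x, ...) {
  tibble(bit = seq_len(x$r), objective = x$trace)
}

#' @export
glance.ksh_model <- function(x, ...) {
  tibble(r = x$r, m_anchor = x$m_anchor, l = x$l, sigma = x$sigma,
         objective = x$objective)
}

#' @export
#' @rdname autoplot-nodulehash
autoplot.ksh_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$bit, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "hash bit", y = "residual objective",
                  title = "Greedy per-bit objective trace") +
    ggplot2::theme_minimal()
}
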