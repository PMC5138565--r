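# Internal helpers shared across modules.

# Deterministic per-item seed derived from a master seed and an index.
# Kept well below 2^31 and computed in double precision without overflow.
derive_seed <- function(master_seed, index) {
  m <- as.numeric(master_seed) %% 100003
  as.integer((m * 20011 + as.numeric(index) * 7877) %% 2147483629)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Quantize gray values in [0,1] to integer levels 1..k (equal-width bins).
quantize_gray <- function(v, k_levels) {
  pmin(as.integer(floor(v * k_levels)), k_levels - 1L) + 1L
}

# Bit counts of the bytes 0..255, for popcount-based code inner products.
popcount_byte <- as.integer(colSums(matrix(as.integer(intToBits(0:255)), nrow = 32L)))

# Separable Gaussian smoothing with edge replication; used by the synthetic
# generator to give noise a spatial correlation length.
smooth2d <- function(m, sd = 1.2, half = 2L) {
  g <- dnorm(seq(-half, half), sd = sd)
  g <- g / sum(g)
  n <- nrow(m)
  p <- ncol(m)
  out <- matrix(0, n, p)
  for (o in seq(-half, half)) {
    idx <- pmin(pmax(seq_len(n) + o, 1L), n)
    out <- out + g[o + half + 1L] * m[idx, , drop = FALSE]
  }
  m2 <- out
  out <- matrix(0, n, p)
  for (o in seq(-half, half)) {
    idx <- pmin(pmax(seq_len(p) + o, 1L), p)
    out <- out + g[o + half + 1L] * m2[, idx, drop = FALSE]
  }
  out
}

# Count 8-connected components of a logical matrix (depth-first flood fill
# on linear pixel indices).
count_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(0L)
  lab <- integer(nr * nc)
  comp <- 0L
  stack <- integer(length(idx))
  for (s0 in idx) {
    if (lab[s0] == 0L) {
      comp <- comp + 1L
      top <- 1L
      stack[1] <- s0
      lab[s0] <- comp
      while (top > 0L) {
        p <- stack[top]
        top <- top - 1L
        r <- ((p - 1L) %% nr) + 1L
        cc <- ((p - 1L) %/% nr) + 1L
        for (dc in -1:1) {
          for (dr in -1:1) {
            r2 <- r + dr
            c2 <- cc + dc
            if ((dr != 0L || dc != 0L) &&
                r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
              p2 <- (c2 - 1L) * nr + r2
              if (mask[p2] && lab[p2] == 0L) {
                lab[p2] <- comp
                top <- top + 1L
                if (top > length(stack)) stack <- c(stack, integer(length(stack)))
                stack[top] <- p2
              }
            }
          }
        }
      }
    }
  }
  comp
}

# Extract the numeric feature matrix from a feature tibble (id, label, f1..)
# or pass a matrix through unchanged.
feature_matrix <- function(x) {
  if (is.matrix(x)) {
    return(x)
  }
  if (is.data.frame(x)) {
    cols <- grep("^f[0-9]+$", names(x), value = TRUE)
    if (length(cols) == 0) {
      abort("no feature columns (f1, f2, ...) found in data frame")
    }
    m <- as.matrix(x[cols])
    rownames(m) <- if ("id" %in% names(x)) x$id else NULL
    return(m)
  }
  if (is.numeric(x)) {
    return(matrix(x, nrow = 1, dimnames = list(NULL, names(x))))
  }
  abort("expected a matrix, data frame, or numeric vector of features")
}
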