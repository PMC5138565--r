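# Independent oracles, written as plain double loops / brute force so they
# share no code path with the package implementation.

# All 14 Haralick statistics by explicit term-by-term summation.
haralick_oracle <- function(G) {
  k <- nrow(G)
  px <- numeric(k)
  py <- numeric(k)
  for (i in 1:k) {
    for (j in 1:k) {
      px[i] <- px[i] + G[i, j]
      py[j] <- py[j] + G[i, j]
    }
  }
  mu_x <- 0; mu_y <- 0
  for (i in 1:k) {
    mu_x <- mu_x + i * px[i]
    mu_y <- mu_y + i * py[i]
  }
  var_x <- 0; var_y <- 0
  for (i in 1:k) {
    var_x <- var_x + (i - mu_x)^2 * px[i]
    var_y <- var_y + (i - mu_y)^2 * py[i]
  }
  l2 <- function(p) if (p > 0) log2(p) else 0

  con <- 0; asm <- 0; ent <- 0; idm <- 0; corr_num <- 0; varss <- 0
  hxy1 <- 0
  for (i in 1:k) {
    for (j in 1:k) {
      g <- G[i, j]
      con_n <- abs(i - j)
      asm <- asm + g^2
      ent <- ent - g * l2(g)
      idm <- idm + g / (1 + (i - j)^2)
      corr_num <- corr_num + (i - mu_x) * (j - mu_y) * g
      varss <- varss + (i - mu_x)^2 * g
      hxy1 <- hxy1 - g * l2(px[i] * py[j])
    }
  }
  con <- 0
  for (n in 0:(k - 1)) {
    band <- 0
    for (i in 1:k) for (j in 1:k) if (abs(i - j) == n) band <- band + G[i, j]
    con <- con + n^2 * band
  }

  p_sum <- numeric(2 * k - 1)   # s = 2 .. 2k
  p_diff <- numeric(k)          # d = 0 .. k-1
  for (i in 1:k) {
    for (j in 1:k) {
      p_sum[i + j - 1] <- p_sum[i + j - 1] + G[i, j]
      p_diff[abs(i - j) + 1] <- p_diff[abs(i - j) + 1] + G[i, j]
    }
  }
  sum_avg <- 0
  for (s in 2:(2 * k)) sum_avg <- sum_avg + s * p_sum[s - 1]
  sum_var <- 0; sum_ent <- 0
  for (s in 2:(2 * k)) {
    sum_var <- sum_var + (s - sum_avg)^2 * p_sum[s - 1]
    sum_ent <- sum_ent - p_sum[s - 1] * l2(p_sum[s - 1])
  }
  mu_d <- 0
  for (d in 0:(k - 1)) mu_d <- mu_d + d * p_diff[d + 1]
  diff_var <- 0; diff_ent <- 0
  for (d in 0:(k - 1)) {
    diff_var <- diff_var + (d - mu_d)^2 * p_diff[d + 1]
    diff_ent <- diff_ent - p_diff[d + 1] * l2(p_diff[d + 1])
  }

  hx <- 0; hy <- 0; hxy2 <- 0
  for (i in 1:k) {
    hx <- hx - px[i] * l2(px[i])
    hy <- hy - py[i] * l2(py[i])
    for (j in 1:k) hxy2 <- hxy2 - px[i] * py[j] * l2(px[i] * py[j])
  }
  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  corr <- if (var_x > 0 && var_y > 0) corr_num / sqrt(var_x * var_y) else 0

  keep <- which(px > 0)
  mcc <- 0
  if (length(keep) >= 2) {
    Q <- matrix(0, length(keep), length(keep))
    for (ai in seq_along(keep)) {
      for (bi in seq_along(keep)) {
        for (ci in seq_along(keep)) {
          a <- keep[ai]; b <- keep[bi]; cc <- keep[ci]
          if (py[cc] > 0) {
            Q[ai, bi] <- Q[ai, bi] + G[a, cc] * G[b, cc] / (px[a] * py[cc])
          }
        }
      }
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(0, min(1, ev[2])))
  }

  c(contrast = con, asm = asm, entropy = ent, idm = idm, correlation = corr,
    variance = varss, sum_average = sum_avg, sum_variance = sum_var,
    sum_entropy = sum_ent, diff_variance = diff_var, diff_entropy = diff_ent,
    imc1 = imc1, imc2 = imc2, mcc = mcc)
}

# Random normalized symmetric co-occurrence matrix.
random_glcm <- function(k, seed) {
  withr::with_seed(seed, {
    M <- matrix(runif(k * k), k)
    G <- M + t(M)
    G / sum(G)
  })
}

# Histogram entropy by direct binning and summation.
entropy_oracle <- function(v, k) {
  bins <- pmin(floor(v * k), k - 1)
  h <- 0
  for (b in 0:(k - 1)) {
    p <- sum(bins == b) / length(v)
    if (p > 0) h <- h - p * log2(p)
  }
  h
}

# First Hu moment by raw per-pixel summation of the defining formulas.
hu_phi1_oracle <- function(mask) {
  xs <- c(); ys <- c()
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j]) { ys <- c(ys, i); xs <- c(xs, j) }
    }
  }
  m00 <- length(xs)
  xb <- sum(xs) / m00
  yb <- sum(ys) / m00
  mu20 <- sum((xs - xb)^2)
  mu02 <- sum((ys - yb)^2)
  mu20 / m00^2 + mu02 / m00^2
}

# Filled digital disk mask.
disk_mask <- function(radius, size = 4 * radius) {
  c0 <- (size + 1) / 2
  outer(seq_len(size), seq_len(size),
        function(i, j) (i - c0)^2 + (j - c0)^2 <= radius^2)
}

rotate90 <- function(m) t(m)[, seq_len(nrow(m)), drop = FALSE][, nrow(m):1, drop = FALSE]

# Exhaustive retrieval oracle: per-record +/-1 dot products and a full sort
# under the same (sim desc, cluster distance asc, id asc) total order.
exhaustive_rank_oracle <- function(db, query_features, tie_rule = "distance") {
  q_std <- drop(apply_standardizer(matrix(query_features, nrow = 1),
                                   db$standardizer))
  q_bits <- drop(encode_features(matrix(q_std, nrow = 1), db$model))
  n <- nrow(db$records)
  sims <- integer(n)
  for (i in seq_len(n)) {
    rec_bits <- unpack_code(structure(as.raw(db$packed[, i]),
                                      r = db$model$r))
    sims[i] <- sum(q_bits * rec_bits)
  }
  d_all <- numeric(nrow(db$centers))
  for (c0 in seq_len(nrow(db$centers))) {
    d_all[c0] <- sum((q_std - db$centers[c0, ])^2)
  }
  d <- d_all[db$records$cluster]
  ord <- if (tie_rule == "distance") {
    order(-sims, d, db$records$id)
  } else {
    order(-sims, db$records$id)
  }
  data.frame(id = db$records$id[ord], sim = sims[ord], d = d[ord],
             label = db$records$label[ord], stringsAsFactors = FALSE)
}

# Three well-separated seeded Gaussian blobs for clustering recovery tests.
make_blobs <- function(n_per = 20, sep = 30, sigma = 0.5, d = 5, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(3 * d), 3) * sep
    X <- do.call(rbind, lapply(1:3, function(i) {
      matrix(rnorm(n_per * d, sd = sigma), n_per, d) +
        matrix(centers[i, ], n_per, d, byrow = TRUE)
    }))
    list(X = X, labels = rep(1:3, each = n_per))
  })
}
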