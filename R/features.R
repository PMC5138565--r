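# Gray-level, medical-sign and GLCM texture features, plus assembly of the
# full 104-dimensional feature vector and the feature standardizer.

#' Feature extraction configuration
#'
#' @param k_levels Number of gray levels for histogram entropy and GLCM
#'   quantization (equal-width bins over `[0, 1]`).
#' @param glcm_distance Pixel offset of the co-occurrence pairs.
#' @param tau_cal Gray level above which a pixel counts as calcified.
#' @param tau_cav Gray level below which a pixel counts as cavitary; must be
#'   smaller than `tau_cal`.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(k_levels = 16L, glcm_distance = 1L,
                           tau_cal = 0.85, tau_cav = 0.15) {
  if (k_levels < 2) abort("k_levels must be >= 2")
  if (glcm_distance < 1) abort("glcm_distance must be >= 1")
  if (tau_cav >= tau_cal) abort("tau_cav must be smaller than tau_cal")
  structure(list(k_levels = as.integer(k_levels),
                 glcm_distance = as.integer(glcm_distance),
                 tau_cal = tau_cal, tau_cav = tau_cav),
            class = "feature_config")
}

glcm_angles <- c(0L, 45L, 90L, 135L)

#' Gray-level statistics of the lesion
#'
#' Mean, variance (population moment) and histogram entropy of the gray
#' values inside the mask (feature slots f1-f3). The entropy is
#' `-sum(p * log2(p))` over a `k_levels`-bin equal-width histogram, with
#' `0 * log 0 = 0`.
#'
#' @param img A `nodule_image`.
#' @param k_levels Number of histogram bins (>= 2).
#' @return Named vector `(mean, variance, entropy)`.
#' @export
gray_features <- function(img, k_levels = 16L) {
  if (!any(img$mask)) abort("mask has no foreground pixel")
  if (k_levels < 2) abort("k_levels must be >= 2")
  v <- img$pixels[img$mask]
  m <- mean(v)
  p <- tabulate(quantize_gray(v, k_levels), nbins = k_levels) / length(v)
  nz <- p[p > 0]
  c(mean = m,
    variance = mean((v - m)^2),
    entropy = -sum(nz * log2(nz)))
}

#' Medical sign features
#'
#' Calcification area and degree, cavitary area and ratio (feature slots
#' f16-f19): a mask pixel counts as calcified when its gray value exceeds
#' `tau_cal` and as cavitary when it falls below `tau_cav`; degrees/ratios
#' are the corresponding fractions of the mask area.
#'
#' @param img A `nodule_image`.
#' @param tau_cal,tau_cav Thresholds on the normalized gray scale,
#'   `tau_cav < tau_cal`.
#' @return Named vector `(calc_area, calc_degree, cavity_area, cavity_ratio)`.
#' @export
medical_signs <- function(img, tau_cal = 0.85, tau_cav = 0.15) {
  if (!any(img$mask)) abort("mask has no foreground pixel")
  if (tau_cav >= tau_cal) abort("tau_cav must be smaller than tau_cal")
  v <- img$pixels[img$mask]
  n <- length(v)
  calc <- sum(v > tau_cal)
  cav <- sum(v < tau_cav)
  c(calc_area = calc, calc_degree = calc / n,
    cavity_area = cav, cavity_ratio = cav / n)
}

#' Gray-level co-occurrence matrix of the lesion
#'
#' Quantizes the mask pixels to `k_levels` equal-width bins over `[0, 1]`,
#' counts ordered pixel pairs `(p, p + offset)` with **both** pixels inside
#' the mask, symmetrizes (adds the transpose) and normalizes to sum 1.
#' Offsets follow the standard GLCM convention in (row, col) steps:
#' 0 deg = (0, +d), 45 deg = (-d, +d), 90 deg = (-d, 0), 135 deg = (-d, -d).
#'
#' @param img A `nodule_image`.
#' @param k_levels Number of gray levels (>= 2).
#' @param angle One of 0, 45, 90, 135 (degrees).
#' @param distance Pixel offset (>= 1).
#' @return A `k_levels x k_levels` matrix of class `glcm` with attributes
#'   `angle` and `distance`; entries are nonnegative and sum to 1.
#' @export
compute_glcm <- function(img, k_levels = 16L, angle = 0L, distance = 1L) {
  if (k_levels < 2) abort("k_levels must be >= 2")
  if (distance < 1) abort("distance must be >= 1")
  if (!angle %in% glcm_angles) abort("angle must be one of 0, 45, 90, 135")
  d <- as.integer(distance)
  off <- switch(as.character(angle),
                "0" = c(0L, d), "45" = c(-d, d),
                "90" = c(-d, 0L), "135" = c(-d, -d))
  q <- matrix(quantize_gray(img$pixels, k_levels), nrow(img$pixels))
  nr <- nrow(q)
  nc <- ncol(q)
  r1 <- max(1L, 1L - off[1]):min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]):min(nc, nc - off[2])
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  ok <- img$mask[r1, c1, drop = FALSE] &
    img$mask[r1 + off[1], c1 + off[2], drop = FALSE]
  if (!any(ok)) abort("no valid pixel pair inside the mask for this offset")
  counts <- tabulate((a[ok] - 1L) * k_levels + b[ok], nbins = k_levels^2)
  G <- matrix(counts, nrow = k_levels, byrow = TRUE)
  G <- G + t(G)
  G <- G / sum(G)
  structure(G, class = c("glcm", "matrix", "array"),
            angle = as.integer(angle), distance = d)
}

#' Haralick statistics of a co-occurrence matrix
#'
#' The canonical set of 14 texture statistics of a normalized, symmetric
#' GLCM, with levels indexed 1..k and all entropies in bits (log base 2):
#' contrast, angular second moment, entropy, inverse difference moment,
#' correlation, variance (sum of squares), sum average, sum variance,
#' sum entropy, difference variance, difference entropy, the two information
#' measures of correlation, and the maximal correlation coefficient (square
#' root of the second-largest eigenvalue of the level-transition matrix Q).
#' Degenerate cases (zero marginal variance, single occupied level) return 0
#' for the affected correlation-type statistics.
#'
#' @param G Square matrix of co-occurrence probabilities (entries >= 0,
#'   summing to 1 within 1e-8).
#' @return Named numeric vector of the 14 statistics.
#' @export
glcm_features <- function(G) {
  G <- unclass(G)
  if (!is.matrix(G) || nrow(G) != ncol(G)) abort("G must be a square matrix")
  if (any(G < 0) || abs(sum(G) - 1) > 1e-8) {
    abort("G must be normalized: nonnegative entries summing to 1")
  }
  k <- nrow(G)
  i <- matrix(rep(seq_len(k), times = k), k)  # row index
  j <- matrix(rep(seq_len(k), each = k), k)   # col index
  px <- rowSums(G)
  py <- colSums(G)
  lv <- seq_len(k)
  mu_x <- sum(lv * px)
  mu_y <- sum(lv * py)
  sd_x <- sqrt(sum((lv - mu_x)^2 * px))
  sd_y <- sqrt(sum((lv - mu_y)^2 * py))
  xlog2 <- function(p) ifelse(p > 0, log2(p), 0)

  # diagonal-band and anti-diagonal marginals
  p_diff <- vapply(0:(k - 1), function(d) sum(G[abs(i - j) == d]), numeric(1))
  p_sum <- vapply(2:(2 * k), function(s) sum(G[(i + j) == s]), numeric(1))
  sum_avg <- sum((2:(2 * k)) * p_sum)

  ent <- -sum(G * xlog2(G))
  hx <- -sum(px * xlog2(px))
  hy <- -sum(py * xlog2(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(G * xlog2(pxy))
  hxy2 <- -sum(pxy * xlog2(pxy))

  # maximal correlation coefficient: Q(a,b) = sum_c G[a,c] G[b,c] / (px[a] py[c])
  keep <- px > 0
  if (sum(keep) >= 2) {
    Gk <- G[keep, keep, drop = FALSE]
    pyk <- py[keep]
    Qk <- matrix(0, sum(keep), sum(keep))
    for (c0 in seq_len(ncol(Gk))) {
      if (pyk[c0] > 0) {
        Qk <- Qk + outer(Gk[, c0] / px[keep], Gk[, c0] / pyk[c0])
      }
    }
    ev <- sort(Re(eigen(Qk, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- if (length(ev) >= 2) sqrt(max(0, min(1, ev[2]))) else 0
  } else {
    mcc <- 0
  }

  imc1 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  corr <- if (sd_x > 0 && sd_y > 0) {
    (sum(i * j * G) - mu_x * mu_y) / (sd_x * sd_y)
  } else 0

  c(
    contrast = sum((0:(k - 1))^2 * p_diff),
    asm = sum(G^2),
    entropy = ent,
    idm = sum(G / (1 + (i - j)^2)),
    correlation = corr,
    variance = sum((i - mu_x)^2 * G),
    sum_average = sum_avg,
    sum_variance = sum(((2:(2 * k)) - sum_avg)^2 * p_sum),
    sum_entropy = -sum(p_sum * xlog2(p_sum)),
    diff_variance = sum(((0:(k - 1)) - sum((0:(k - 1)) * p_diff))^2 * p_diff),
    diff_entropy = -sum(p_diff * xlog2(p_diff)),
    imc1 = imc1,
    imc2 = imc2,
    mcc = mcc
  )
}

#' GLCM texture block (84 values)
#'
#' The 14 Haralick statistics at the four standard angles (0, 45, 90,
#' 135 degrees; angle-major order), followed by the per-statistic mean and
#' per-statistic population variance across the four angles — feature slots
#' f21-f104.
#'
#' @param img A `nodule_image`.
#' @param k_levels Number of gray levels.
#' @param distance Co-occurrence pixel offset.
#' @return Named numeric vector of length 84.
#' @export
texture_block <- function(img, k_levels = 16L, distance = 1L) {
  per_angle <- vapply(glcm_angles, function(a) {
    glcm_features(compute_glcm(img, k_levels, a, distance))
  }, numeric(14))  # 14 x 4
  means <- rowMeans(per_angle)
  vars <- rowMeans((per_angle - means)^2)
  vals <- c(as.vector(per_angle), means, vars)
  names(vals) <- c(
    as.vector(outer(rownames(per_angle), glcm_angles,
                    function(f, a) paste0(f, "_", a))),
    paste0(rownames(per_angle), "_mean"),
    paste0(rownames(per_angle), "_var")
  )
  vals
}

#' Names of the 104 feature vector components
#'
#' @return Character vector `f1` ... `f104`.
#' @export
feature_names <- function() paste0("f", 1:104)

#' Human-readable dictionary of the 104 features
#'
#' @return A tibble with columns `name`, `group`, `description`.
#' @export
feature_dictionary <- function() {
  tex <- texture_stat_names()
  tibble(
    name = feature_names(),
    group = c(rep("gray", 3), rep("morphology", 17), rep("texture", 84)),
    description = c(
      "gray mean", "gray variance", "gray entropy (bits)",
      paste0("Hu invariant moment phi", 1:7),
      "perimeter", "area", "max diameter", "rectangularity", "roundness",
      "calcification area", "calcification degree",
      "cavitary area", "cavitary ratio",
      "boundary Fourier descriptor (harmonics 2-8 energy)",
      tex
    )
  )
}

texture_stat_names <- function() {
  stats14 <- c("contrast", "asm", "entropy", "idm", "correlation", "variance",
               "sum_average", "sum_variance", "sum_entropy", "diff_variance",
               "diff_entropy", "imc1", "imc2", "mcc")
  c(as.vector(outer(stats14, glcm_angles,
                    function(f, a) paste0("glcm ", f, " @", a, "deg"))),
    paste0("glcm ", stats14, " mean over angles"),
    paste0("glcm ", stats14, " variance over angles"))
}

#' Compute the full 104-dimensional feature vector of one image
#'
#' Concatenates, in fixed order: gray statistics (f1-f3), Hu moments
#' (f4-f10), geometric features (f11-f15), medical signs (f16-f19), the
#' boundary Fourier descriptor (f20), and the GLCM texture block (f21-f104).
#'
#' @param img A `nodule_image`.
#' @param config A [feature_config()].
#' @return Named numeric vector of length 104 (`f1` ... `f104`), all finite.
#' @export
compute_feature_vector <- function(img, config = feature_config()) {
  v <- c(
    gray_features(img, config$k_levels),
    hu_moments(img$mask),
    geometric_features(img$mask),
    medical_signs(img, config$tau_cal, config$tau_cav),
    fourier = fourier_descriptor(img$mask),
    texture_block(img, config$k_levels, config$glcm_distance)
  )
  if (length(v) != 104 || any(!is.finite(v))) {
    abort("feature vector must have 104 finite components")
  }
  names(v) <- feature_names()
  v
}

#' Extract features for a list of images
#'
#' Data-frame front end of the feature extractor: one row per image with its
#' id, label and the 104 feature columns.
#'
#' @param images List of `nodule_image` objects.
#' @param config A [feature_config()].
#' @return A tibble with columns `id`, `label`, `f1` ... `f104`.
#' @export
#' @examples
#' imgs <- generate_dataset(2, 2, master_seed = 1)
#' feats <- extract_features(imgs)
#' dim(feats)
extract_features <- function(images, config = feature_config()) {
  rows <- purrr::map(images, function(img) {
    v <- compute_feature_vector(img, config)
    dplyr::bind_cols(tibble(id = img$id, label = img$label),
                     as_tibble(as.list(v)))
  })
  dplyr::bind_rows(rows)
}

#' Fit / apply a feature standardizer
#'
#' `fit_standardizer()` learns per-component center (mean) and scale
#' (standard deviation; components with zero variance get scale 1 so they
#' pass through centering unchanged). `apply_standardizer()` maps feature
#' rows to z-scores and `invert_standardizer()` undoes the mapping. Needed
#' because the 104 features mix wildly different scales (pixel counts vs.
#' probabilities) while the similarity, kernel and pruning distances are all
#' Euclidean.
#'
#' @param x Feature tibble (columns `f1` ...) or numeric matrix with at
#'   least 2 rows.
#' @return An object of class `nodule_standardizer`.
#' @export
fit_standardizer <- function(x) {
  m <- feature_matrix(x)
  if (nrow(m) < 2) abort("need at least 2 feature vectors to fit a standardizer")
  center <- colMeans(m)
  scale <- apply(m, 2, sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  structure(list(center = center, scale = scale, names = colnames(m)),
            class = "nodule_standardizer")
}

#' @rdname fit_standardizer
#' @param std A fitted `nodule_standardizer`.
#' @export
apply_standardizer <- function(x, std) {
  stopifnot(inherits(std, "nodule_standardizer"))
  m <- feature_matrix(x)
  if (ncol(m) != length(std$center)) {
    abort("feature dimension does not match the fitted standardizer")
  }
  sweep(sweep(m, 2, std$center), 2, std$scale, "/")
}

#' @rdname fit_standardizer
#' @export
invert_standardizer <- function(x, std) {
  stopifnot(inherits(std, "nodule_standardizer"))
  m <- feature_matrix(x)
  sweep(sweep(m, 2, std$scale, "*"), 2, std$center, "+")
}
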