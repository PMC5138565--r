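#' Parameters for the synthetic nodule generator
#'
#' Bundles the knobs of the two-class synthetic nodule-image generator.
#' `irregularity` and `texture_sigma` are *upper bounds*: each generated image
#' draws its own amplitude from the low end of the range for the benign class
#' (smooth, round) and the high end for the malignant class (irregular, rough).
#'
#' @param base_radius Nominal lesion radius in pixels.
#' @param irregularity Maximum radial-perturbation amplitude, in `[0, 1)`.
#'   Zero gives a perfect digital disk.
#' @param texture_sigma Maximum interior gray-noise standard deviation, in
#'   `[0, 1]` on the normalized gray scale.
#' @param calc_prob Probability that a small bright (>= 0.9) calcification
#'   disk is stamped inside the lesion.
#' @param cavity_prob Probability that a small dark (<= 0.1) cavity disk is
#'   stamped inside the lesion.
#' @param image_size Image side length in pixels; must be at least
#'   `4 * base_radius` so the lesion fits with margin.
#' @param seed Integer seed making a single image reproducible.
#'
#' @return A list of class `nodule_params`.
#' @export
#' @examples
#' p <- nodule_params(seed = 7)
#' img <- generate_nodule(0, p)
nodule_params <- function(base_radius = 14, irregularity = 0.55,
                          texture_sigma = 0.35, calc_prob = 0.25,
                          cavity_prob = 0.25, image_size = 64, seed = 1L) {
  if (image_size < 4 * base_radius) {
    abort("image_size must be >= 4 * base_radius so the lesion fits with margin")
  }
  for (nm in c("calc_prob", "cavity_prob", "texture_sigma")) {
    v <- get(nm)
    if (v < 0 || v > 1) abort(paste0(nm, " must lie in [0, 1]"))
  }
  if (irregularity < 0 || irregularity >= 1) {
    abort("irregularity must lie in [0, 1) so the boundary never self-intersects")
  }
  structure(
    list(base_radius = base_radius, irregularity = irregularity,
         texture_sigma = texture_sigma, calc_prob = calc_prob,
         cavity_prob = cavity_prob, image_size = as.integer(image_size),
         seed = as.integer(seed)),
    class = "nodule_params"
  )
}

new_nodule_image <- function(pixels, mask, label, id) {
  stopifnot(is.matrix(pixels), is.matrix(mask),
            all(dim(pixels) == dim(mask)))
  if (!any(mask)) abort("mask has no foreground pixel")
  structure(
    list(pixels = pixels, mask = mask, label = as.integer(label), id = id),
    class = "nodule_image"
  )
}

#' Construct a nodule image from raw matrices
#'
#' Validates the per-image invariants: pixel values in `[0, 1]`, identical
#' pixel/mask shapes, a nonempty mask with exactly one 8-connected component.
#'
#' @param pixels Gray-level matrix with values in `[0, 1]`.
#' @param mask Logical (or 0/1) matrix of the same shape.
#' @param label 0 (benign) or 1 (malignant).
#' @param id Image identifier.
#' @return A `nodule_image` object.
#' @export
nodule_image <- function(pixels, mask, label = 0L, id = "img") {
  mask <- mask > 0.5
  if (any(pixels < 0 | pixels > 1)) abort("pixels must lie in [0, 1]")
  if (!any(mask)) abort("mask has no foreground pixel")
  if (count_components(mask) != 1) {
    abort("mask must have exactly one connected component")
  }
  new_nodule_image(pixels, mask, label, id)
}

#' @export
print.nodule_image <- function(x, ...) {
  cat(sprintf("<nodule_image %s: %dx%d px, area %d, label %d (%s)>\n",
              x$id, nrow(x$pixels), ncol(x$pixels), sum(x$mask), x$label,
              if (x$label == 0) "benign" else "malignant"))
  invisible(x)
}

#' Generate one synthetic nodule image
#'
#' Draws a star-convex lesion whose boundary radius is
#' `base_radius * (1 + a * sum of low-order sinusoids)` with seeded random
#' phases, fills the interior with spatially smoothed gray noise, and
#' optionally stamps a bright calcification spot or a dark cavity. The benign
#' class (label 0) draws its irregularity amplitude and noise scale from the
#' low end of the configured ranges, the malignant class (label 1) from the
#' high end, so shape and texture features separate the classes.
#'
#' The output is bit-identical for identical `(class_label, params$seed)`.
#'
#' @param class_label 0 (benign) or 1 (malignant).
#' @param params A [nodule_params()] object.
#'
#' @return A `nodule_image`: list with `pixels` (gray matrix in `[0,1]`),
#'   `mask` (logical matrix, one connected component), `label`, `id`.
#' @export
generate_nodule <- function(class_label, params = nodule_params()) {
  if (!is.numeric(class_label) || length(class_label) != 1 ||
      !(class_label %in% c(0, 1))) {
    abort("class_label must be 0 (benign) or 1 (malignant)")
  }
  stopifnot(inherits(params, "nodule_params"))
  withr::with_seed(params$seed, {
    n <- params$image_size
    R <- params$base_radius
    if (class_label == 0) {
      irr <- runif(1, 0.00, 0.30) * params$irregularity
      tex <- runif(1, 0.10, 0.35) * params$texture_sigma
    } else {
      irr <- runif(1, 0.55, 1.00) * params$irregularity
      tex <- runif(1, 0.60, 1.00) * params$texture_sigma
    }

    # star-convex boundary: low-order sinusoids, amplitudes normalized so the
    # total perturbation never exceeds irr (hence radius stays positive)
    harmonics <- 2:6
    amps <- runif(length(harmonics), 0.3, 1)
    amps <- amps / sum(amps)
    phases <- runif(length(harmonics), 0, 2 * pi)
    radius_fun <- function(theta) {
      pert <- rep(0, length(theta))
      for (h in seq_along(harmonics)) {
        pert <- pert + amps[h] * cos(harmonics[h] * theta + phases[h])
      }
      R * (1 + irr * pert)
    }

    cx <- (n + 1) / 2
    cy <- (n + 1) / 2
    xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
    ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
    dx <- xs - cx
    dy <- ys - cy
    rho <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)
    mask <- rho <= radius_fun(theta)

    base <- runif(1, 0.45, 0.60)
    noise <- smooth2d(matrix(rnorm(n * n), n, n))
    noise <- noise / sd(noise)
    pixels <- matrix(0.08, n, n)
    pixels[mask] <- clamp01(base + tex * noise[mask])

    stamp <- function(pixels, value_lo, value_hi) {
      ang <- runif(1, 0, 2 * pi)
      rad <- runif(1, 0, 0.4) * R
      scx <- cx + rad * cos(ang)
      scy <- cy + rad * sin(ang)
      srad <- runif(1, 1.5, max(2, 0.25 * R))
      inside <- mask & ((xs - scx)^2 + (ys - scy)^2 <= srad^2)
      pixels[inside] <- runif(1, value_lo, value_hi)
      pixels
    }
    if (runif(1) < params$calc_prob) pixels <- stamp(pixels, 0.92, 1.00)
    if (runif(1) < params$cavity_prob) pixels <- stamp(pixels, 0.00, 0.08)

    new_nodule_image(pixels, mask, class_label,
                     sprintf("%s%08d", if (class_label == 0) "b" else "m",
                             params$seed %% 100000000L))
  })
}

#' Generate a labeled synthetic dataset
#'
#' Per-image seeds are derived deterministically from `master_seed` and the
#' image index, so datasets are reproducible and extensible.
#'
#' @param n_benign,n_malignant Number of images per class (>= 0).
#' @param master_seed Integer master seed.
#' @param params [nodule_params()] template; its `seed` field is overridden
#'   per image.
#'
#' @return A list of `nodule_image` objects, benign first, with unique ids.
#' @export
#' @examples
#' imgs <- generate_dataset(3, 5, master_seed = 42)
#' table(vapply(imgs, function(x) x$label, integer(1)))
generate_dataset <- function(n_benign, n_malignant, master_seed = 1L,
                             params = nodule_params()) {
  stopifnot(n_benign >= 0, n_malignant >= 0)
  labels <- c(rep(0L, n_benign), rep(1L, n_malignant))
  purrr::imap(labels, function(lab, i) {
    p <- params
    p$seed <- derive_seed(master_seed, i)
    img <- generate_nodule(lab, p)
    img$id <- sprintf("s%d_%s%05d", master_seed, if (lab == 0) "b" else "m", i)
    img
  })
}

#' Write a dataset of nodule images to disk
#'
#' Writes `<id>_img.png` and `<id>_mask.png` (8-bit grayscale PNG) plus a
#' `labels.csv` with columns `id,label`.
#'
#' @param images List of `nodule_image` objects.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(images, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (img in images) {
    png::writePNG(img$pixels, file.path(dir, paste0(img$id, "_img.png")))
    png::writePNG(img$mask * 1, file.path(dir, paste0(img$id, "_mask.png")))
  }
  labs <- data.frame(id = vapply(images, function(x) x$id, character(1)),
                     label = vapply(images, function(x) x$label, integer(1)))
  write.csv(labs, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a dataset of nodule images from disk
#'
#' Counterpart of [write_dataset()]: expects `labels.csv` and per-id
#' `<id>_img.png` / `<id>_mask.png` grayscale files.
#'
#' @param dir Directory written by [write_dataset()] (or following its layout).
#' @return A list of `nodule_image` objects.
#' @export
read_dataset <- function(dir) {
  labs <- read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  purrr::map2(labs$id, labs$label, function(id, label) {
    px <- png::readPNG(file.path(dir, paste0(id, "_img.png")))
    mk <- png::readPNG(file.path(dir, paste0(id, "_mask.png")))
    if (length(dim(px)) == 3) px <- px[, , 1]
    if (length(dim(mk)) == 3) mk <- mk[, , 1]
    new_nodule_image(px, mk > 0.5, label, id)
  })
}

#' Label table of a dataset
#'
#' @param images List of `nodule_image` objects.
#' @return A tibble with columns `id` and `label`.
#' @export
dataset_labels <- function(images) {
  tibble(id = vapply(images, function(x) x$id, character(1)),
         label = vapply(images, function(x) x$label, integer(1)))
}

#' @export
#' @rdname autoplot-nodulehash
autoplot.nodule_image <- function(object, ...) {
  n <- nrow(object$pixels)
  df <- tibble(
    row = rep(seq_len(n), times = ncol(object$pixels)),
    col = rep(seq_len(ncol(object$pixels)), each = n),
    gray = as.vector(object$pixels),
    mask = as.vector(object$mask)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$gray)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("%s (label %d)", object$id, object$label),
                  x = NULL, y = NULL, fill = "gray") +
    ggplot2::theme_minimal()
}
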