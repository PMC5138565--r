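# Shape descriptors of the binary lesion mask: boundary tracing, Hu invariant
# moments, geometric features (perimeter, area, diameter, rectangularity,
# roundness) and the boundary Fourier descriptor.

# Moore-neighbour boundary tracing (8-connectivity, clockwise) returning the
# ordered closed contour as a matrix of (row, col) pixel coordinates. The
# start pixel is the top-most, then left-most foreground pixel; the trace
# stops when the start is re-entered with the starting backtrack position
# (Jacob's stopping criterion), with a hard iteration cap for safety.
trace_boundary <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  fg <- which(mask, arr.ind = TRUE)
  if (nrow(fg) == 0) abort("mask has no foreground pixel")
  start <- as.integer(fg[order(fg[, 1], fg[, 2]), , drop = FALSE][1, ])
  if (nrow(fg) == 1) {
    return(matrix(start, ncol = 2, dimnames = list(NULL, c("row", "col"))))
  }
  # clockwise Moore neighbourhood in (dr, dc), starting West
  nb <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L,
                 0L, 1L,  1L, 1L,  1L, 0L,  1L, -1L),
               ncol = 2, byrow = TRUE)
  nb_index <- function(d) which(nb[, 1] == d[1] & nb[, 2] == d[2])
  inside <- function(p) p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc &&
    mask[p[1], p[2]]
  b0 <- start + c(0L, -1L)  # West neighbour, background by the scan order
  cur <- start
  back <- b0
  path <- matrix(0L, nrow = 8L * nrow(fg) + 8L, ncol = 2)
  path[1, ] <- start
  np <- 1L
  repeat {
    bi <- nb_index(back - cur)
    found <- FALSE
    last_bg <- back
    for (s in 1:8) {
      d <- ((bi - 1L + s) %% 8L) + 1L
      cand <- cur + nb[d, ]
      if (inside(cand)) {
        found <- TRUE
        break
      }
      last_bg <- cand
    }
    if (!found) break  # isolated pixel relative to this component
    back <- last_bg
    cur <- cand
    if (cur[1] == start[1] && cur[2] == start[2] &&
        back[1] == b0[1] && back[2] == b0[2]) {
      break  # closed the contour
    }
    np <- np + 1L
    if (np > nrow(path)) break  # safety cap; cannot occur for valid masks
    path[np, ] <- cur
  }
  structure(path[seq_len(np), , drop = FALSE],
            dimnames = list(NULL, c("row", "col")))
}

# Contour length of the traced closed boundary: unit steps count 1, diagonal
# steps sqrt(2). A single-pixel mask gets the perimeter of its unit square.
contour_perimeter <- function(boundary) {
  n <- nrow(boundary)
  if (n == 1) return(4)
  nxt <- rbind(boundary[-1, , drop = FALSE], boundary[1, , drop = FALSE])
  steps <- sqrt(rowSums((nxt - boundary)^2))
  sum(steps)
}

#' Hu invariant moments of a binary mask
#'
#' The seven rotation/translation/scale-invariant functions of the normalized
#' central moments of the foreground pixel set, used as shape descriptors of
#' the lesion mask (feature slots f4-f10).
#'
#' @param mask Logical matrix with at least one `TRUE` pixel.
#' @return Named numeric vector `phi1` ... `phi7`.
#' @export
hu_moments <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0) abort("mask has no foreground pixel")
  y <- pts[, 1]
  x <- pts[, 2]
  xb <- mean(x)
  yb <- mean(y)
  mu <- function(p, q) sum((x - xb)^p * (y - yb)^q)
  m00 <- nrow(pts)
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  c(
    phi1 = n20 + n02,
    phi2 = (n20 - n02)^2 + 4 * n11^2,
    phi3 = (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    phi4 = (n30 + n12)^2 + (n21 + n03)^2,
    phi5 = (n30 - 3 * n12) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
      (3 * n21 - n03) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2),
    phi6 = (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
      4 * n11 * (n30 + n12) * (n21 + n03),
    phi7 = (3 * n21 - n03) * (n30 + n12) *
      ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
      (n30 - 3 * n12) * (n21 + n03) *
      (3 * (n30 + n12)^2 - (n21 + n03)^2)
  )
}

# Minimum-area rotated bounding rectangle over a point set, by rotating
# calipers on the convex hull. Returns the rectangle area.
min_rect_area <- function(x, y) {
  h <- grDevices::chull(x, y)
  hx <- x[h]
  hy <- y[h]
  nh <- length(h)
  if (nh < 3) {
    return((max(x) - min(x)) * (max(y) - min(y)))
  }
  best <- Inf
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    ex <- hx[j] - hx[i]
    ey <- hy[j] - hy[i]
    len <- sqrt(ex^2 + ey^2)
    if (len == 0) next
    ux <- ex / len
    uy <- ey / len
    pu <- hx * ux + hy * uy
    pv <- -hx * uy + hy * ux
    area <- (max(pu) - min(pu)) * (max(pv) - min(pv))
    if (area < best) best <- area
  }
  best
}

#' Geometric shape features of a lesion mask
#'
#' Returns the five geometric descriptors (feature slots f11-f15):
#' `perimeter` (traced boundary length, diagonal steps weighted sqrt(2)),
#' `area` (foreground pixel count), `max_diameter` (largest pairwise distance
#' between boundary pixel centres), `rectangularity` (area divided by the
#' area of the minimum rotated bounding rectangle of the pixel squares), and
#' `roundness` F = 4 * pi * A / L^2, which is 1 for a perfect circle and
#' smaller for irregular boundaries.
#'
#' @param mask Logical matrix; must be nonempty and a single 8-connected
#'   component.
#' @return Named numeric vector of the five features.
#' @export
geometric_features <- function(mask) {
  if (!any(mask)) abort("mask has no foreground pixel")
  if (count_components(mask) != 1) {
    abort("mask must have exactly one connected component")
  }
  area <- sum(mask)
  boundary <- trace_boundary(mask)
  bp <- unique(boundary)
  perimeter <- contour_perimeter(boundary)
  max_diameter <- if (nrow(bp) < 2) 0 else max(stats::dist(bp))
  # rectangle over pixel *squares*: each foreground pixel contributes its four
  # corners, so an axis-aligned filled n x n square scores exactly 1
  cx <- c(bp[, 2] - 0.5, bp[, 2] + 0.5, bp[, 2] - 0.5, bp[, 2] + 0.5)
  cy <- c(bp[, 1] - 0.5, bp[, 1] - 0.5, bp[, 1] + 0.5, bp[, 1] + 0.5)
  rect <- min_rect_area(cx, cy)
  c(perimeter = perimeter,
    area = area,
    max_diameter = max_diameter,
    rectangularity = area / rect,
    roundness = 4 * pi * area / perimeter^2)
}

#' Boundary Fourier descriptor of a lesion mask
#'
#' Traces the closed boundary as a complex sequence, takes its discrete
#' Fourier transform, normalizes coefficient magnitudes by the magnitude of
#' the first harmonic, and reports the energy in harmonics 2-8 as a single
#' scalar irregularity measure (feature slot f20). The value is invariant to
#' translation, scale, rotation and the starting point of the trace; a
#' near-circular boundary concentrates its energy in harmonic 1 and scores
#' close to 0.
#'
#' @param mask Logical matrix; single component with at least 8 boundary
#'   pixels.
#' @return A scalar, non-negative.
#' @export
fourier_descriptor <- function(mask) {
  if (!any(mask)) abort("mask has no foreground pixel")
  boundary <- trace_boundary(mask)
  n <- nrow(boundary)
  if (n < 8) abort("boundary too short for a Fourier descriptor (need >= 8 pixels)")
  z <- complex(real = boundary[, 2], imaginary = boundary[, 1])
  Z <- fft(z)
  h1 <- Mod(Z[2])
  if (h1 == 0) return(0)
  hs <- 2:min(8, n - 2)
  sum((Mod(Z[hs + 1]) / h1)^2)
}
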