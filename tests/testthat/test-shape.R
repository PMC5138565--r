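test_that("Hu moments are invariant to translation and 90-degree rotation", {
  mask <- disk_mask(8, 40)
  mask[10:14, 22:30] <- TRUE  # break the symmetry a bit
  mask <- mask | rotate90(disk_mask(8, 40))
  h0 <- hu_moments(mask)

  shifted <- matrix(FALSE, 48, 48)
  shifted[5 + seq_len(40), 3 + seq_len(40)] <- mask
  expect_equal(hu_moments(shifted), h0, tolerance = 1e-12)

  expect_equal(unname(hu_moments(rotate90(mask))), unname(h0),
               tolerance = 1e-6)
})

test_that("Hu moments are scale invariant on upsampled masks", {
  mask <- disk_mask(7, 32)
  mask[8:12, 20:26] <- TRUE
  big <- kronecker(mask, matrix(TRUE, 4, 4)) > 0
  h1 <- hu_moments(mask)
  h4 <- hu_moments(big)
  expect_lt(max(abs(h1 - h4)), 1e-2)
})

test_that("phi1 of a 3x3 cross matches raw moment summation", {
  cross <- matrix(FALSE, 3, 3)
  cross[2, ] <- TRUE
  cross[, 2] <- TRUE
  expect_equal(hu_moments(cross)[["phi1"]], hu_phi1_oracle(cross))
  expect_error(hu_moments(matrix(FALSE, 3, 3)), "foreground")
})

test_that("geometric features behave on canonical shapes", {
  g <- geometric_features(disk_mask(32, 140))
  expect_gt(g[["roundness"]], 0.9)
  expect_lt(g[["roundness"]], 1.1)
  expect_equal(g[["area"]], sum(disk_mask(32, 140)))

  sq <- matrix(FALSE, 20, 20)
  sq[5:14, 7:16] <- TRUE
  expect_equal(geometric_features(sq)[["rectangularity"]], 1.0)

  two <- matrix(FALSE, 10, 10)
  two[2, 2] <- TRUE
  two[8, 8] <- TRUE
  expect_error(geometric_features(two), "one connected component")
})

test_that("max diameter equals the brute-force pairwise maximum on an L-shape", {
  L <- matrix(FALSE, 8, 8)
  L[2:6, 2] <- TRUE   # 5 pixels down
  L[6, 3:4] <- TRUE   # 2 pixels right
  g <- geometric_features(L)
  pts <- which(L, arr.ind = TRUE)
  best <- 0
  for (i in seq_len(nrow(pts))) {
    for (j in seq_len(nrow(pts))) {
      best <- max(best, sqrt(sum((pts[i, ] - pts[j, ])^2)))
    }
  }
  expect_equal(g[["max_diameter"]], best)
})

test_that("roundness decreases with the generator irregularity knob", {
  mean_roundness <- function(irr) {
    vals <- vapply(1:8, function(s) {
      p <- nodule_params(irregularity = irr, texture_sigma = 0, calc_prob = 0,
                         cavity_prob = 0, seed = 100 + s)
      geometric_features(generate_nodule(1, p)$mask)[["roundness"]]
    }, numeric(1))
    mean(vals)
  }
  r_lo <- mean_roundness(0.1)
  r_mid <- mean_roundness(0.4)
  r_hi <- mean_roundness(0.7)
  expect_gt(r_lo, r_mid)
  expect_gt(r_mid, r_hi)
})

test_that("Fourier descriptor is small for disks and scale invariant", {
  disk <- disk_mask(20, 90)
  fd <- fourier_descriptor(disk)
  expect_lt(fd, 0.05)

  small <- disk_mask(9, 40)
  small[12:16, 25:31] <- TRUE
  big <- kronecker(small, matrix(TRUE, 2, 2)) > 0
  expect_lt(abs(fourier_descriptor(small) - fourier_descriptor(big)), 0.02)

  expect_error(fourier_descriptor(matrix(c(FALSE, TRUE, FALSE, FALSE), 2, 2)),
               "boundary too short")
})

test_that("Fourier descriptor grows with boundary irregularity", {
  for (s in 1:5) {
    m0 <- generate_nodule(0, nodule_params(irregularity = 0, texture_sigma = 0,
                                           calc_prob = 0, cavity_prob = 0,
                                           seed = s))$mask
    m3 <- generate_nodule(1, nodule_params(irregularity = 0.3, texture_sigma = 0,
                                           calc_prob = 0, cavity_prob = 0,
                                           seed = s))$mask
    expect_gt(fourier_descriptor(m3), fourier_descriptor(m0))
  }
})
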