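test_that("vesselness vanishes on constant images", {
  vf <- frangi_vesselness(matrix(3.7, 64, 64))
  expect_true(all(vf$vesselness == 0))
  expect_true(all(is.na(vf$orientation_deg)))
})

test_that("orientation on an analytic ridge matches its angle", {
  # oracle: closed-form Gaussian-profile ridge; on the centreline the
  # Hessian's weak eigenvector points along the ridge, so the recovered
  # orientation must equal the construction angle
  for (theta in c(0, 30, -60, 85)) {
    rd <- analytic_ridge(theta, width = 1.5)
    vf <- frangi_vesselness(rd$image)
    interior <- abs(rd$dist) < 0.7
    interior[c(1:15, 114:128), ] <- FALSE
    interior[, c(1:15, 114:128)] <- FALSE
    ang <- vf$orientation_deg[interior]
    expect_true(all(is.finite(ang)))
    expect_lt(max(axial_difference(ang, theta)), 3)
    # centreline response exceeds any off-ridge response
    expect_gt(min(vf$vesselness[interior]),
              max(vf$vesselness[abs(rd$dist) > 6]))
  }
})

test_that("blob response is suppressed relative to an equal-contrast ridge", {
  # at a blob centre both eigenvalues are equal (R_B = 1), so the blobness
  # term must suppress the response
  rd <- analytic_ridge(20, width = 1.5)
  bl <- analytic_blob(width = 1.5)
  v_ridge <- frangi_vesselness(rd$image)$vesselness[64, 64]
  v_blob <- frangi_vesselness(bl)$vesselness[64, 64]
  expect_lt(v_blob, 0.5 * v_ridge)
})

test_that("vesselness rejects invalid input", {
  img <- matrix(1, 8, 8); img[3, 3] <- NA
  expect_error(frangi_vesselness(img), "finite")
  expect_error(frangi_vesselness(matrix(1, 8, 8), scales = -1), "positive")
  expect_error(frangi_vesselness(matrix(1, 8, 8), beta = 0), "beta")
})

test_that("alignment fraction counts strictly within the cutoff", {
  rd <- analytic_ridge(10)
  vf <- frangi_vesselness(rd$image)
  res <- alignment_fraction(vf, 10)
  expect_gt(res$percent_aligned, 99)
  res45 <- alignment_fraction(vf, 55)     # 45 degrees away: outside the band
  expect_lt(res45$percent_aligned, 1)
  # empty support is flagged undefined, not zero
  none <- alignment_fraction(vf, 0, threshold = 0.999)
  expect_true(none$undefined)
  expect_true(is.na(none$percent_aligned))
  expect_error(alignment_fraction(vf, 0, cutoff_deg = 90), "cutoff")
  expect_error(alignment_fraction(vf, 0, threshold = 0), "threshold")
})

test_that("restrict_mask limits the support", {
  rd <- analytic_ridge(0)
  vf <- frangi_vesselness(rd$image)
  m <- matrix(FALSE, 128, 128); m[, 1:64] <- TRUE
  res <- alignment_fraction(vf, 0, restrict_mask = m)
  full <- alignment_fraction(vf, 0)
  expect_lt(res$n_support_pixels, full$n_support_pixels)
})

test_that("alignment is equivariant under 90-degree rotation and axially invariant", {
  f <- generate_neurite_field(60, c(256, 256), seed = 4)
  vf <- frangi_vesselness(f$image)
  base <- alignment_fraction(vf, 15)$percent_aligned
  vr <- frangi_vesselness(neuritescreen:::rot90_ccw(f$image))
  rot <- alignment_fraction(vr, wrap_axial(15 + 90))$percent_aligned
  expect_lt(abs(base - rot), 1)
  # adding 180 to every orientation changes nothing (exact)
  vf2 <- vf
  vf2$orientation_deg <- wrap_axial(vf$orientation_deg + 180)
  expect_equal(alignment_fraction(vf2, 15)$percent_aligned, base)
})

test_that("alignment tracks the aligned fraction of a neurite field", {
  # closed-form mixture expectation, concentrated component sd 5 degrees;
  # stratified draws pin the field's true aligned fraction to f
  p_c <- mean(abs(wrap_axial(rnorm(1e5, 0, 5))) < 30)
  meas <- vapply(c(0, 0.5, 1), function(f) {
    set.seed(40 + f * 10)
    k <- round(80 * f)
    ang <- c(wrap_axial(rnorm(k, 0, 5)), runif(80 - k, -90, 90))
    nf <- generate_neurite_field(80, c(384, 384), angles = ang,
                                 seed = 40 + f * 10)
    alignment_fraction(frangi_vesselness(neuritescreen:::norm01(nf$image)),
                       0)$percent_aligned
  }, numeric(1))
  expected <- 100 * (c(0, 0.5, 1) * p_c + (1 - c(0, 0.5, 1)) / 3)
  expect_true(all(abs(meas - expected) < 7))
  expect_true(all(diff(meas) > 0))
})
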