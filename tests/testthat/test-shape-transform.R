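test_that("convex hull volume is exact on a known tetrahedron and cube", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(crtradiomics:::convex_hull_volume(tet), 1 / 6, tolerance = 1e-12)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1)) * 3
  jitter <- rbind(cube, c(1.5, 1.5, 1.5), c(0.3, 0.2, 2.9))  # interior points
  expect_equal(crtradiomics:::convex_hull_volume(jitter), 27, tolerance = 1e-9)
  coplanar <- cbind(matrix(runif(20), 10), 0)
  expect_equal(crtradiomics:::convex_hull_volume(coplanar), 0)
})

test_that("digital sphere: solidity near 1, eccentricity near 0", {
  f <- shape_features(sphere_mask(10), c(1, 1, 1))
  expect_gt(f["solidity"], 0.95)
  expect_lt(f["eccentricity"], 0.1)
  expect_equal(unname(f["volume"]), sum(sphere_mask(10)))
  # longest diameter of a radius-10 digital sphere is ~20 voxels
  expect_equal(unname(f["size"]), 20, tolerance = 0.1)
})

test_that("single voxel takes the degenerate shape conventions", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  f <- shape_features(m, c(0.97, 0.97, 2.5))
  expect_equal(unname(f), c(0.97 * 0.97 * 2.5, 0, 1, 0))
})

test_that("2:1 axis ellipsoid has eccentricity sqrt(1 - 0.25)", {
  n <- 41
  ax <- seq_len(n) - (n + 1) / 2
  d2 <- outer(outer((ax / 16)^2, (ax / 8)^2, `+`), (ax / 8)^2, `+`)
  mask <- array(d2 <= 1, c(n, n, n))
  f <- shape_features(mask, c(1, 1, 1))
  expect_equal(unname(f["eccentricity"]), sqrt(1 - 0.25), tolerance = 0.05)
})

test_that("histogram features match moment oracles and degenerate conventions", {
  r_sym <- as_quantized_roi(array(c(1L, 2L, 3L), c(3, 1, 1)), 4)
  expect_equal(unname(histogram_features(r_sym)["skewness"]), 0)
  x <- c(0, 0, 0, 0, 15)
  r <- as_quantized_roi(array(as.integer(x), c(5, 1, 1)), 4)
  mom <- bf_moments(x)
  f <- histogram_features(r)
  expect_equal(unname(f["skewness"]), mom$skew)
  expect_equal(unname(f["kurtosis"]), mom$kurt)
  expect_equal(unname(f["mean"]), mom$mean)
  rc <- as_quantized_roi(array(5L, c(4, 1, 1)), 4)
  fc <- histogram_features(rc)
  expect_equal(unname(fc[c("entropy", "energy", "skewness", "kurtosis")]),
               c(0, 1, 0, 0))
})

test_that("GLGCM: constant section puts all gradient mass in the zero bin", {
  roi <- as_quantized_roi(matrix(5L, 6, 6), 4)
  f <- glgcm_features(roi)
  expect_equal(unname(f["GradientMean"]), 1)      # 1-based bin index
  expect_equal(unname(f["GradientVariance"]), 0)
  expect_equal(unname(f["GradientEntropy"]), 0)
})

test_that("GLGCM joint histogram matches direct convolution + binning", {
  for (s in 1:5) {
    lev <- random_roi(c(7, 6), 4, seed = 200 + s)
    roi <- as_quantized_roi(lev, 4)
    got <- crtradiomics:::glgcm_histogram(roi)
    want <- bf_glgcm_hist(lev, !is.na(lev), 16)
    expect_equal(got, want)
    expect_equal(sum(got), (nrow(lev) - 2) * (ncol(lev) - 2))  # interior pixels
  }
  # vertical two-level step on a 4x4 grid: gradient mass concentrates at the step
  step <- matrix(c(0, 0, 8, 8), 4, 4, byrow = TRUE)
  H <- bf_glgcm_hist(step, array(TRUE, dim(step)), 16)
  expect_equal(crtradiomics:::glgcm_histogram(as_quantized_roi(step, 4)), H)
  expect_true(sum(H[, 2:16]) > 0)   # step pixels carry nonzero gradient
})

test_that("LoG annihilates constants and is scale-selective for Gaussian blobs", {
  const <- matrix(4.2, 20, 20)
  mask <- matrix(TRUE, 20, 20)
  f <- log_features(const, mask)
  expect_equal(unname(f["sigma1.0_variance"]), 0, tolerance = 1e-18)
  expect_equal(unname(f["sigma2.0_skewness"]), 0)
  # delta input reproduces the (flipped) kernel around the impulse
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  resp <- Re(crtradiomics:::conv2_same(imp, crtradiomics:::log_kernel(1)))
  k <- crtradiomics:::log_kernel(1)
  expect_equal(resp[11, 11], k[5, 5], tolerance = 1e-10)
  expect_equal(which(abs(resp) == max(abs(resp)), arr.ind = TRUE)[1, ],
               c(row = 11, col = 11))
  # blob of scale sigma responds most to the closest filter scale
  blob_resp <- function(sb) {
    g <- outer(seq(-15, 15), seq(-15, 15),
               function(x, y) exp(-(x^2 + y^2) / (2 * sb^2)))
    vapply(c(1, 2, 2.5), function(s)
      abs(Re(crtradiomics:::conv2_same(g, crtradiomics:::log_kernel(s)))[16, 16]),
      numeric(1))
  }
  expect_equal(which.max(blob_resp(1)), 1)
  expect_equal(which.max(blob_resp(2.5)), 3)
})

test_that("Gabor bank: zero image gives MSA 0 and MSE 0 everywhere", {
  f <- gabor_features(matrix(0, 16, 16), matrix(TRUE, 16, 16))
  expect_length(f, 80)
  expect_true(all(f == 0))
})

test_that("Gabor orientation tuning: grating maximizes MSA at its own orientation", {
  n <- 48
  freqs <- gabor_frequencies()
  mask <- matrix(TRUE, n, n)
  for (o_true in c(1, 3, 5)) {
    th <- (o_true - 1) * pi / 8
    fr <- freqs[2]
    img <- outer(seq_len(n), seq_len(n), function(x, y)
      cos(2 * pi * fr * (x * cos(th) + y * sin(th))))
    f <- gabor_features(img, mask)
    msa_scale2 <- f[sprintf("MSA-2%d", 1:8)]
    expect_equal(unname(which.max(msa_scale2)), o_true)
  }
})

test_that("feature extraction yields the full finite manifest deterministically", {
  cases <- generate_cohort(small_cohort_spec(n1 = 1, n0 = 1, seed = 21))
  man <- feature_manifest()
  fv <- extract_all(cases[[1]])
  expect_length(fv, 214)
  expect_identical(names(fv), man$name)
  expect_true(all(is.finite(fv)))
  expect_identical(fv, extract_all(cases[[1]]))
  expect_equal(sum(man$dimensionality == "3D"), 60)
  expect_equal(sum(man$dimensionality == "2D"), 154)
  # second observer's contour gives a valid, different vector
  fv2 <- extract_all(cases[[1]], observer = 2L)
  expect_true(all(is.finite(fv2)))
  expect_false(identical(fv, fv2))
})
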