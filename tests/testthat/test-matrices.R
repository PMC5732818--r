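# Worked examples and equivalence checks for the texture-matrix builders.

test_that("GLCM on the worked 3x3 image matches the enumerated pair counts", {
  # printed image rows: [0,0,1],[0,1,1],[2,2,2]; horizontal adjacency
  img <- t(matrix(c(0, 0, 1,
                    0, 1, 1,
                    2, 2, 2), 3, 3, byrow = TRUE))
  roi <- as_quantized_roi(img, k = 4)
  m <- glcm_matrix(roi, directions = list(c(1, 0)))  # along printed rows
  expect_equal(m$counts[1, 1], 2)  # (0,0)
  expect_equal(m$counts[1, 2], 2)  # (0,1)
  expect_equal(m$counts[2, 1], 2)  # (1,0)
  expect_equal(m$counts[2, 2], 2)  # (1,1)
  expect_equal(m$counts[3, 3], 4)  # (2,2)
  expect_equal(sum(m$counts), 12)
  expect_equal(sum(m$p), 1)
})

test_that("constant image: GLCM entropy 0, energy 1, contrast 0", {
  roi <- as_quantized_roi(matrix(3L, 4, 4), k = 4)
  f <- glcm_features(glcm_matrix(roi), glcm_feature_names_2d)
  expect_equal(unname(f["Entropy"]), 0)
  expect_equal(unname(f["Energy"]), 1)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["Correlation"]), 0)  # constant-image convention
})

test_that("checkerboard horizontal GLCM: contrast 1, energy 0.5", {
  img <- outer(1:6, 1:6, function(i, j) (i + j) %% 2)
  roi <- as_quantized_roi(img, k = 4)
  f <- glcm_features(glcm_matrix(roi, directions = list(c(1, 0))),
                     glcm_feature_names_2d)
  expect_equal(unname(f["Contrast"]), 1)
  expect_equal(unname(f["Energy"]), 0.5)
})

test_that("run enumeration oracle: worked rows", {
  r1 <- bf_glrlm(matrix(c(0, 0, 0, 1), 4, 1), c(1, 0), 16)
  expect_equal(r1[1, 3], 1)  # level 0, length 3
  expect_equal(r1[2, 1], 1)  # level 1, length 1
  m1 <- glrlm_matrix(as_quantized_roi(matrix(c(0, 0, 0, 1), 4, 1), 4), c(1, 0))
  expect_equal(m1$counts[, 1:4], r1[, 1:4])
  # RP = runs / pixels = 2/4
  f <- crtradiomics:::emphasis_features(m1$counts, m1$n_pixels)
  expect_equal(unname(f["RP"]), 0.5)
  # constant N-pixel row: single run, LRE = N^2
  mN <- glrlm_matrix(as_quantized_roi(matrix(2L, 7, 1), 4), c(1, 0))
  expect_equal(unname(crtradiomics:::emphasis_features(mN$counts, mN$n_pixels)["LRE"]), 49)
  # alternating row: all runs length 1, SRE = 1
  mA <- glrlm_matrix(as_quantized_roi(matrix(c(0L, 1L, 0L, 1L), 4, 1), 4), c(1, 0))
  expect_equal(unname(crtradiomics:::emphasis_features(mA$counts, mA$n_pixels)["SRE"]), 1)
})

test_that("size zones: LZE on worked zone sizes", {
  # image with zones of sizes {4, 1, 1} -> LZE = (16 + 1 + 1)/3 = 6
  img <- matrix(c(1, 1, 2,
                  1, 1, 3), 2, 3, byrow = TRUE)
  roi <- as_quantized_roi(img, k = 4)
  zl <- bf_zones(roi$levels)
  expect_equal(sort(zl[, "size"]), c(1, 1, 4))
  f <- glszm_features(roi)
  expect_equal(unname(f["LZE"]), (16 + 1 + 1) / 3)
  # constant n-pixel image: one zone, LZE = n^2
  fc <- glszm_features(as_quantized_roi(matrix(3L, 3, 4), 4))
  expect_equal(unname(fc["LZE"]), 144)
  # all-distinct levels: every zone size 1, LZE = 1
  fd <- glszm_features(as_quantized_roi(matrix(0:8, 3, 3), 4))
  expect_equal(unname(fd["LZE"]), 1)
})

test_that("NGTDM hand example: single deviant center voxel", {
  img <- matrix(2L, 3, 3); img[2, 2] <- 7L
  roi <- as_quantized_roi(img, k = 4)
  m <- ngtdm_matrix(roi)
  # only the center has a full 8-neighborhood; its neighbors all have level 2
  expect_equal(m$n_valid, 1)
  expect_equal(m$s[8], abs(7 - 2))          # s for level 7
  expect_equal(sum(m$n), 1)
  # constant image: all s_i = 0, contrast 0
  fc <- ngtdm_features(as_quantized_roi(matrix(4L, 5, 5), 4))
  expect_equal(unname(fc["Contrast"]), 0)
})

test_that("coarseness ranks a smooth gradient above a checkerboard", {
  grad <- matrix(rep(rep(0:3, each = 2), each = 8), 8, 8)  # smooth banded gradient
  chk <- outer(1:8, 1:8, function(i, j) ((i + j) %% 2) * 7L)
  f_grad <- ngtdm_features(as_quantized_roi(grad, 4))
  f_chk <- ngtdm_features(as_quantized_roi(chk, 4))
  expect_gt(f_grad["Coarseness"], f_chk["Coarseness"])
})

test_that("matrix builders equal brute-force enumeration on random 2D arrays", {
  for (s in 1:10) {
    lev <- random_roi(c(8, 8), 4, seed = s, na_frac = 0.2)
    roi <- as_quantized_roi(lev, k = 4)
    expect_equal(glcm_matrix(roi)$counts[1:4, 1:4],
                 bf_glcm(lev, half_offsets(2), 4)[1:4, 1:4])
    for (dir in list(c(1, 0), c(1, 1))) {
      got <- glrlm_matrix(roi, dir)$counts
      want <- bf_glrlm(lev, dir, 16)
      expect_equal(got[, seq_len(ncol(want))], want)
    }
    got_z <- glszm_matrix(roi)$counts
    zl <- bf_zones(lev)
    want_z <- matrix(0, 16, max(zl[, "size"]))
    for (r in seq_len(nrow(zl)))
      want_z[zl[r, "level"] + 1, zl[r, "size"]] <-
        want_z[zl[r, "level"] + 1, zl[r, "size"]] + 1
    expect_equal(got_z[, seq_len(ncol(want_z))], want_z)
    got_n <- ngtdm_matrix(roi)
    want_n <- bf_ngtdm(lev, 16)
    expect_equal(got_n$n, want_n$n)
    expect_equal(got_n$s, want_n$s)
    expect_equal(got_n$n_valid, want_n$n_valid)
  }
})

test_that("normalized probability forms sum to 1 and counts are nonneg integers", {
  for (s in 1:5) {
    lev <- random_roi(c(5, 5, 5), 4, seed = 100 + s, na_frac = 0.1)
    roi <- as_quantized_roi(lev, k = 4)
    g <- glcm_matrix(roi)
    expect_equal(sum(g$p), 1)
    expect_true(all(g$counts >= 0), all(g$counts == round(g$counts)))
    z <- glszm_matrix(roi)
    expect_true(all(z$counts >= 0))
    expect_equal(sum(z$counts %% 1), 0)
  }
})

test_that("direction-averaged 2D GLCM/GLRLM features are 90-degree rotation invariant", {
  lev <- random_roi(c(9, 7), 4, seed = 42)
  rot <- t(lev)[ncol(lev):1, , drop = FALSE]  # 90-degree rotation
  roi_a <- as_quantized_roi(lev, 4); roi_b <- as_quantized_roi(rot, 4)
  expect_equal(glcm_features(glcm_matrix(roi_a), glcm_feature_names_2d),
               glcm_features(glcm_matrix(roi_b), glcm_feature_names_2d))
  expect_equal(glrlm_features(roi_a), glrlm_features(roi_b))
})

test_that("features are invariant to translating the ROI within the volume", {
  lev <- array(NA_integer_, c(12, 12, 8))
  block <- random_roi(c(4, 4, 3), 4, seed = 77)
  a <- lev; a[2:5, 2:5, 2:4] <- block
  b <- lev; b[7:10, 6:9, 5:7] <- block
  ra <- as_quantized_roi(a, 4); rb <- as_quantized_roi(b, 4)
  expect_equal(glcm_features(glcm_matrix(ra)), glcm_features(glcm_matrix(rb)))
  expect_equal(glszm_features(ra), glszm_features(rb))
  expect_equal(ngtdm_features(ra), ngtdm_features(rb))
  expect_equal(histogram_features(ra), histogram_features(rb))
})
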