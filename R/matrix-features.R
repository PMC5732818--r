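# Feature formulas over the gray-level matrices. Degenerate inputs
# (single-level ROIs, zero denominators) take the documented conventions:
# correlation-type features 0, entropy terms 0*log(0) = 0, so every feature
# value is finite.

#' Feature-name sets per matrix family
#'
#' Ordered names of the features computed from each gray-level matrix, as
#' used by the manifest.
#' @name feature_name_sets
NULL

#' @rdname feature_name_sets
#' @export
glcm_feature_names_2d <- c("Energy", "Contrast", "Correlation", "Homogeneity",
                           "Entropy", "Dissimilarity", "Variance",
                           "SumAverage", "MaxProbability")

#' @rdname feature_name_sets
#' @export
glcm_feature_names_3d <- c(glcm_feature_names_2d,
                           "SumEntropy", "SumVariance", "DifferenceEntropy",
                           "DifferenceVariance", "IMC1", "IMC2",
                           "Autocorrelation", "ClusterShade",
                           "ClusterProminence", "InverseDifference")

#' Features of a gray-level co-occurrence matrix
#'
#' @param glcm A [glcm_matrix()].
#' @param which Character vector of feature names (defaults to the 3D set of
#'   19; the 2D manifest uses the first 9).
#' @return Named numeric vector.
#' @export
glcm_features <- function(glcm, which = glcm_feature_names_3d) {
  p <- glcm$p
  n <- glcm$n_levels
  i <- matrix(rep(1:n, n), n, n)        # row gray value
  j <- t(i)
  nz <- p > 0
  mu <- sum(i * p)                       # symmetric: mu_x = mu_y
  sig2 <- sum((i - mu)^2 * p)
  # diagonal distributions
  pxy_sum <- vapply(2:(2 * n), function(k) sum(p[i + j == k]), numeric(1))
  pxy_dif <- vapply(0:(n - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  px <- rowSums(p)
  hx <- entropy_bits(px)
  hxy <- entropy_bits(p[nz])
  # joint entropies against the independence product, for IMC1/IMC2
  pij <- outer(px, px)
  hxy1 <- -sum(p[pij > 0] * log2(pij[pij > 0]))
  hxy2 <- -sum(pij[pij > 0] * log2(pij[pij > 0]))
  sa <- sum((2:(2 * n)) * pxy_sum)
  dv_mean <- sum((0:(n - 1)) * pxy_dif)
  vals <- c(
    Energy = sum(p^2),
    Contrast = sum((i - j)^2 * p),
    Correlation = if (sig2 > 0) sum((i - mu) * (j - mu) * p) / sig2 else 0,
    Homogeneity = sum(p / (1 + (i - j)^2)),
    Entropy = hxy,
    Dissimilarity = sum(abs(i - j) * p),
    Variance = sum((i - mu)^2 * p),
    SumAverage = sa,
    MaxProbability = max(p),
    SumEntropy = entropy_bits(pxy_sum),
    SumVariance = sum(((2:(2 * n)) - sa)^2 * pxy_sum),
    DifferenceEntropy = entropy_bits(pxy_dif),
    DifferenceVariance = sum(((0:(n - 1)) - dv_mean)^2 * pxy_dif),
    IMC1 = if (hx > 0) (hxy - hxy1) / hx else 0,
    IMC2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    Autocorrelation = sum(i * j * p),
    ClusterShade = sum((i + j - 2 * mu)^3 * p),
    ClusterProminence = sum((i + j - 2 * mu)^4 * p),
    InverseDifference = sum(p / (1 + abs(i - j)))
  )
  vals[which]
}

#' @rdname feature_name_sets
#' @export
glrlm_feature_names <- c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE",
                         "SRLGE", "SRHGE", "LRLGE", "LRHGE", "GLV", "RLV")

# Shared emphasis formulas for run-length and size-zone matrices: rows index
# gray value i (1-based), columns index run length / zone size j.
emphasis_features <- function(M, n_pixels) {
  nr <- sum(M)
  if (nr == 0) return(setNames(numeric(13), glrlm_feature_names))
  i <- matrix(rep(seq_len(nrow(M)), ncol(M)), nrow(M), ncol(M))
  j <- t(matrix(rep(seq_len(ncol(M)), nrow(M)), ncol(M), nrow(M)))
  p <- M / nr
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  c(SRE = sum(M / j^2) / nr,
    LRE = sum(M * j^2) / nr,
    GLN = sum(rowSums(M)^2) / nr,
    RLN = sum(colSums(M)^2) / nr,
    RP = nr / n_pixels,
    LGRE = sum(M / i^2) / nr,
    HGRE = sum(M * i^2) / nr,
    SRLGE = sum(M / (i^2 * j^2)) / nr,
    SRHGE = sum(M * i^2 / j^2) / nr,
    LRLGE = sum(M * j^2 / i^2) / nr,
    LRHGE = sum(M * i^2 * j^2) / nr,
    GLV = sum(p * (i - mu_i)^2),
    RLV = sum(p * (j - mu_j)^2))
}

#' Run-length features averaged over directions
#'
#' Builds one run-length matrix per direction (4 in 2D, 13 in 3D) and
#' averages each of the 13 features over directions.
#'
#' @param roi A quantized ROI.
#' @return Named numeric vector (SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE,
#'   SRHGE, LRLGE, LRHGE, GLV, RLV).
#' @export
glrlm_features <- function(roi) {
  per_dir <- vapply(roi_directions(roi), function(dir) {
    m <- glrlm_matrix(roi, dir)
    emphasis_features(m$counts, m$n_pixels)
  }, numeric(13))
  rowMeans(per_dir)
}

#' @rdname feature_name_sets
#' @export
glszm_feature_names <- c("SZE", "LZE", "GLN", "ZSN", "ZP", "LGZE", "HGZE",
                         "SZLGE", "SZHGE", "LZLGE", "LZHGE", "GLV", "ZSV")

#' Size-zone features
#'
#' @param roi A quantized ROI.
#' @return Named numeric vector; LZE (large zone emphasis) is
#'   `sum_ij j^2 P(i,j) / N_z`.
#' @export
glszm_features <- function(roi) {
  m <- glszm_matrix(roi)
  setNames(emphasis_features(m$counts, m$n_pixels), glszm_feature_names)
}

#' @rdname feature_name_sets
#' @export
ngtdm_feature_names <- c("Coarseness", "Contrast", "Busyness", "Complexity",
                         "Strength")

#' Neighborhood gray-tone difference features
#'
#' Amadasun-King coarseness, contrast, busyness, complexity and strength
#' computed over strict-interior ROI voxels. Degenerate denominators yield 0.
#'
#' @param roi A quantized ROI.
#' @return Named numeric vector of the 5 features.
#' @export
ngtdm_features <- function(roi) {
  m <- ngtdm_matrix(roi)
  out <- setNames(numeric(5), ngtdm_feature_names)
  if (m$n_valid == 0) return(out)
  pres <- which(m$n > 0)
  p <- m$n / m$n_valid
  s <- m$s
  iv <- seq_len(m$n_levels)
  ng <- length(pres)
  den_ps <- sum(p * s)
  out["Coarseness"] <- if (den_ps > 0) 1 / den_ps else 0
  if (ng >= 2) {
    pi_ <- p[pres]; ii <- iv[pres]; si <- s[pres]
    d2 <- outer(ii, ii, function(a, b) (a - b)^2)
    out["Contrast"] <- (sum(outer(pi_, pi_) * d2) / (ng * (ng - 1))) *
      (sum(s) / m$n_valid)
    den_b <- sum(abs(outer(ii * pi_, ii * pi_, `-`)))
    out["Busyness"] <- if (den_b > 0) den_ps / den_b else 0
    psmat <- outer(pi_ * si, pi_ * si, `+`)
    pmat <- outer(pi_, pi_, `+`)
    out["Complexity"] <- sum(abs(outer(ii, ii, `-`)) * psmat / pmat) / m$n_valid
    den_s <- sum(s)
    out["Strength"] <- if (den_s > 0) sum(pmat * d2) / den_s else 0
  }
  out
}
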