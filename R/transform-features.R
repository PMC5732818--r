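# 2D-only feature families: gray-level gradient co-occurrence (GLGCM),
# Laplacian-of-Gaussian first-order statistics, and the Gabor filter bank.

#' Histogram features of a quantized ROI
#'
#' First-order statistics of the quantized gray levels: mean, variance,
#' skewness (third standardized moment), kurtosis (Pearson, non-excess),
#' energy and entropy of the `2^k`-bin level histogram. Zero-variance ROIs
#' take skewness 0 and kurtosis 0 by convention.
#'
#' @param roi A [quantize_gray_levels()] result.
#' @return Named numeric vector of 6 values.
#' @export
histogram_features <- function(roi) {
  x <- roi$levels[!is.na(roi$levels)]
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  p <- tabulate(x + 1L, roi$n_levels) / n
  out <- c(mean = m, variance = m2, skewness = 0, kurtosis = 0,
           energy = sum(p^2), entropy = entropy_bits(p))
  if (m2 > 0) {
    out["skewness"] <- mean((x - m)^3) / m2^1.5
    out["kurtosis"] <- mean((x - m)^4) / m2^2
  }
  out
}

#' @rdname feature_name_sets
#' @export
glgcm_feature_names <- c("SmallGradientEmphasis", "LargeGradientEmphasis",
                         "GrayNonuniformity", "GradientNonuniformity",
                         "Energy", "Correlation", "GrayEntropy",
                         "GradientEntropy", "GradientMean",
                         "GradientVariance")

# Joint (gray level x gradient-magnitude bin) histogram over the interior
# pixels of the ROI bounding-box crop; background pixels enter at level 0.
glgcm_histogram <- function(roi, n_gradient_bins = 16L) {
  stopifnot(roi$dimensionality == "2D")
  cr <- crop_to_mask(roi$levels, roi$roi_mask)
  img <- cr$arr
  img[is.na(img)] <- 0L
  d <- dim(img)
  if (any(d < 3)) return(matrix(0, roi$n_levels, n_gradient_bins))
  g <- sobel_magnitude(img)[2:(d[1] - 1), 2:(d[2] - 1), drop = FALSE]
  lv <- img[2:(d[1] - 1), 2:(d[2] - 1), drop = FALSE]
  gmax <- max(g)
  gb <- if (gmax > 0) pmin(floor(n_gradient_bins * g / gmax), n_gradient_bins - 1L) else g * 0L
  tab <- tabulate(lv * n_gradient_bins + gb + 1L, roi$n_levels * n_gradient_bins)
  matrix(tab, roi$n_levels, n_gradient_bins, byrow = TRUE)
}

# Sobel gradient magnitude of a 2D array, defined on interior pixels.
sobel_magnitude <- function(img) {
  d <- dim(img)
  gx <- matrix(0, d[1], d[2]); gy <- matrix(0, d[1], d[2])
  ix <- 2:(d[1] - 1); iy <- 2:(d[2] - 1)
  gx[ix, iy] <- (img[ix + 1, iy - 1] + 2 * img[ix + 1, iy] + img[ix + 1, iy + 1]) -
                (img[ix - 1, iy - 1] + 2 * img[ix - 1, iy] + img[ix - 1, iy + 1])
  gy[ix, iy] <- (img[ix - 1, iy + 1] + 2 * img[ix, iy + 1] + img[ix + 1, iy + 1]) -
                (img[ix - 1, iy - 1] + 2 * img[ix, iy - 1] + img[ix + 1, iy - 1])
  sqrt(gx^2 + gy^2)
}

#' Gray-level gradient co-occurrence features (2D)
#'
#' Joint histogram of quantized gray level against Sobel gradient magnitude
#' quantized to 16 bins, evaluated on the interior pixels of the ROI
#' bounding-box section (out-of-mask pixels enter at level 0, which keeps the
#' operator well defined up to the tumor boundary). Ten features summarize
#' the joint distribution.
#'
#' @param roi A 2D [quantize_gray_levels()] result.
#' @param n_gradient_bins Number of gradient-magnitude bins (default 16).
#' @return Named numeric vector of 10 features.
#' @export
glgcm_features <- function(roi, n_gradient_bins = 16L) {
  H <- glgcm_histogram(roi, n_gradient_bins)
  N <- sum(H)
  if (N == 0) return(setNames(numeric(10), glgcm_feature_names))
  p <- H / N
  i <- matrix(rep(seq_len(nrow(H)), ncol(H)), nrow(H), ncol(H))
  j <- t(matrix(rep(seq_len(ncol(H)), nrow(H)), ncol(H), nrow(H)))
  pi_ <- rowSums(p); pj <- colSums(p)
  mu_i <- sum(seq_along(pi_) * pi_); mu_j <- sum(seq_along(pj) * pj)
  v_i <- sum((seq_along(pi_) - mu_i)^2 * pi_)
  v_j <- sum((seq_along(pj) - mu_j)^2 * pj)
  corr <- if (v_i > 0 && v_j > 0)
    sum((i - mu_i) * (j - mu_j) * p) / sqrt(v_i * v_j) else 0
  c(SmallGradientEmphasis = sum(p / j^2),
    LargeGradientEmphasis = sum(p * j^2),
    GrayNonuniformity = sum(rowSums(H)^2) / N,
    GradientNonuniformity = sum(colSums(H)^2) / N,
    Energy = sum(p^2),
    Correlation = corr,
    GrayEntropy = entropy_bits(pi_),
    GradientEntropy = entropy_bits(pj),
    GradientMean = mu_j,
    GradientVariance = v_j)
}

# FFT-based 'same' 2D convolution with replicate (edge) padding, so that
# zero-sum kernels annihilate constants exactly up to the image border.
conv2_same <- function(img, kern) {
  di <- dim(img); dk <- dim(kern)
  r <- (dk - 1) %/% 2
  src_i <- pmin(pmax(seq(1 - r[1], di[1] + r[1]), 1), di[1])
  src_j <- pmin(pmax(seq(1 - r[2], di[2] + r[2]), 1), di[2])
  pad <- img[src_i, src_j, drop = FALSE]
  dp <- dim(pad) + dk - 1
  P <- matrix(0, dp[1], dp[2]); P[1:nrow(pad), 1:ncol(pad)] <- pad
  K <- matrix(0, dp[1], dp[2]); K[1:dk[1], 1:dk[2]] <- kern
  full <- fft(fft(P) * fft(K), inverse = TRUE) / prod(dp)
  full[(2 * r[1] + 1):(2 * r[1] + di[1]), (2 * r[2] + 1):(2 * r[2] + di[2])]
}

log_kernel <- function(sigma) {
  r <- max(2L, ceiling(4 * sigma))
  x <- seq(-r, r)
  g2 <- outer(x^2, x^2, `+`)
  k <- (g2 - 2 * sigma^2) / sigma^4 * exp(-g2 / (2 * sigma^2))
  k - mean(k)  # zero-sum: exact annihilation of constants
}

#' Laplacian-of-Gaussian texture statistics (2D)
#'
#' Convolves the intensity section with LoG filters at the given sigmas
#' (1.0 highlights fine, 2.0 medium, 2.5 coarse texture) and returns the six
#' first-order statistics of the filtered values inside the mask per sigma.
#'
#' @param section 2D numeric intensity array.
#' @param mask Logical 2D array.
#' @param sigmas Filter scales in pixels.
#' @return Named numeric vector of `6 * length(sigmas)` values, named
#'   `sigma<σ>_<stat>`.
#' @export
log_features <- function(section, mask, sigmas = c(1.0, 2.0, 2.5)) {
  out <- numeric(0)
  for (s in sigmas) {
    f <- Re(conv2_same(section, log_kernel(s)))
    st <- first_order_stats(f[mask])
    names(st) <- sprintf("sigma%.1f_%s", s, names(st))
    out <- c(out, st)
  }
  out
}

# Gabor kernel (complex), orientation theta, center frequency f cycles/px.
gabor_kernel <- function(f, theta, gamma = 0.5) {
  sigma <- 0.56 / f   # ~1 octave bandwidth
  r <- ceiling(2.5 * sigma / min(1, gamma))
  x <- seq(-r, r)
  X <- matrix(rep(x, length(x)), length(x))
  Y <- t(X)
  xr <- X * cos(theta) + Y * sin(theta)
  yr <- -X * sin(theta) + Y * cos(theta)
  env <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2))
  env * exp(2i * pi * f * xr)
}

#' Gabor filter-bank features (2D)
#'
#' A bank of 5 scales x 8 orientations (`theta = (o-1) * pi/8`); scale 1 is
#' the finest (highest center frequency). For each filter, MSA is the mean
#' complex-response magnitude over in-mask pixels and MSE the Shannon entropy
#' of the 16-bin normalized magnitude histogram. Names follow `MSA-so` /
#' `MSE-so` with scale index s and orientation index o, so `-54` means
#' scale 5, orientation 4.
#'
#' @param section 2D numeric intensity array.
#' @param mask Logical 2D array.
#' @param frequencies Center frequencies (cycles/pixel), finest first.
#' @param n_orientations Number of orientations (default 8).
#' @return Named numeric vector of `2 * 5 * 8 = 80` values, all MSA first.
#' @export
gabor_features <- function(section, mask,
                           frequencies = gabor_frequencies(),
                           n_orientations = 8L) {
  msa <- numeric(0); mse <- numeric(0)
  for (s in seq_along(frequencies)) {
    for (o in seq_len(n_orientations)) {
      k <- gabor_kernel(frequencies[s], (o - 1) * pi / n_orientations)
      resp_re <- Re(conv2_same(section, Re(k)))
      resp_im <- Re(conv2_same(section, Im(k)))
      mag <- sqrt(resp_re^2 + resp_im^2)[mask]
      msa[sprintf("MSA-%d%d", s, o)] <- mean(mag)
      rng <- range(mag)
      if (rng[2] - rng[1] <= .Machine$double.eps * max(1, rng[2])) {
        mse[sprintf("MSE-%d%d", s, o)] <- 0
      } else {
        b <- pmin(floor((mag - rng[1]) / (rng[2] - rng[1]) * 16), 15)
        mse[sprintf("MSE-%d%d", s, o)] <- entropy_bits(tabulate(b + 1L, 16) / length(b))
      }
    }
  }
  c(msa, mse)
}

#' Default Gabor center frequencies
#'
#' Five log-spaced center frequencies spanning 0.05-0.4 cycles/pixel
#' (ratio 2^(3/4)), finest scale first.
#' @return Numeric length-5.
#' @export
gabor_frequencies <- function() 0.4 / (2^(3 / 4))^(0:4)
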