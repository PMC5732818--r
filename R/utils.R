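#' @importFrom stats rnorm runif var sd fft pnorm pchisq pbinom setNames
#'   kruskal.test predict
#' @importFrom utils head tail write.csv read.csv
NULL

# Derive a 32-bit child seed from a parent seed and a stream index, so that
# every stage/case draws from its own reproducible stream.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483647 * 1009 + index * 9973) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Shannon entropy (base 2) of a probability vector; 0*log(0) := 0.
entropy_bits <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

# First-order statistics used by several feature families. `x` is a numeric
# vector of values; energy/entropy are computed over an `nbins`-bin histogram
# spanning the observed range. Zero-variance inputs take the degenerate
# conventions (skewness 0, kurtosis 0, energy 1, entropy 0).
first_order_stats <- function(x, nbins = 16L) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= .Machine$double.eps * max(1, m^2)) {
    return(c(mean = m, variance = 0, skewness = 0, kurtosis = 0,
             energy = 1, entropy = 0))
  }
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  rng <- range(x)
  bin <- pmin(floor((x - rng[1]) / (rng[2] - rng[1]) * nbins), nbins - 1L)
  p <- tabulate(bin + 1L, nbins) / n
  c(mean = m,
    variance = m2,
    skewness = m3 / m2^1.5,
    kurtosis = m4 / m2^2,   # Pearson (non-excess)
    energy = sum(p^2),
    entropy = entropy_bits(p))
}

# Axis-aligned bounding-box crop of `arr` to the TRUE region of `mask`,
# returned with the cropped mask.
crop_to_mask <- function(arr, mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (is.null(dim(mask))) stop("mask must be an array")
  ranges <- lapply(seq_len(ncol(idx)), function(d) range(idx[, d]))
  args <- lapply(ranges, function(r) r[1]:r[2])
  list(arr = do.call(`[`, c(list(arr), args, list(drop = FALSE))),
       mask = do.call(`[`, c(list(mask), args, list(drop = FALSE))))
}

# Separable Gaussian smoothing of a 3D array, sigma given per-axis in voxels.
gaussian_smooth3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    arr <- convolve_axis(arr, k, ax)
  }
  arr
}

# Convolve a 3D array with a 1D kernel along axis `ax` (replicate padding),
# implemented as a banded matrix product along that axis.
convolve_axis <- function(arr, k, ax) {
  d <- dim(arr)
  n <- d[ax]
  r <- (length(k) - 1L) / 2L
  W <- matrix(0, n, n)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate edges
    W[cbind(seq_len(n), src)] <- W[cbind(seq_len(n), src)] + k[j]
  }
  apply_axis_matrix(arr, W, ax)
}

# Apply matrix W (n_out x n_in) along axis `ax` of 3D array `arr`.
apply_axis_matrix <- function(arr, W, ax) {
  d <- dim(arr)
  perm <- c(ax, setdiff(1:3, ax))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[ax])
  out <- W %*% m
  d2 <- c(nrow(W), d[perm[2]], d[perm[3]])
  out <- array(out, d2)
  aperm(out, order(perm))
}
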