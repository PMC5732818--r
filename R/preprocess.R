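#' Image volume with voxel spacing
#'
#' Lightweight container for a 3D scalar volume plus its voxel spacing and
#' physical origin, the unit handled by the preprocessing stage.
#'
#' @param data 3D numeric array of intensities.
#' @param spacing Numeric length-3, voxel spacing in mm (all > 0).
#' @param origin Numeric length-3, physical position (mm) of the first voxel.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3)
  if (any(spacing <= 0)) stopf("voxel spacing must be strictly positive")
  if (!all(is.finite(data))) stopf("volume intensities must be finite")
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels @ %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

# 1D Catmull-Rom (cubic convolution) resampling weights from an input grid of
# n_in samples at `sp_in` spacing to n_out samples at `sp_out` spacing, with
# voxel centers at (i - 0.5) * spacing. Rows sum to 1, so constants are
# reproduced exactly and an identity grid yields the identity matrix.
cubic_weight_matrix <- function(n_in, sp_in, n_out, sp_out) {
  u <- ((seq_len(n_out) - 0.5) * sp_out) / sp_in - 0.5  # 0-based input coord
  i0 <- floor(u)
  t <- u - i0
  # Catmull-Rom basis for samples at i0-1, i0, i0+1, i0+2
  w <- cbind(((-t + 2 * t^2 - t^3) / 2),
             ((2 - 5 * t^2 + 3 * t^3) / 2),
             ((t + 4 * t^2 - 3 * t^3) / 2),
             ((-t^2 + t^3) / 2))
  W <- matrix(0, n_out, n_in)
  for (j in 1:4) {
    src <- pmin(pmax(i0 + j - 2L, 0L), n_in - 1L) + 1L  # clamp = replicate edge
    for (k in seq_len(n_out)) W[k, src[k]] <- W[k, src[k]] + w[k, j]
  }
  W
}

nearest_weight_matrix <- function(n_in, sp_in, n_out, sp_out) {
  u <- ((seq_len(n_out) - 0.5) * sp_out) / sp_in - 0.5
  src <- pmin(pmax(round(u), 0), n_in - 1) + 1L
  W <- matrix(0, n_out, n_in)
  W[cbind(seq_len(n_out), src)] <- 1
  W
}

#' Resample a volume and mask to isotropic voxels
#'
#' Resamples intensities with separable cubic (Catmull-Rom) interpolation and
#' the mask with nearest-neighbor interpolation, preserving the physical
#' extent of the volume to within one voxel. The default target of
#' 1 x 1 x 1 mm puts every case on a common geometric footing before texture
#' analysis, so voxel-count-based features are comparable across scanners
#' with anisotropic acquisition (e.g. 0.97 x 0.97 x 2.5 mm).
#'
#' @param volume An [image_volume()].
#' @param mask Logical/binary 3D array, same shape as `volume$data`.
#' @param target_spacing Numeric length-3 target spacing in mm.
#' @return List with elements `volume` (resampled [image_volume()]) and
#'   `mask` (logical array).
#' @export
resample_isotropic <- function(volume, mask, target_spacing = c(1, 1, 1)) {
  stopifnot(inherits(volume, "image_volume"))
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(mask), dim(volume$data)))
    stopf("mask shape %s does not match volume shape %s",
          paste(dim(mask), collapse = "x"), paste(dim(volume$data), collapse = "x"))
  d_in <- dim(volume$data)
  extent <- d_in * volume$spacing
  d_out <- pmax(1L, as.integer(round(extent / target_spacing)))

  dat <- volume$data
  msk <- mask + 0
  for (ax in 1:3) {
    if (d_in[ax] == d_out[ax] && abs(volume$spacing[ax] - target_spacing[ax]) < 1e-12)
      next
    Wc <- cubic_weight_matrix(d_in[ax], volume$spacing[ax], d_out[ax], target_spacing[ax])
    Wn <- nearest_weight_matrix(d_in[ax], volume$spacing[ax], d_out[ax], target_spacing[ax])
    dat <- apply_axis_matrix(dat, Wc, ax)
    msk <- apply_axis_matrix(msk, Wn, ax)
    d_in[ax] <- d_out[ax]
  }
  msk <- array(msk > 0.5, dim(msk))
  if (!any(msk)) stopf("degenerate ROI: mask is empty after resampling")
  list(volume = image_volume(dat, target_spacing, volume$origin), mask = msk)
}

#' Quantize ROI intensities to a finite gray-level range
#'
#' Normalizes the intensities of the contoured ROI to `2^k` discrete gray
#' levels: `V(x) = floor(2^k * (I(x) - min) / (max - min))` with min/max taken
#' over ROI voxels only, and the voxel(s) attaining the ROI maximum clamped to
#' `2^k - 1` so the output occupies exactly the levels `0 ... 2^k - 1`. The
#' mapping is invariant to affine rescaling of the input intensities, which
#' suppresses acquisition-dependent intensity-range differences between cases.
#'
#' @param volume An [image_volume()] (or a bare 3D/2D numeric array).
#' @param mask Logical array, same shape; must be nonempty.
#' @param k Bits of quantization; `2^k` must lie in 16..128 (default `k = 4`,
#'   i.e. 16 levels).
#' @return An object of class `quantized_roi` with fields `levels` (integer
#'   array, `NA` outside the ROI), `k`, `n_levels`, `roi_mask`,
#'   `dimensionality` ("2D" or "3D"), and `flat` (TRUE if the ROI had zero
#'   intensity range).
#' @export
quantize_gray_levels <- function(volume, mask, k = 4L) {
  dat <- if (inherits(volume, "image_volume")) volume$data else volume
  n_levels <- 2^k
  if (n_levels < 16 || n_levels > 128)
    stopf("2^k must lie in [16, 128]; got k = %s", k)
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(mask), dim(dat))) stopf("mask shape must match volume shape")
  if (!any(mask)) stopf("degenerate ROI: empty mask")
  vals <- dat[mask]
  lo <- min(vals); hi <- max(vals)
  levels <- array(NA_integer_, dim(dat))
  flat <- (hi - lo) <= 0
  if (flat) {
    warning("flat ROI (zero intensity range): all levels set to 0")
    levels[mask] <- 0L
  } else {
    v <- floor(n_levels * (vals - lo) / (hi - lo))
    v[v >= n_levels] <- n_levels - 1
    levels[mask] <- as.integer(v)
  }
  structure(list(levels = levels, k = as.integer(k), n_levels = as.integer(n_levels),
                 roi_mask = mask,
                 dimensionality = if (length(dim(dat)) == 2) "2D" else "3D",
                 flat = flat),
            class = "quantized_roi")
}

#' Index of the largest axial cross-section of a mask
#'
#' Returns the axial (third-axis) slice index with the most in-mask voxels;
#' ties are broken toward the lowest index. The 2D feature families operate on
#' this section, the plane where the tumor outline is largest.
#'
#' @param mask Logical 3D array, nonempty.
#' @return Integer slice index (1-based).
#' @export
largest_axial_section <- function(mask) {
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stopf("degenerate ROI: empty mask")
  areas <- apply(mask, 3, sum)
  which.max(areas)  # which.max takes the first maximum => lowest index
}

#' Wrap a pre-quantized level array as a quantized ROI
#'
#' For data already expressed as discrete gray levels (e.g. worked examples
#' or externally quantized images). `NA` entries are treated as outside the
#' ROI; alternatively pass an explicit `mask`.
#'
#' @param levels Integer 2D/3D array of levels in `0 ... 2^k - 1`.
#' @param k Quantization bits.
#' @param mask Optional logical array; defaults to `!is.na(levels)`.
#' @return A `quantized_roi`.
#' @export
as_quantized_roi <- function(levels, k = 4L, mask = NULL) {
  if (is.null(mask)) mask <- !is.na(levels)
  levels[!mask] <- NA_integer_
  stopifnot(any(mask), min(levels, na.rm = TRUE) >= 0,
            max(levels, na.rm = TRUE) <= 2^k - 1)
  structure(list(levels = array(as.integer(levels), dim(levels)),
                 k = as.integer(k), n_levels = as.integer(2^k),
                 roi_mask = array(as.logical(mask), dim(mask)),
                 dimensionality = if (length(dim(levels)) == 2) "2D" else "3D",
                 flat = FALSE),
            class = "quantized_roi")
}

# Extract the largest axial section of a resampled case as a 2D intensity
# array + 2D mask, for the 2D feature families.
axial_section <- function(volume, mask) {
  z <- largest_axial_section(mask)
  dat <- if (inherits(volume, "image_volume")) volume$data else volume
  list(intensity = dat[, , z, drop = TRUE], mask = mask[, , z, drop = TRUE], z = z)
}
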