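#' Texture parameters for one response class
#'
#' Controls the intra-tumor intensity texture of synthetic tumors. The two
#' knobs that matter scientifically are `correlation_length` (the spatial
#' scale of heterogeneity, mm) and `skew_strength` (asymmetry of the
#' intensity histogram): responders and nonresponders are contrasted on
#' exactly these two axes, emulating the phenotype difference that
#' histogram-skewness and size-zone features pick up on clinical CT.
#'
#' @param mean_intensity Mean in-tumor intensity (HU-like units).
#' @param correlation_length Spatial smoothness scale of the heterogeneity
#'   field, mm (> 0).
#' @param skew_strength Dimensionless >= 0; 0 gives a symmetric intensity
#'   histogram, larger values give increasingly right-skewed histograms.
#' @param heterogeneity_sd Standard deviation of the (correlated) intensity
#'   heterogeneity, intensity units (>= 0).
#' @return A `texture_params` object.
#' @export
texture_params <- function(mean_intensity = 60, correlation_length = 4,
                           skew_strength = 0, heterogeneity_sd = 12) {
  if (correlation_length <= 0) stopf("correlation_length must be > 0")
  if (heterogeneity_sd < 0) stopf("heterogeneity_sd must be >= 0")
  structure(list(mean_intensity = mean_intensity,
                 correlation_length = correlation_length,
                 skew_strength = skew_strength,
                 heterogeneity_sd = heterogeneity_sd),
            class = "texture_params")
}

#' Specification of a synthetic two-class cohort
#'
#' Defaults emulate the study conditions of a 49-patient esophageal-carcinoma
#' cohort: 33 responders vs 16 nonresponders, anisotropic CT voxels of
#' 0.97 x 0.97 x 2.5 mm, and tumors of 8-14 mm radius. Nonresponders carry a
#' right-skewed intensity histogram and a longer heterogeneity correlation
#' length than responders.
#'
#' @param n_responders,n_nonresponders Class sizes (>= 1 each).
#' @param volume_shape Integer length-3 voxel grid.
#' @param voxel_spacing Numeric length-3, mm.
#' @param tumor_radius_range Numeric length-2 (mm); must fit in the volume.
#' @param responder_texture,nonresponder_texture [texture_params()] for each
#'   class.
#' @param noise_sd Independent voxel noise sd (intensity units).
#' @param contour_perturbation_mm Magnitude of the second observer's contour
#'   perturbation (mm).
#' @param background_intensity Constant soft-tissue-like background (HU-like).
#' @param case_variability Inter-patient heterogeneity: per-case lognormal
#'   multipliers (sd on the log scale) on `correlation_length` and
#'   `heterogeneity_sd`, plus a normal shift (intensity units) on
#'   `mean_intensity`. Real cohorts vary far more between patients than a
#'   re-contouring of the same patient varies, and the reproducibility stage
#'   is only meaningful under that regime.
#' @param seed Integer master seed for the cohort.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_responders = 33, n_nonresponders = 16,
                        volume_shape = c(48, 48, 20),
                        voxel_spacing = c(0.97, 0.97, 2.5),
                        tumor_radius_range = c(8, 14),
                        responder_texture = texture_params(
                          mean_intensity = 60, correlation_length = 4,
                          skew_strength = 0, heterogeneity_sd = 12),
                        nonresponder_texture = texture_params(
                          mean_intensity = 60, correlation_length = 8,
                          skew_strength = 1.2, heterogeneity_sd = 12),
                        noise_sd = 5,
                        contour_perturbation_mm = 1,
                        background_intensity = 45,
                        case_variability = list(log_correlation_sd = 0.3,
                                                log_heterogeneity_sd = 0.3,
                                                mean_intensity_sd = 10,
                                                skew_sd = 0.35,
                                                log_noise_sd = 0.3),
                        seed = 1L) {
  if (n_responders < 1 || n_nonresponders < 1)
    stopf("both classes need at least one case")
  if (any(voxel_spacing <= 0)) stopf("voxel spacing must be strictly positive")
  extent <- volume_shape * voxel_spacing
  if (2 * max(tumor_radius_range) * 1.3 >= min(extent))
    stopf("tumor_radius_range does not fit inside the volume (extent %s mm)",
          paste(signif(extent, 3), collapse = "x"))
  structure(list(n_responders = as.integer(n_responders),
                 n_nonresponders = as.integer(n_nonresponders),
                 volume_shape = as.integer(volume_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 tumor_radius_range = as.numeric(tumor_radius_range),
                 responder_texture = responder_texture,
                 nonresponder_texture = nonresponder_texture,
                 noise_sd = noise_sd,
                 contour_perturbation_mm = contour_perturbation_mm,
                 background_intensity = background_intensity,
                 case_variability = case_variability,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate one synthetic tumor volume and mask
#'
#' Places a random axis-aligned ellipsoid of mean radius `radius` in the
#' field of view and fills it with a correlated Gaussian heterogeneity field
#' (white noise smoothed at `correlation_length`) passed through a monotone
#' exponential skewing transform, plus independent voxel noise. The
#' background is a constant soft-tissue-like intensity plus the same
#' independent noise, so a contour that spills slightly outside the tumor
#' meets plausible tissue values rather than an intensity cliff. Identical
#' arguments and seed reproduce the output bit-for-bit.
#'
#' @param params [texture_params()].
#' @param shape Integer length-3 voxel grid.
#' @param spacing Numeric length-3 voxel spacing, mm.
#' @param radius Mean tumor radius, mm; must fit inside the field of view.
#' @param noise_sd Independent voxel noise sd.
#' @param background Constant background intensity (HU-like).
#' @param seed Integer seed.
#' @return List with `volume` ([image_volume()]) and `mask` (logical array).
#' @export
generate_tumor_volume <- function(params, shape, spacing, radius,
                                  noise_sd = 5, background = 45, seed = 1L) {
  stopifnot(inherits(params, "texture_params"))
  shape <- as.integer(shape)
  extent <- shape * spacing
  if (2 * radius * 1.3 >= min(extent))
    stopf("tumor radius %.1f mm does not fit inside a %s mm field of view",
          radius, paste(signif(extent, 3), collapse = "x"))
  withr::with_seed(seed, {
    # ellipsoid geometry: random per-axis anisotropy, center jittered but kept
    # inside the volume with margin for the largest semi-axis
    aniso <- runif(3, 0.7, 1.3)
    semi <- radius * aniso
    margin <- semi + 1
    center <- extent / 2 + vapply(seq_len(3), function(i) {
      lim <- max(0, extent[i] / 2 - margin[i])
      runif(1, -min(lim, 3), min(lim, 3))
    }, numeric(1))
    cx <- lapply(1:3, function(i) ((seq_len(shape[i]) - 0.5) * spacing[i] - center[i]) / semi[i])
    d2 <- outer(outer(cx[[1]]^2, cx[[2]]^2, `+`), cx[[3]]^2, `+`)
    mask <- d2 <= 1

    vol <- array(0, shape)
    if (params$heterogeneity_sd > 0) {
      field <- array(rnorm(prod(shape)), shape)
      field <- gaussian_smooth3d(field, params$correlation_length / spacing)
      # standardize against the in-mask sample so the tumor texture has sd
      # heterogeneity_sd and its histogram shape follows skew_strength
      # regardless of where the tumor sits in the random field
      field <- (field - mean(field[mask])) /
        max(sd(field[mask]), .Machine$double.eps)
      s <- params$skew_strength
      if (s > 0) {
        field <- (exp(s * field) - 1) / s   # monotone, right-skewing
        field <- (field - mean(field[mask])) /
          max(sd(field[mask]), .Machine$double.eps)
      }
      vol <- vol + field * params$heterogeneity_sd
    }
    vol[!mask] <- background
    vol[mask] <- vol[mask] + params$mean_intensity
    if (noise_sd > 0) vol <- vol + rnorm(length(vol), sd = noise_sd)
    list(volume = image_volume(vol, spacing), mask = mask)
  })
}

#' Randomly perturb a tumor contour
#'
#' Emulates a second radiologist's delineation of the same tumor: the binary
#' mask is softened at scale `magnitude_mm`, a smooth random field shifts the
#' 0.5 iso-surface locally by about `magnitude_mm`, and the result is
#' re-thresholded. `magnitude_mm = 0` returns the input unchanged; expected
#' overlap (Dice) with the original decreases as `magnitude_mm` grows.
#'
#' @param mask Logical 3D array, nonempty.
#' @param magnitude_mm Perturbation scale, mm (>= 0).
#' @param spacing Voxel spacing, mm.
#' @param seed Integer seed.
#' @param max_attempts Retries (fresh substreams) if a perturbation empties
#'   the mask before erroring.
#' @return Logical array of the same shape.
#' @export
perturb_mask <- function(mask, magnitude_mm, spacing, seed = 1L,
                         max_attempts = 5L) {
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stopf("cannot perturb an empty mask")
  if (magnitude_mm == 0) return(mask)
  for (attempt in seq_len(max_attempts)) {
    out <- withr::with_seed(child_seed(seed, attempt - 1L), {
      soft <- gaussian_smooth3d(mask + 0, magnitude_mm / spacing)
      g <- array(rnorm(length(mask)), dim(mask))
      g <- gaussian_smooth3d(g, 4 / spacing)        # ~4 mm correlated wobble
      g <- g / max(sd(g), .Machine$double.eps)
      w <- 4 * soft * (1 - soft)                    # boundary-localized weight
      array(soft + 0.4 * g * w >= 0.5, dim(mask))
    })
    if (any(out) && any(out & mask)) return(out)
  }
  stopf("contour perturbation emptied the mask after %d attempts", max_attempts)
}

#' Dice overlap of two binary masks
#' @param a,b Logical arrays of the same shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Generate a synthetic cohort of patient cases
#'
#' Produces `n_responders` responder cases labeled CR/PR (alternating,
#' CR first) and `n_nonresponders` nonresponder cases labeled SD, each with a
#' primary tumor mask and a perturbed secondary mask standing in for a second
#' observer's contour. Fully deterministic under the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return List of `patient_case` objects, each with fields `case_id`,
#'   `volume`, `mask_primary`, `mask_secondary`, `label`, `responder`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_responders + spec$n_nonresponders
  labels <- c(rep(c("CR", "PR"), length.out = spec$n_responders),
              rep("SD", spec$n_nonresponders))
  cv <- spec$case_variability
  percase <- withr::with_seed(child_seed(spec$seed, 900001L), list(
    radius = runif(n, spec$tumor_radius_range[1], spec$tumor_radius_range[2]),
    corr_mult = exp(rnorm(n, sd = cv$log_correlation_sd)),
    het_mult = exp(rnorm(n, sd = cv$log_heterogeneity_sd)),
    mean_shift = rnorm(n, sd = cv$mean_intensity_sd),
    skew_shift = rnorm(n, sd = cv$skew_sd),
    noise_mult = exp(rnorm(n, sd = cv$log_noise_sd))))
  lapply(seq_len(n), function(i) {
    responder <- labels[i] %in% c("CR", "PR")
    params <- if (responder) spec$responder_texture else spec$nonresponder_texture
    params$correlation_length <- params$correlation_length * percase$corr_mult[i]
    params$heterogeneity_sd <- params$heterogeneity_sd * percase$het_mult[i]
    params$mean_intensity <- params$mean_intensity + percase$mean_shift[i]
    params$skew_strength <- max(0, params$skew_strength + percase$skew_shift[i])
    tumor <- generate_tumor_volume(params, spec$volume_shape, spec$voxel_spacing,
                                   percase$radius[i],
                                   spec$noise_sd * percase$noise_mult[i],
                                   background = spec$background_intensity,
                                   seed = child_seed(spec$seed, i))
    mask2 <- perturb_mask(tumor$mask, spec$contour_perturbation_mm,
                          spec$voxel_spacing, seed = child_seed(spec$seed, 100000L + i))
    structure(list(case_id = sprintf("case_%03d", i),
                   volume = tumor$volume,
                   mask_primary = tumor$mask,
                   mask_secondary = mask2,
                   label = labels[i],
                   responder = responder),
              class = "patient_case")
  })
}

#' @export
print.patient_case <- function(x, ...) {
  cat(sprintf("<patient_case %s> label=%s responder=%s, %d mask voxels\n",
              x$case_id, x$label, x$responder, sum(x$mask_primary)))
  invisible(x)
}

#' Write a cohort to disk as NIfTI volumes plus a label table
#'
#' Writes `<case_id>.nii.gz`, `<case_id>_mask1.nii.gz`,
#' `<case_id>_mask2.nii.gz` per case, `cohort.csv`
#' (case_id, label, responder, split) and `spec.json` into `dir`.
#'
#' @param cases List of `patient_case` (from [generate_cohort()]).
#' @param dir Output directory (created if needed).
#' @param split Optional character vector ("train"/"test") per case.
#' @param spec Optional [cohort_spec()] echoed to `spec.json`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cases, dir, split = NULL, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (case in cases) {
    pix <- case$volume$spacing
    img <- RNifti::asNifti(case$volume$data, reference = NULL)
    RNifti::pixdim(img) <- pix
    RNifti::writeNifti(img, file.path(dir, paste0(case$case_id, ".nii.gz")))
    m1 <- RNifti::asNifti(case$mask_primary + 0L); RNifti::pixdim(m1) <- pix
    RNifti::writeNifti(m1, file.path(dir, paste0(case$case_id, "_mask1.nii.gz")))
    if (!is.null(case$mask_secondary)) {
      m2 <- RNifti::asNifti(case$mask_secondary + 0L); RNifti::pixdim(m2) <- pix
      RNifti::writeNifti(m2, file.path(dir, paste0(case$case_id, "_mask2.nii.gz")))
    }
  }
  tab <- data.frame(case_id = vapply(cases, `[[`, "", "case_id"),
                    label = vapply(cases, `[[`, "", "label"),
                    responder = vapply(cases, `[[`, TRUE, "responder"),
                    split = if (is.null(split)) NA_character_ else split)
  write.csv(tab, file.path(dir, "cohort.csv"), row.names = FALSE)
  if (!is.null(spec)) {
    sp <- spec
    sp$responder_texture <- unclass(sp$responder_texture)
    sp$nonresponder_texture <- unclass(sp$nonresponder_texture)
    jsonlite::write_json(unclass(sp), file.path(dir, "spec.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a directory of volumes, masks and labels back into patient cases
#'
#' Inverse of [write_cohort()]: expects `cohort.csv` with columns
#' `case_id`, `label` (CR/PR/SD/PD) and optionally `split`, plus per case a
#' volume file and at least a primary mask. Cases with only one observer mask
#' are accepted (they are excluded from reproducibility analysis downstream).
#'
#' @param dir Directory written by [write_cohort()] (or hand-assembled to the
#'   same layout).
#' @return List of `patient_case` objects with a `split` attribute per case.
#' @export
read_case_directory <- function(dir) {
  tab_path <- file.path(dir, "cohort.csv")
  if (!file.exists(tab_path)) stopf("no cohort.csv in %s", dir)
  tab <- read.csv(tab_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    cid <- tab$case_id[i]
    label <- tab$label[i]
    if (!label %in% c("CR", "PR", "SD", "PD"))
      stopf("case %s: unknown response label '%s'", cid, label)
    vol_path <- file.path(dir, paste0(cid, ".nii.gz"))
    m1_path <- file.path(dir, paste0(cid, "_mask1.nii.gz"))
    m2_path <- file.path(dir, paste0(cid, "_mask2.nii.gz"))
    if (!file.exists(vol_path)) stopf("case %s: missing volume file", cid)
    if (!file.exists(m1_path)) stopf("case %s: missing primary mask", cid)
    img <- RNifti::readNifti(vol_path)
    spacing <- RNifti::pixdim(img)[1:3]
    vol <- image_volume(array(as.numeric(img), dim(img)[1:3]), spacing)
    m1 <- RNifti::readNifti(m1_path)
    if (!identical(dim(m1)[1:3], dim(img)[1:3]))
      stopf("case %s: mask shape does not match volume", cid)
    mask1 <- array(as.numeric(m1) > 0.5, dim(img)[1:3])
    if (!any(mask1)) stopf("case %s: empty primary mask", cid)
    mask2 <- NULL
    if (file.exists(m2_path)) {
      m2 <- RNifti::readNifti(m2_path)
      if (!identical(dim(m2)[1:3], dim(img)[1:3]))
        stopf("case %s: secondary mask shape does not match volume", cid)
      mask2 <- array(as.numeric(m2) > 0.5, dim(img)[1:3])
    }
    case <- structure(list(case_id = cid, volume = vol, mask_primary = mask1,
                           mask_secondary = mask2, label = label,
                           responder = label %in% c("CR", "PR")),
                      class = "patient_case")
    attr(case, "split") <- if ("split" %in% names(tab)) tab$split[i] else NA_character_
    case
  })
}
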