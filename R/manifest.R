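#' The canonical 214-feature manifest
#'
#' Single source of truth for the ordered feature inventory: 60
#' three-dimensional features (4 shape + 6 histogram + 19 GLCM + 13 GLRLM +
#' 13 GLSZM + 5 NGTDM) and 154 two-dimensional features (6 histogram +
#' 9 GLCM + 13 GLRLM + 13 GLSZM + 5 NGTDM + 10 GLGCM + 18 LoG + 80 Gabor),
#' extracted from the largest axial tumor section. Names encode family and
#' dimensionality, e.g. `Histogram2D_skewness`, `GLSZM2D_LZE`,
#' `Gabor2D_MSA-54`.
#'
#' @return A data.frame with columns `name`, `family` (shape / histogram /
#'   texture / transform), `dimensionality` ("3D"/"2D") and `definition_id`,
#'   with exactly 214 rows.
#' @export
feature_manifest <- function() {
  hist_stats <- c("mean", "variance", "skewness", "kurtosis", "energy", "entropy")
  rows <- list(
    data.frame(name = paste0("Shape3D_", c("volume", "size", "solidity", "eccentricity")),
               family = "shape", dimensionality = "3D",
               definition_id = paste0("shape.", c("volume", "size", "solidity", "eccentricity"))),
    data.frame(name = paste0("Histogram3D_", hist_stats),
               family = "histogram", dimensionality = "3D",
               definition_id = paste0("histogram.", hist_stats)),
    data.frame(name = paste0("GLCM3D_", glcm_feature_names_3d),
               family = "texture", dimensionality = "3D",
               definition_id = paste0("glcm.", glcm_feature_names_3d)),
    data.frame(name = paste0("GLRLM3D_", glrlm_feature_names),
               family = "texture", dimensionality = "3D",
               definition_id = paste0("glrlm.", glrlm_feature_names)),
    data.frame(name = paste0("GLSZM3D_", glszm_feature_names),
               family = "texture", dimensionality = "3D",
               definition_id = paste0("glszm.", glszm_feature_names)),
    data.frame(name = paste0("NGTDM3D_", ngtdm_feature_names),
               family = "texture", dimensionality = "3D",
               definition_id = paste0("ngtdm.", ngtdm_feature_names)),
    data.frame(name = paste0("Histogram2D_", hist_stats),
               family = "histogram", dimensionality = "2D",
               definition_id = paste0("histogram.", hist_stats)),
    data.frame(name = paste0("GLCM2D_", glcm_feature_names_2d),
               family = "texture", dimensionality = "2D",
               definition_id = paste0("glcm.", glcm_feature_names_2d)),
    data.frame(name = paste0("GLRLM2D_", glrlm_feature_names),
               family = "texture", dimensionality = "2D",
               definition_id = paste0("glrlm.", glrlm_feature_names)),
    data.frame(name = paste0("GLSZM2D_", glszm_feature_names),
               family = "texture", dimensionality = "2D",
               definition_id = paste0("glszm.", glszm_feature_names)),
    data.frame(name = paste0("NGTDM2D_", ngtdm_feature_names),
               family = "texture", dimensionality = "2D",
               definition_id = paste0("ngtdm.", ngtdm_feature_names)),
    data.frame(name = paste0("GLGCM2D_", glgcm_feature_names),
               family = "texture", dimensionality = "2D",
               definition_id = paste0("glgcm.", glgcm_feature_names)),
    data.frame(name = paste0("LoG2D_", as.vector(outer(sprintf("sigma%.1f", c(1, 2, 2.5)),
                                                       hist_stats, paste, sep = "_"))),
               family = "transform", dimensionality = "2D",
               definition_id = "log"),
    data.frame(name = paste0("Gabor2D_", c(as.vector(t(outer(1:5, 1:8, function(s, o) sprintf("MSA-%d%d", s, o)))),
                                           as.vector(t(outer(1:5, 1:8, function(s, o) sprintf("MSE-%d%d", s, o)))))),
               family = "transform", dimensionality = "2D",
               definition_id = "gabor")
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stopifnot(nrow(out) == 214, !anyDuplicated(out$name),
            sum(out$dimensionality == "3D") == 60,
            sum(out$dimensionality == "2D") == 154)
  out
}

#' Extraction configuration
#'
#' @param target_spacing Isotropic resampling target, mm.
#' @param k_bits Quantization bits (2^k gray levels, default 16 levels).
#' @return List of class `extract_config`.
#' @export
extract_config <- function(target_spacing = c(1, 1, 1), k_bits = 4L) {
  structure(list(target_spacing = target_spacing, k_bits = as.integer(k_bits)),
            class = "extract_config")
}

#' Extract the full 214-feature vector for one case
#'
#' Resamples to isotropic voxels, quantizes the 3D ROI and (separately, over
#' the section's own intensity range) the largest axial section, then runs
#' every feature family. Fully deterministic.
#'
#' @param case A `patient_case`.
#' @param config An [extract_config()].
#' @param observer 1 (primary mask) or 2 (secondary observer's mask).
#' @return Named numeric vector in [feature_manifest()] order (length 214,
#'   all finite).
#' @export
extract_all <- function(case, config = extract_config(), observer = 1L) {
  mask <- if (observer == 1L) case$mask_primary else case$mask_secondary
  if (is.null(mask)) stopf("case %s has no observer-%d mask", case$case_id, observer)
  res <- tryCatch(
    resample_isotropic(case$volume, mask, config$target_spacing),
    error = function(e) stopf("case %s: %s", case$case_id, conditionMessage(e)))
  roi3 <- quantize_gray_levels(res$volume, res$mask, config$k_bits)
  sec <- axial_section(res$volume, res$mask)
  roi2 <- quantize_gray_levels(sec$intensity, sec$mask, config$k_bits)

  prefixed <- function(x, prefix) setNames(x, paste0(prefix, names(x)))
  vals <- c(
    prefixed(shape_features(res$mask, res$volume$spacing), "Shape3D_"),
    prefixed(histogram_features(roi3), "Histogram3D_"),
    prefixed(glcm_features(glcm_matrix(roi3), glcm_feature_names_3d), "GLCM3D_"),
    prefixed(setNames(glrlm_features(roi3), glrlm_feature_names), "GLRLM3D_"),
    prefixed(glszm_features(roi3), "GLSZM3D_"),
    prefixed(ngtdm_features(roi3), "NGTDM3D_"),
    prefixed(histogram_features(roi2), "Histogram2D_"),
    prefixed(glcm_features(glcm_matrix(roi2), glcm_feature_names_2d), "GLCM2D_"),
    prefixed(setNames(glrlm_features(roi2), glrlm_feature_names), "GLRLM2D_"),
    prefixed(glszm_features(roi2), "GLSZM2D_"),
    prefixed(ngtdm_features(roi2), "NGTDM2D_"),
    prefixed(glgcm_features(roi2), "GLGCM2D_"),
    prefixed(log_features(sec$intensity, sec$mask), "LoG2D_"),
    prefixed(gabor_features(sec$intensity, sec$mask), "Gabor2D_")
  )
  manifest <- feature_manifest()
  out <- vals[manifest$name]
  if (anyNA(out) || !all(is.finite(out)))
    stopf("case %s: non-finite feature values", case$case_id)
  out
}

#' Extract a feature table for a whole cohort
#'
#' @param cases List of `patient_case`.
#' @param config An [extract_config()].
#' @param observer 1 or 2.
#' @return data.frame: `case_id` column plus the 214 manifest features.
#' @export
extract_cohort <- function(cases, config = extract_config(), observer = 1L) {
  mat <- t(vapply(cases, extract_all, numeric(214), config = config,
                  observer = observer))
  out <- data.frame(case_id = vapply(cases, `[[`, "", "case_id"),
                    mat, check.names = FALSE)
  rownames(out) <- NULL
  out
}
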