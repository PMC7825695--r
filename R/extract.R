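#' Extraction configuration
#'
#' Bundles the tunable parameters of feature extraction: fixed bin width 25,
#' resampling to 2 x 2 x 2 mm, a 5 mm Laplacian-of-Gaussian width, the coif1
#' wavelet family, and co-occurrence distance 1 with mean-over-directions
#' aggregation over the 13 unique 3D directions.
#'
#' @param bin_width discretization bin width, intensity units (> 0).
#' @param spacing target voxel spacing in mm, or `NULL` to extract on the
#'   native grid.
#' @param log_sigma Laplacian-of-Gaussian width in mm.
#' @param wavelet_family wavelet family name.
#' @param glcm_distance co-occurrence distance in voxels.
#' @param image_types derived-image classes to extract from; any subset of
#'   `c("original", "log", "wavelet")`.
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(bin_width = 25, spacing = c(2, 2, 2),
                              log_sigma = 5, wavelet_family = "coif1",
                              glcm_distance = 1L,
                              image_types = c("original", "log", "wavelet")) {
  stopifnot(bin_width > 0, log_sigma > 0, glcm_distance >= 1)
  image_types <- match.arg(image_types, several.ok = TRUE)
  structure(
    list(
      bin_width = bin_width, spacing = spacing, log_sigma = log_sigma,
      wavelet_family = wavelet_family, glcm_distance = as.integer(glcm_distance),
      image_types = image_types
    ),
    class = "extraction_config"
  )
}

.WAVELET_BANDS <- c("HHH", "HHL", "HLH", "HLL", "LHH", "LHL", "LLH", "LLL")

.image_names <- function(config) {
  out <- character(0)
  if ("original" %in% config$image_types) out <- c(out, "original")
  if ("log" %in% config$image_types) {
    out <- c(out, sprintf("log-sigma-%gmm", config$log_sigma))
  }
  if ("wavelet" %in% config$image_types) {
    out <- c(out, paste0("wavelet-", .WAVELET_BANDS))
  }
  out
}

.FIRSTORDER_NAMES <- c(
  "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
  "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
  "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
  "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity"
)
.SHAPE_NAMES <- c(
  "MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
  "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
  "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "MajorAxisLength",
  "MinorAxisLength", "LeastAxisLength", "Elongation", "Flatness"
)
.GLCM_NAMES <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy", "MCC",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares"
)
.GLRLM_NAMES <- c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis"
)
.GLSZM_NAMES <- c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis"
)
.GLDM_NAMES <- c(
  "SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "GrayLevelVariance",
  "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
  "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
  "SmallDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis",
  "LargeDependenceHighGrayLevelEmphasis"
)

#' Feature-name registry
#'
#' The frozen, ordered list of feature names for a given extraction
#' configuration: `{image-type}_{class}_{feature}`. With the default
#' configuration this is 944 names: 107 `original` (14 shape + 18
#' first-order + 24 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM + 5 NGTDM), 93 on
#' the LoG image and 93 on each of the 8 wavelet sub-bands (shape features
#' are geometry-only and are not recomputed on derived images).
#'
#' @param config an [extraction_config()].
#' @return Character vector of feature names, in extraction order.
#' @export
feature_registry <- function(config = extraction_config()) {
  classes <- list(
    firstorder = .FIRSTORDER_NAMES, glcm = .GLCM_NAMES,
    glrlm = .GLRLM_NAMES, glszm = .GLSZM_NAMES, gldm = .GLDM_NAMES,
    ngtdm = c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
  )
  out <- character(0)
  if ("original" %in% config$image_types) {
    out <- c(out, paste0("original_shape_", .SHAPE_NAMES))
  }
  for (img in .image_names(config)) {
    for (cl in names(classes)) {
      out <- c(out, paste(img, cl, classes[[cl]], sep = "_"))
    }
  }
  out
}

#' Write the feature-name registry to a text file
#'
#' @param path output path.
#' @param config an [extraction_config()].
#' @return `path`, invisibly.
#' @export
write_feature_registry <- function(path, config = extraction_config()) {
  writeLines(feature_registry(config), path)
  invisible(path)
}

# all intensity-class features on one (possibly derived) image
.intensity_features <- function(volume, mask, config, image_name) {
  disc <- discretize(volume, mask, config$bin_width)
  out <- c(
    compute_first_order(volume, mask, config$bin_width),
    compute_glcm_features(disc, config$glcm_distance),
    compute_glrlm_features(disc),
    compute_glszm_features(disc),
    compute_gldm_features(disc),
    compute_ngtdm_features(disc)
  )
  classes <- rep(
    c("firstorder", "glcm", "glrlm", "glszm", "gldm", "ngtdm"),
    c(18, 24, 16, 16, 14, 5)
  )
  names(out) <- paste(image_name, classes, names(out), sep = "_")
  out
}

#' Extract the full radiomic feature vector for one ROI
#'
#' Resamples volume and mask to the configured spacing, derives the LoG and
#' 8 wavelet sub-band images, and computes every configured feature class,
#' returning the named vector in registry order (944 features with the
#' default configuration).
#'
#' @param volume an [image_volume()] (already bias-corrected/normalised).
#' @param mask an aligned [roi_mask()].
#' @param config an [extraction_config()].
#' @return Named numeric vector matching [feature_registry()].
#' @export
extract_all <- function(volume, mask, config = extraction_config()) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "roi_mask"))
  .check_aligned(volume, mask)
  if (!is.null(config$spacing)) {
    rs <- resample_volume(volume, mask, config$spacing)
    volume <- rs$volume
    mask <- rs$mask
  }
  out <- numeric(0)
  if ("original" %in% config$image_types) {
    shp <- compute_shape(mask)
    names(shp) <- paste0("original_shape_", names(shp))
    out <- c(
      out, shp,
      .with_class_context("original", .intensity_features(volume, mask, config, "original"))
    )
  }
  if ("log" %in% config$image_types) {
    nm <- sprintf("log-sigma-%gmm", config$log_sigma)
    lg <- apply_log_filter(volume, config$log_sigma)
    out <- c(out, .with_class_context(nm, .intensity_features(lg, mask, config, nm)))
  }
  if ("wavelet" %in% config$image_types) {
    wb <- wavelet_decompose(volume, config$wavelet_family)
    for (b in .WAVELET_BANDS) {
      nm <- paste0("wavelet-", b)
      out <- c(out, .with_class_context(nm, .intensity_features(wb[[b]], mask, config, nm)))
    }
  }
  out
}

.with_class_context <- function(image_name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("feature extraction failed on image '%s': %s", image_name, conditionMessage(e)),
      call. = FALSE
    )
  })
}

#' Extract a feature table for a set of patients
#'
#' Applies the preprocessing chain (bias correction, histogram matching to a
#' reference volume, resampling) and [extract_all()] to each
#' (volume, mask) pair.
#'
#' @param volumes list of [image_volume()] objects.
#' @param masks list of aligned [roi_mask()] objects (same length).
#' @param config an [extraction_config()].
#' @param preprocess logical; run bias correction + histogram matching
#'   first (default TRUE).
#' @param reference_index index of the histogram-matching reference volume
#'   (default 1, the first volume — a deterministic choice).
#' @param n_landmarks quantile landmarks for histogram matching.
#' @param bias_sigma_mm width of the bias-field estimator, mm.
#' @return A numeric matrix, one row per patient, columns =
#'   [feature_registry()].
#' @export
extract_feature_table <- function(volumes, masks, config = extraction_config(),
                                  preprocess = TRUE, reference_index = 1L,
                                  n_landmarks = 64, bias_sigma_mm = 25) {
  stopifnot(length(volumes) == length(masks), length(volumes) >= 1L)
  if (preprocess) {
    volumes <- lapply(volumes, correct_bias_field, sigma_mm = bias_sigma_mm)
    ref <- volumes[[reference_index]]
    volumes <- lapply(volumes, match_histogram, reference = ref, n_landmarks = n_landmarks)
  }
  rows <- lapply(seq_along(volumes), function(i) {
    extract_all(volumes[[i]], masks[[i]], config)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- names(volumes)
  tab
}
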