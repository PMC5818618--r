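#' Extraction configuration
#'
#' @param n_bins Gray levels for the histogram and both texture matrices
#'   (default 32, ROI-relative equal-width bins).
#' @param energy_variant \code{"uniformity"} (sum of squared histogram
#'   probabilities, the default) or \code{"intensity"} (sum of squared HU
#'   values over the ROI).
#' @return A list of class \code{extraction_config}.
#' @export
extraction_config <- function(n_bins = 32L, energy_variant = c("uniformity", "intensity")) {
  energy_variant <- match.arg(energy_variant)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  structure(list(n_bins = as.integer(n_bins), energy_variant = energy_variant),
            class = "extraction_config")
}

#' The frozen tumor feature list
#'
#' The 52 quantitative tumor features and their six imaging categories:
#' global (2), histogram-based (15), lung cancer-specific (4), shape (7),
#' local / GLCM (13) and regional / GLSZM (11).
#'
#' @return data.frame with columns \code{feature} and \code{category}.
#' @export
tumor_feature_list <- function() {
  spec <- list(
    global = c("volume_ml", "mass_g"),
    histogram = c("mean", "sd", "min", "max", "range", "energy", "entropy",
                  "kurtosis", "skewness", "iqr", "p2.5", "p25", "p50", "p75",
                  "p97.5"),
    lung_cancer_specific = c("mpp", "positive_pixel_fraction", "positive_sd",
                             "positive_entropy"),
    shape = c("surface_area_mm2", "sphericity", "spherical_disproportion",
              "surface_to_volume", "max_3d_diameter_mm", "compactness1",
              "compactness2"),
    local = c("autocorrelation", "cluster_prominence", "cluster_shade",
              "cluster_tendency", "contrast", "correlation", "dissimilarity",
              "glcm_energy", "glcm_entropy", "homogeneity",
              "inverse_difference_moment", "maximum_probability",
              "sum_average"),
    regional = c("small_zone_emphasis", "large_zone_emphasis",
                 "intensity_variability", "size_zone_variability",
                 "zone_percentage", "low_intensity_emphasis",
                 "high_intensity_emphasis", "low_intensity_small_zone_emphasis",
                 "high_intensity_small_zone_emphasis",
                 "low_intensity_large_zone_emphasis",
                 "high_intensity_large_zone_emphasis"))
  data.frame(feature = unlist(spec, use.names = FALSE),
             category = rep(names(spec), lengths(spec)),
             stringsAsFactors = FALSE)
}

#' Extract all 52 tumor features from a volume and mask
#'
#' Runs the global, histogram-based, lung cancer-specific, shape, GLCM and
#' GLSZM extractors and assembles a single feature vector. Features that are
#' undefined for the input (e.g. MPP with no positive voxels, skewness of a
#' constant ROI) are carried as NA, never silently zero. The result is
#' deterministic given the inputs and configuration.
#'
#' @param volume An \code{image_volume}.
#' @param mask A \code{roi_mask} on the same grid.
#' @param config An \code{extraction_config}.
#' @return A \code{feature_vector}: list with \code{values} (named numeric,
#'   length 52) and \code{categories} (named character).
#' @export
extract_all <- function(volume, mask, config = extraction_config()) {
  stopifnot(inherits(config, "extraction_config"))
  vox <- roi_voxels(volume, mask)
  hu <- vox$hu
  run <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("feature group '", what, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  glob <- run("global", global_features(volume, mask))
  hist_f <- run("histogram", histogram_features(hu, config$n_bins))
  if (config$energy_variant == "intensity") hist_f$energy <- sum(hu^2)
  lcs <- run("lung_cancer_specific", lung_cancer_specific_features(hu, config$n_bins))
  shp <- run("shape", shape_features(mask))

  # place discretized levels back on the grid via the same voxel ordering
  # roi_voxels used to pull hu out
  lev_vec <- discretize(hu, config$n_bins)
  lev <- array(0L, dim(mask$data))
  lev[cbind(vox$i, vox$j, vox$k)] <- lev_vec

  loc <- run("local", glcm_features(glcm(lev, mask, n_levels = config$n_bins)))
  reg <- run("regional", glszm_features(glszm(lev, mask, n_levels = config$n_bins)))

  all <- c(glob, hist_f, lcs, shp, loc, reg)
  ref <- tumor_feature_list()
  vals <- vapply(ref$feature, function(f) {
    v <- all[[f]]
    if (is.null(v)) stop("feature '", f, "' was not computed")
    as.numeric(v)
  }, numeric(1))
  structure(list(values = vals,
                 categories = stats::setNames(ref$category, ref$feature)),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("<feature_vector> ", length(x$values), " features in ",
      length(unique(x$categories)), " categories\n", sep = "")
  invisible(x)
}

#' Convert a feature vector to a tidy data.frame
#'
#' @param fv A \code{feature_vector}.
#' @param patient_id Optional patient identifier column.
#' @return data.frame with columns patient_id (if given), feature, category,
#'   value.
#' @export
feature_vector_to_df <- function(fv, patient_id = NULL) {
  stopifnot(inherits(fv, "feature_vector"))
  df <- data.frame(feature = names(fv$values),
                   category = unname(fv$categories[names(fv$values)]),
                   value = unname(fv$values),
                   stringsAsFactors = FALSE)
  if (!is.null(patient_id)) df <- cbind(patient_id = patient_id, df)
  df
}
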