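#' Discretize HU values into equal-width gray levels
#'
#' Bins span the ROI's own [min, max]. The maximum maps to \code{n_bins};
#' a constant input maps every voxel to level 1. This is the discretization
#' used for the intensity histogram and for both texture matrices.
#'
#' @param hu_values Numeric vector of HU values (non-empty).
#' @param n_bins Number of gray levels (>= 2).
#' @return Integer vector of levels in \code{1..n_bins}.
#' @export
discretize <- function(hu_values, n_bins = 32L) {
  if (length(hu_values) == 0L) stop("no values to discretize")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  rng <- range(hu_values)
  if (rng[1] == rng[2]) return(rep.int(1L, length(hu_values)))
  lev <- floor(n_bins * (hu_values - rng[1]) / (rng[2] - rng[1])) + 1L
  lev[lev > n_bins] <- n_bins
  as.integer(lev)
}

#' Global tumor features: volume and mass
#'
#' Volume is voxel count times the physical voxel volume. Mass converts HU to
#' physical density via (HU + 1000)/1000 g/cm3 (water = 0 HU = 1 g/cm3),
#' clipping negative densities to zero voxel-wise, and integrates over the ROI.
#'
#' @param volume An \code{image_volume}.
#' @param mask A \code{roi_mask}.
#' @return Named list with \code{volume_ml} and \code{mass_g}.
#' @export
global_features <- function(volume, mask) {
  vox <- roi_voxels(volume, mask)
  vox_ml <- prod(volume$spacing) / 1000          # mm3 -> cm3 (= ml)
  density <- pmax((vox$hu + 1000) / 1000, 0)     # g/cm3
  list(volume_ml = nrow(vox) * vox_ml,
       mass_g = sum(density) * vox_ml)
}

#' Histogram-based first-order features
#'
#' Energy and entropy are computed on the discretized intensity histogram
#' (energy = sum of squared bin probabilities, the uniformity form; entropy in
#' bits). Kurtosis is Fisher (excess); skewness and kurtosis of a constant ROI
#' are undefined and returned as NA. Percentiles use linear interpolation.
#'
#' @param hu_values Numeric vector of ROI HU values.
#' @param n_bins Gray levels for the histogram energy/entropy (default 32).
#' @return Named list of 15 statistics.
#' @export
histogram_features <- function(hu_values, n_bins = 32L) {
  if (length(hu_values) == 0L) stop("empty ROI")
  x <- hu_values
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  qs <- stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975),
                        names = FALSE, type = 7)
  lev <- discretize(x, n_bins)
  p <- tabulate(lev, nbins = max(lev)) / n
  p <- p[p > 0]
  if (m2 > 0) {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2 - 3
  } else {
    skew <- NA_real_
    kurt <- NA_real_
  }
  list(mean = mu,
       sd = stats::sd(x),
       min = min(x),
       max = max(x),
       range = max(x) - min(x),
       energy = sum(p^2),
       entropy = -sum(p * log2(p)),
       kurtosis = kurt,
       skewness = skew,
       iqr = qs[4] - qs[2],
       p2.5 = qs[1],
       p25 = qs[2],
       p50 = qs[3],
       p75 = qs[4],
       p97.5 = qs[5])
}

#' Mean value of positive pixels (MPP)
#'
#' Mean HU over ROI voxels strictly above 0 HU; NA if no voxel is positive.
#' MPP restricts attention to soft-tissue-density (non-air, non-fat) voxels
#' and is treated as a lung cancer-specific feature.
#'
#' @param hu_values Numeric vector of ROI HU values.
#' @return Scalar, or NA if no positive voxels.
#' @export
mpp <- function(hu_values) {
  pos <- hu_values[hu_values > 0]
  if (length(pos) == 0L) return(NA_real_)
  mean(pos)
}

# Lung cancer-specific first-order set built on the positive-pixel
# distribution; all but the fraction are NA when no voxel exceeds 0 HU.
lung_cancer_specific_features <- function(hu_values, n_bins = 32L) {
  pos <- hu_values[hu_values > 0]
  out <- list(mpp = NA_real_, positive_pixel_fraction = 0,
              positive_sd = NA_real_, positive_entropy = NA_real_)
  if (length(pos) == 0L) return(out)
  out$mpp <- mean(pos)
  out$positive_pixel_fraction <- length(pos) / length(hu_values)
  out$positive_sd <- if (length(pos) > 1L) stats::sd(pos) else 0
  p <- tabulate(discretize(pos, n_bins)) / length(pos)
  p <- p[p > 0]
  out$positive_entropy <- -sum(p * log2(p))
  out
}
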