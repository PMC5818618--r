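#' Segment left and right lungs by thresholding and connected components
#'
#' Voxels below \code{threshold} HU that are not connected (26-connectivity)
#' to the volume border are lung candidates; the two largest components are
#' taken as the lungs and assigned right/left by centroid x-coordinate, with
#' the right lung at the smaller x (radiological convention: the patient's
#' right appears on the image left).
#'
#' @param volume An \code{image_volume} of an inspiratory chest CT.
#' @param threshold Lung candidate threshold in HU (default -300, strictly
#'   below).
#' @return A \code{lung_masks} object: list with \code{left} and \code{right}
#'   \code{roi_mask}s (disjoint by construction).
#' @export
segment_lungs <- function(volume, threshold = -300) {
  stopifnot(inherits(volume, "image_volume"))
  cand <- volume$data < threshold
  if (!any(cand)) stop("lung segmentation failed: no sub-threshold voxels")
  lab <- label_components_26(array(as.integer(cand), dim(cand)))
  d <- dim(lab)
  border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
  border <- border[border > 0L]
  keep <- setdiff(seq_len(max(lab)), border)
  if (length(keep) < 2L)
    stop("lung segmentation failed: fewer than two interior low-attenuation components")
  sizes <- tabulate(lab[lab > 0L])
  top2 <- keep[order(sizes[keep], decreasing = TRUE)][1:2]
  cx <- vapply(top2, function(l) mean(which(lab == l, arr.ind = TRUE)[, 1]),
               numeric(1))
  right_lab <- top2[which.min(cx)]
  left_lab <- top2[which.max(cx)]
  structure(list(
    left = roi_mask(array(as.integer(lab == left_lab), d), volume),
    right = roi_mask(array(as.integer(lab == right_lab), d), volume)),
    class = "lung_masks")
}

#' The 11 emphysema features
#'
#' Emphysema is defined as lung voxels with attenuation of -950 HU or less
#' (inclusive) on inspiratory CT. Normal lung volume is total lung volume
#' minus emphysema volume; the emphysema index is the percentage of lung
#' voxels at or below -950 HU, reported overall and per side.
#'
#' @param volume An \code{image_volume}.
#' @param lungs A \code{lung_masks} object (e.g. from
#'   \code{\link{segment_lungs}}).
#' @param threshold_hu Emphysema threshold in HU, inclusive (default -950).
#' @return Named list of exactly 11 features: total/right/left lung volume
#'   (ml), total/right/left emphysema volume (ml), emphysema index (\%),
#'   right/left emphysema index (\%), normal lung volume (ml) and normal lung
#'   percentage (\%).
#' @export
emphysema_features <- function(volume, lungs, threshold_hu = -950) {
  stopifnot(inherits(volume, "image_volume"), inherits(lungs, "lung_masks"))
  vox_ml <- prod(volume$spacing) / 1000
  side <- function(mask) {
    n <- sum(mask$data)
    if (n == 0L) stop("empty lung mask")
    hu <- volume$data[mask$data != 0L]
    e <- sum(hu <= threshold_hu)
    c(n = n, e = e)
  }
  r <- side(lungs$right)
  l <- side(lungs$left)
  n_tot <- r["n"] + l["n"]
  e_tot <- r["e"] + l["e"]
  list(total_lung_volume_ml = unname(n_tot * vox_ml),
       right_lung_volume_ml = unname(r["n"] * vox_ml),
       left_lung_volume_ml = unname(l["n"] * vox_ml),
       emphysema_volume_ml = unname(e_tot * vox_ml),
       right_emphysema_volume_ml = unname(r["e"] * vox_ml),
       left_emphysema_volume_ml = unname(l["e"] * vox_ml),
       emphysema_index_pct = unname(100 * e_tot / n_tot),
       right_emphysema_index_pct = unname(100 * r["e"] / r["n"]),
       left_emphysema_index_pct = unname(100 * l["e"] / l["n"]),
       normal_lung_volume_ml = unname((n_tot - e_tot) * vox_ml),
       normal_lung_percentage = unname(100 * (n_tot - e_tot) / n_tot))
}

#' The frozen emphysema feature list
#'
#' @return data.frame with columns \code{feature} and \code{category}
#'   (all \code{"emphysema"}).
#' @export
emphysema_feature_list <- function() {
  data.frame(feature = c("total_lung_volume_ml", "right_lung_volume_ml",
                         "left_lung_volume_ml", "emphysema_volume_ml",
                         "right_emphysema_volume_ml", "left_emphysema_volume_ml",
                         "emphysema_index_pct", "right_emphysema_index_pct",
                         "left_emphysema_index_pct", "normal_lung_volume_ml",
                         "normal_lung_percentage"),
             category = "emphysema", stringsAsFactors = FALSE)
}
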