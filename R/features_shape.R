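#' Shape features of a tumor mask
#'
#' Surface area is computed by exposed-face counting: a voxel face is exposed
#' if its 6-neighbour is background or outside the grid, and each face
#' contributes its physical area (e.g. dy*dz for a face normal to x). This is
#' exact for box-shaped phantoms and carries a documented staircase bias for
#' curved surfaces. The maximum 3D diameter is the largest Euclidean distance
#' between foreground voxel centres in mm. With V the physical volume and
#' r = (3V / 4 pi)^(1/3) the radius of the equal-volume sphere, spherical
#' disproportion is A / (4 pi r^2) (>= 1, larger = more irregular) and
#' sphericity is its reciprocal.
#'
#' @param mask A \code{roi_mask}.
#' @param spacing Voxel spacing in mm; defaults to the mask's own.
#' @return Named list: \code{surface_area_mm2}, \code{sphericity},
#'   \code{spherical_disproportion}, \code{surface_to_volume},
#'   \code{max_3d_diameter_mm}, \code{compactness1}, \code{compactness2}.
#' @export
shape_features <- function(mask, spacing = mask$spacing) {
  stopifnot(inherits(mask, "roi_mask"))
  m <- mask$data
  n_fg <- sum(m)
  if (n_fg == 0L) stop("empty ROI")
  dx <- spacing[1]; dy <- spacing[2]; dz <- spacing[3]

  vol_mm3 <- n_fg * dx * dy * dz
  area <- exposed_face_area(m, spacing)

  surf_idx <- surface_voxel_indices(m)
  coords <- sweep(surf_idx, 2, spacing, `*`)
  max_diam <- if (nrow(coords) < 2L) 0 else max(stats::dist(coords))

  r_eq <- (3 * vol_mm3 / (4 * pi))^(1 / 3)
  sph_disp <- area / (4 * pi * r_eq^2)
  list(surface_area_mm2 = area,
       sphericity = 1 / sph_disp,
       spherical_disproportion = sph_disp,
       surface_to_volume = area / vol_mm3,
       max_3d_diameter_mm = max_diam,
       compactness1 = vol_mm3 / (sqrt(pi) * area^1.5),
       compactness2 = 36 * pi * vol_mm3^2 / area^3)
}

# Total exposed-face area in mm2. Counts, per axis, face pairs where a
# foreground voxel abuts background or the grid boundary.
exposed_face_area <- function(m, spacing) {
  d <- dim(m)
  dx <- spacing[1]; dy <- spacing[2]; dz <- spacing[3]
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  dp <- dim(pad)
  # exposed faces along each axis: foreground voxel whose shifted neighbour is 0
  n_x <- sum(pad[-1, , ] == 1L & pad[-dp[1], , ] == 0L) +
         sum(pad[-dp[1], , ] == 1L & pad[-1, , ] == 0L)
  n_y <- sum(pad[, -1, ] == 1L & pad[, -dp[2], ] == 0L) +
         sum(pad[, -dp[2], ] == 1L & pad[, -1, ] == 0L)
  n_z <- sum(pad[, , -1] == 1L & pad[, , -dp[3]] == 0L) +
         sum(pad[, , -dp[3]] == 1L & pad[, , -1] == 0L)
  n_x * dy * dz + n_y * dx * dz + n_z * dx * dy
}

# Indices (voxel units) of foreground voxels with at least one exposed face;
# the max pairwise distance over these equals the max over all foreground
# voxels, and they are far fewer for solid masks.
surface_voxel_indices <- function(m) {
  d <- dim(m)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb6 <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
         pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
         pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
         pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
         pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
         pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  which(core == 1L & !nb6, arr.ind = TRUE)
}
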