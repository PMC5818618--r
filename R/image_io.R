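#' Construct an image volume
#'
#' A 3D scalar grid of CT attenuation values in Hounsfield units (HU) with
#' per-axis voxel spacing in millimetres. Axes are ordered (x, y, z) and
#' indices are 1-based as usual in R.
#'
#' @param data 3D numeric array of HU values; must be finite everywhere.
#' @param spacing Numeric length-3 vector (dx, dy, dz) in mm; all > 0.
#' @param origin Numeric length-3 vector, world position of the first voxel
#'   centre in mm. Plays no role in feature computation.
#' @return An object of class \code{image_volume}.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D volume, got ", length(dim(data)), " dimensions")
  if (!all(is.finite(data)))
    stop("volume contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive finite values (mm)")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "image_volume")
}

#' Construct a binary region-of-interest mask
#'
#' A binary mask on the same grid as its paired volume. Any nonzero voxel is
#' treated as foreground.
#'
#' @param data 3D array; nonzero entries become foreground.
#' @param volume The paired \code{image_volume}; geometry is validated
#'   against it.
#' @return An object of class \code{roi_mask} whose \code{data} slot is an
#'   integer array of 0/1.
#' @export
roi_mask <- function(data, volume) {
  stopifnot(inherits(volume, "image_volume"))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D mask, got ", length(dim(data)), " dimensions")
  if (!identical(dim(data), dim(volume$data)))
    stop("mask shape (", paste(dim(data), collapse = "x"),
         ") does not match volume shape (",
         paste(dim(volume$data), collapse = "x"), ")")
  m <- array(as.integer(data != 0), dim = dim(data))
  structure(list(data = m, spacing = volume$spacing, origin = volume$origin),
            class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, HU range [", signif(min(x$data), 4), ", ",
      signif(max(x$data), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", sum(x$data), " foreground\n", sep = "")
  invisible(x)
}

#' Read a CT volume from a NIfTI-1 file
#'
#' HU values are taken as stored (after the NIfTI scale slope/intercept that
#' \pkg{RNifti} applies); spacing comes from the header pixdim.
#'
#' @param path Path to a .nii or .nii.gz file containing a 3D image.
#' @return An \code{image_volume}.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3D volume in ", path, ", got ", length(d), " dimensions")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("non-positive voxel spacing in header of ", path)
  org <- tryCatch(RNifti::origin(img), error = function(e) c(0, 0, 0))
  image_volume(array(as.numeric(img), dim = d), spacing = sp,
               origin = as.numeric(org)[1:3])
}

#' Read a binary mask from a NIfTI-1 file
#'
#' Nonzero voxels become foreground. The grid must match the paired volume:
#' identical shape and spacing equal to within \code{tol} mm.
#'
#' @param path Path to the mask file.
#' @param volume The \code{image_volume} the mask belongs to.
#' @param tol Spacing agreement tolerance in mm (default 1e-4).
#' @return A \code{roi_mask}.
#' @export
read_mask <- function(path, volume, tol = 1e-4) {
  stopifnot(inherits(volume, "image_volume"))
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected 3D mask in ", path, ", got ", length(d), " dimensions")
  if (!identical(as.integer(d), as.integer(dim(volume$data))))
    stop("mask shape (", paste(d, collapse = "x"),
         ") does not match volume shape (",
         paste(dim(volume$data), collapse = "x"), ")")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(abs(sp - volume$spacing) > tol))
    stop("mask spacing (", paste(signif(sp, 6), collapse = ", "),
         ") differs from volume spacing (",
         paste(signif(volume$spacing, 6), collapse = ", "),
         ") by more than ", tol, " mm")
  roi_mask(array(as.numeric(img), dim = d), volume)
}

#' Write a volume or mask to a NIfTI-1 file
#'
#' @param x An \code{image_volume} or \code{roi_mask}.
#' @param path Output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(x, path) {
  stopifnot(inherits(x, "image_volume") || inherits(x, "roi_mask"))
  img <- RNifti::asNifti(x$data)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Enumerate the voxels inside an ROI
#'
#' Returns the foreground voxels with their HU values in deterministic
#' lexicographic order of the (i, j, k) index triples (i fastest is NOT used:
#' ordering is i, then j, then k compared left to right, i.e. row-major over
#' the triple).
#'
#' @param volume An \code{image_volume}.
#' @param mask A \code{roi_mask} on the same grid.
#' @return A data.frame with columns \code{i}, \code{j}, \code{k} (1-based
#'   indices) and \code{hu}.
#' @export
roi_voxels <- function(volume, mask) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(mask$data), dim(volume$data)))
    stop("mask and volume shapes differ")
  idx <- which(mask$data != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty ROI")
  ord <- order(idx[, 1], idx[, 2], idx[, 3])
  idx <- idx[ord, , drop = FALSE]
  data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
             hu = volume$data[idx])
}
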