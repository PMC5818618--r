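#' Label 26-connected components of a 3D array
#'
#' Voxels are connected when they share a face, edge or corner (26-neighbour
#' connectivity) and carry the same value of \code{values} (when given).
#' Adjacencies are collected with vectorized array shifts over the 13 unique
#' direction offsets and resolved with a graph connected-components pass.
#'
#' @param mask 3D 0/1 array; zero voxels are background.
#' @param values Optional 3D array; components are constrained to constant
#'   value (used for gray-level zones).
#' @return Integer array of the same shape: 0 for background, and labels
#'   1..n_components (consecutive, ordered by first voxel linear index).
#' @export
label_components_26 <- function(mask, values = NULL) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  fg <- mask != 0
  if (!is.null(values)) stopifnot(identical(dim(values), d))
  fg_idx <- which(fg)
  n_fg <- length(fg_idx)
  lab <- array(0L, d)
  if (n_fg == 0L) return(lab)
  node <- array(0L, d)
  node[fg_idx] <- seq_len(n_fg)

  offs <- glcm_offsets_3d()
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    a_rng <- seq(max(1L, 1L - off[1]), min(d[1], d[1] - off[1]))
    b_rng <- seq(max(1L, 1L - off[2]), min(d[2], d[2] - off[2]))
    c_rng <- seq(max(1L, 1L - off[3]), min(d[3], d[3] - off[3]))
    if (!length(a_rng) || !length(b_rng) || !length(c_rng)) next
    from <- node[a_rng, b_rng, c_rng]
    to <- node[a_rng + off[1], b_rng + off[2], c_rng + off[3]]
    ok <- from > 0L & to > 0L
    if (!is.null(values)) {
      v1 <- values[a_rng, b_rng, c_rng]
      v2 <- values[a_rng + off[1], b_rng + off[2], c_rng + off[3]]
      ok <- ok & v1 == v2
    }
    if (any(ok)) edges[[r]] <- cbind(from[ok], to[ok])
  }
  el <- do.call(rbind, edges)
  if (is.null(el)) {
    memb <- seq_len(n_fg)
  } else {
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n_fg - igraph::vcount(g)))
    memb <- igraph::components(g, mode = "weak")$membership
  }
  # deterministic labels ordered by first (smallest) voxel linear index
  first <- match(seq_len(max(memb)), memb)
  relab <- integer(max(memb))
  relab[order(first)] <- seq_len(max(memb))
  lab[fg_idx] <- relab[memb]
  lab
}

#' Gray-level size-zone matrix over an ROI
#'
#' Zones are 26-connected components of equal discretized level within the
#' mask. Entry (g, s) counts the zones of level g with size s voxels.
#'
#' @param levels 3D integer array of gray levels in \code{1..n_levels}.
#' @param mask A \code{roi_mask} or 0/1 array of the same shape.
#' @param n_levels Number of gray levels.
#' @return A \code{glszm_matrix}: list with \code{counts} (n_levels x S),
#'   \code{n_levels}, \code{n_voxels}, \code{connectivity = 26}.
#' @export
glszm <- function(levels, mask, n_levels) {
  m <- if (inherits(mask, "roi_mask")) mask$data else array(as.integer(mask != 0), dim(mask))
  stopifnot(identical(dim(levels), dim(m)))
  if (sum(m) == 0L) stop("empty ROI")
  inside <- levels[m != 0L]
  if (min(inside) < 1L || max(inside) > n_levels)
    stop("levels outside 1..n_levels")
  lab <- label_components_26(m, values = levels)
  zone_ids <- lab[lab > 0L]
  sizes <- tabulate(zone_ids)
  # level of each zone: level at any member voxel
  first_vox <- match(seq_along(sizes), zone_ids)
  zone_level <- levels[lab > 0L][first_vox]
  s_max <- max(sizes)
  counts <- matrix(0, n_levels, s_max)
  for (z in seq_along(sizes))
    counts[zone_level[z], sizes[z]] <- counts[zone_level[z], sizes[z]] + 1
  structure(list(counts = counts, n_levels = as.integer(n_levels),
                 n_voxels = sum(m), connectivity = 26L),
            class = "glszm_matrix")
}

#' Texture features from a gray-level size-zone matrix
#'
#' With c(g, s) the zone counts and N the total number of zones:
#' size-zone variability = sum_s (sum_g c)^2 / N (zone-size non-uniformity),
#' intensity variability = sum_g (sum_s c)^2 / N (gray-level non-uniformity),
#' zone percentage = N / number of ROI voxels; the emphasis features weight
#' zones by inverse/direct squared size and level.
#'
#' @param z A \code{glszm_matrix}.
#' @return Named list of 11 GLSZM features.
#' @export
glszm_features <- function(z) {
  stopifnot(inherits(z, "glszm_matrix"))
  cnt <- z$counts
  N <- sum(cnt)
  if (N < 1) stop("no zones")
  g <- matrix(seq_len(nrow(cnt)), nrow(cnt), ncol(cnt))
  s <- matrix(seq_len(ncol(cnt)), nrow(cnt), ncol(cnt), byrow = TRUE)
  list(small_zone_emphasis = sum(cnt / s^2) / N,
       large_zone_emphasis = sum(cnt * s^2) / N,
       intensity_variability = sum(rowSums(cnt)^2) / N,
       size_zone_variability = sum(colSums(cnt)^2) / N,
       zone_percentage = N / z$n_voxels,
       low_intensity_emphasis = sum(cnt / g^2) / N,
       high_intensity_emphasis = sum(cnt * g^2) / N,
       low_intensity_small_zone_emphasis = sum(cnt / (g^2 * s^2)) / N,
       high_intensity_small_zone_emphasis = sum(cnt * g^2 / s^2) / N,
       low_intensity_large_zone_emphasis = sum(cnt * s^2 / g^2) / N,
       high_intensity_large_zone_emphasis = sum(cnt * g^2 * s^2) / N)
}
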