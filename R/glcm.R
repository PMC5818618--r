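#' The 13 unique 3D direction offsets at distance 1
#'
#' All 26-neighbourhood displacement vectors up to sign, so that each
#' co-occurrence pair is counted once per direction before symmetrization.
#'
#' @return A 13 x 3 integer matrix of (dx, dy, dz) voxel displacements.
#' @export
glcm_offsets_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), , drop = FALSE]
  # keep one representative per +/- pair: first nonzero component positive
  keep <- apply(g, 1, function(v) v[match(TRUE, v != 0)] > 0)
  m <- g[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

#' Gray-level co-occurrence matrix over an ROI
#'
#' Counts pairs of discretized levels at each offset where both voxels lie
#' inside the mask, symmetrizes each directional matrix (offset and its
#' negation), normalizes it to sum 1, and averages the normalized matrices
#' over all offsets that produced at least one pair.
#'
#' @param levels 3D integer array of gray levels in \code{1..n_levels}
#'   (entries outside the mask are ignored).
#' @param mask A \code{roi_mask} or a 3D 0/1 array of the same shape.
#' @param offsets Integer matrix of displacement vectors, one per row;
#'   default the 13 unique distance-1 directions.
#' @param n_levels Number of gray levels.
#' @return A \code{glcm_matrix}: list with \code{counts} (the averaged
#'   normalized matrix), \code{n_levels}, \code{offsets}, \code{normalized}.
#' @export
glcm <- function(levels, mask, offsets = glcm_offsets_3d(), n_levels) {
  m <- if (inherits(mask, "roi_mask")) mask$data else array(as.integer(mask != 0), dim(mask))
  stopifnot(identical(dim(levels), dim(m)))
  lv <- levels
  lv[m == 0L] <- NA_integer_
  inside <- lv[!is.na(lv)]
  if (length(inside) && (min(inside) < 1L || max(inside) > n_levels))
    stop("levels outside 1..n_levels")
  acc <- matrix(0, n_levels, n_levels)
  n_used <- 0L
  for (r in seq_len(nrow(offsets))) {
    cnt <- glcm_count_offset(lv, offsets[r, ], n_levels)
    tot <- sum(cnt)
    if (tot > 0) {
      sym <- cnt + t(cnt)
      acc <- acc + sym / sum(sym)
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0L) stop("no co-occurrences: ROI too small for all offsets")
  structure(list(counts = acc / n_used, n_levels = as.integer(n_levels),
                 offsets = offsets, normalized = TRUE),
            class = "glcm_matrix")
}

# Raw directional count matrix for one offset, vectorized via array overlap.
glcm_count_offset <- function(lv, off, n_levels) {
  d <- dim(lv)
  a_rng <- seq(max(1L, 1L - off[1]), min(d[1], d[1] - off[1]))
  b_rng <- seq(max(1L, 1L - off[2]), min(d[2], d[2] - off[2]))
  c_rng <- seq(max(1L, 1L - off[3]), min(d[3], d[3] - off[3]))
  if (!length(a_rng) || !length(b_rng) || !length(c_rng))
    return(matrix(0, n_levels, n_levels))
  from <- lv[a_rng, b_rng, c_rng]
  to <- lv[a_rng + off[1], b_rng + off[2], c_rng + off[3]]
  ok <- !is.na(from) & !is.na(to)
  if (!any(ok)) return(matrix(0, n_levels, n_levels))
  code <- (from[ok] - 1L) * n_levels + to[ok]
  matrix(tabulate(code, nbins = n_levels * n_levels),
         n_levels, n_levels, byrow = TRUE)
}

#' Texture features from a normalized GLCM
#'
#' With p(i, j) the averaged normalized matrix and marginal means
#' mu_x = sum_i i p_i+ and mu_y = sum_j j p_+j: cluster shade is
#' sum (i + j - mu_x - mu_y)^3 p(i,j), cluster prominence the same with
#' exponent 4, cluster tendency exponent 2. Correlation is NA for a
#' degenerate (single-level) matrix.
#'
#' @param g A \code{glcm_matrix} with \code{normalized = TRUE}.
#' @return Named list of 13 GLCM features.
#' @export
glcm_features <- function(g) {
  stopifnot(inherits(g, "glcm_matrix"))
  if (!isTRUE(g$normalized) || abs(sum(g$counts) - 1) > 1e-9)
    stop("GLCM must be normalized (entries summing to 1)")
  p <- g$counts
  n <- g$n_levels
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  px <- rowSums(p)
  py <- colSums(p)
  mux <- sum(seq_len(n) * px)
  muy <- sum(seq_len(n) * py)
  sx <- sqrt(sum((seq_len(n) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(n) - muy)^2 * py))
  corr <- if (sx > 0 && sy > 0) sum((i - mux) * (j - muy) * p) / (sx * sy) else NA_real_
  pp <- p[p > 0]
  list(autocorrelation = sum(i * j * p),
       cluster_prominence = sum((i + j - mux - muy)^4 * p),
       cluster_shade = sum((i + j - mux - muy)^3 * p),
       cluster_tendency = sum((i + j - mux - muy)^2 * p),
       contrast = sum((i - j)^2 * p),
       correlation = corr,
       dissimilarity = sum(abs(i - j) * p),
       glcm_energy = sum(p^2),
       glcm_entropy = -sum(pp * log2(pp)),
       homogeneity = sum(p / (1 + abs(i - j))),
       inverse_difference_moment = sum(p / (1 + (i - j)^2)),
       maximum_probability = max(p),
       sum_average = sum((i + j) * p))
}
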