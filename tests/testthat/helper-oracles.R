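# Independent brute-force oracles used to pin down the texture and counting
# code. These deliberately use plain nested loops / recursion, not the
# vectorized implementations under test.

# All 26 neighbour displacements
all_offsets_26 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(g != 0) > 0, , drop = FALSE]
}

# Exhaustive pair-counting GLCM: per offset, loop every voxel, count pairs
# with both ends in the mask, symmetrize, normalize, average over offsets.
brute_glcm <- function(lev, mask, n_levels) {
  d <- dim(lev)
  offs <- sqccradiomics::glcm_offsets_3d()
  acc <- matrix(0, n_levels, n_levels)
  n_used <- 0
  for (r in seq_len(nrow(offs))) {
    cnt <- matrix(0, n_levels, n_levels)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      if (mask[i, j, k] == 0) next
      ii <- i + offs[r, 1]; jj <- j + offs[r, 2]; kk <- k + offs[r, 3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
      if (mask[ii, jj, kk] == 0) next
      cnt[lev[i, j, k], lev[ii, jj, kk]] <- cnt[lev[i, j, k], lev[ii, jj, kk]] + 1
    }
    sym <- cnt + t(cnt)
    if (sum(sym) > 0) {
      acc <- acc + sym / sum(sym)
      n_used <- n_used + 1
    }
  }
  acc / n_used
}

# Stack-based flood fill over 26-neighbourhoods of equal level: returns a
# data.frame census of zones (level, size), sorted.
brute_zone_census <- function(lev, mask) {
  d <- dim(lev)
  seen <- array(FALSE, d)
  offs <- all_offsets_26()
  zones <- list()
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (mask[i, j, k] == 0 || seen[i, j, k]) next
    level <- lev[i, j, k]
    stack <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(offs))) {
        w <- v + offs[r, ]
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] == 0 || seen[w[1], w[2], w[3]]) next
        if (lev[w[1], w[2], w[3]] != level) next
        seen[w[1], w[2], w[3]] <- TRUE
        stack[[length(stack) + 1]] <- w
      }
    }
    zones[[length(zones) + 1]] <- c(level = level, size = size)
  }
  df <- as.data.frame(do.call(rbind, zones))
  df[order(df$level, df$size), , drop = FALSE]
}

# zone census from a glszm_matrix for comparison with the flood-fill oracle
glszm_to_census <- function(z) {
  idx <- which(z$counts > 0, arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(idx)), function(r) {
    g <- unname(idx[r, 1]); s <- unname(idx[r, 2])
    data.frame(level = rep(g, z$counts[g, s]), size = s)
  })
  df <- do.call(rbind, rows)
  df[order(df$level, df$size), , drop = FALSE]
}

# Fisher 2x2 exact p by hypergeometric tail enumeration: sum the
# probabilities of all tables with the same margins that are no more likely.
brute_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# direct-formula first-order statistics (moment loops, sorted-order quantiles)
brute_histogram_stats <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  list(mean = mu, m2 = m2,
       skewness = m3 / m2^1.5,
       kurtosis = m4 / m2^2 - 3)
}

# random discretized test instance on a dims-sized grid
random_texture_instance <- function(dims, n_levels, p_mask = 0.7) {
  mask <- array(rbinom(prod(dims), 1, p_mask), dims)
  lev <- array(sample.int(n_levels, prod(dims), replace = TRUE), dims)
  list(mask = mask, lev = lev)
}

make_box_mask <- function(dims, lo, hi, spacing = c(1, 1, 1)) {
  m <- array(0L, dims)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1L
  vol <- image_volume(array(0, dims), spacing = spacing)
  roi_mask(m, vol)
}
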