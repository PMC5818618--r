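# Run code under a temporary RNG state so generators are bit-reproducible per
# seed without clobbering the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a textured ellipsoidal tumor phantom
#'
#' @param shape Grid dimensions in voxels.
#' @param spacing Voxel spacing (dx, dy, dz) in mm.
#' @param semi_axes_mm Ellipsoid semi-axes in mm.
#' @param center_mm Ellipsoid centre in mm from the first voxel centre;
#'   default the grid centre.
#' @param base_hu Mean tumor attenuation in HU.
#' @param texture_sd Gaussian HU noise inside the tumor (0 = homogeneous).
#' @param core_fraction Fraction of each semi-axis occupied by an optional
#'   concentric low-attenuation core (0 = none); core voxels sit 30 HU below
#'   \code{base_hu}.
#' @param background_hu Attenuation outside the tumor.
#' @param seed RNG seed; fully determines the output.
#' @return A \code{phantom_spec} list.
#' @export
tumor_phantom_spec <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                               semi_axes_mm = c(12, 10, 8), center_mm = NULL,
                               base_hu = 40, texture_sd = 20,
                               core_fraction = 0, background_hu = -800,
                               seed = 1L) {
  if (is.null(center_mm)) center_mm <- (shape - 1) / 2 * spacing
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 semi_axes_mm = as.numeric(semi_axes_mm),
                 center_mm = as.numeric(center_mm), base_hu = base_hu,
                 texture_sd = texture_sd, core_fraction = core_fraction,
                 background_hu = background_hu, seed = as.integer(seed)),
            class = "phantom_spec")
}

# voxel-centre coordinate arrays in mm for a grid
grid_coords <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - 1) * spacing[1],
       y = (seq_len(shape[2]) - 1) * spacing[2],
       z = (seq_len(shape[3]) - 1) * spacing[3])
}

# boolean ellipsoid occupancy over the grid (voxel centre inside)
ellipsoid_mask <- function(shape, spacing, center, semi) {
  co <- grid_coords(shape, spacing)
  qx <- ((co$x - center[1]) / semi[1])^2
  qy <- ((co$y - center[2]) / semi[2])^2
  qz <- ((co$z - center[3]) / semi[3])^2
  q <- outer(outer(qx, qy, `+`), qz, `+`)
  array(q <= 1, shape)
}

#' Generate a textured ellipsoidal tumor phantom
#'
#' HU inside the tumor is \code{base_hu} plus i.i.d. Gaussian noise of sd
#' \code{texture_sd}; an optional concentric core sits 30 HU lower. The mask
#' is the generating ellipsoid (ground truth).
#'
#' @param spec A \code{phantom_spec}.
#' @return List with \code{volume} (\code{image_volume}) and \code{mask}
#'   (\code{roi_mask}).
#' @export
make_tumor_phantom <- function(spec = tumor_phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  ext_lo <- spec$center_mm - spec$semi_axes_mm
  ext_hi <- spec$center_mm + spec$semi_axes_mm
  if (any(ext_lo < 0) || any(ext_hi > (spec$shape - 1) * spec$spacing))
    stop("tumor ellipsoid exceeds the grid")
  m <- ellipsoid_mask(spec$shape, spec$spacing, spec$center_mm,
                      spec$semi_axes_mm)
  if (!any(m)) stop("tumor ellipsoid contains no voxel centres")
  data <- array(spec$background_hu, spec$shape)
  n_in <- sum(m)
  hu <- with_seed(spec$seed, {
    base <- rep(spec$base_hu, n_in)
    if (spec$core_fraction > 0) {
      core <- ellipsoid_mask(spec$shape, spec$spacing, spec$center_mm,
                             spec$semi_axes_mm * spec$core_fraction)
      base[core[m]] <- spec$base_hu - 30
    }
    base + if (spec$texture_sd > 0) stats::rnorm(n_in, 0, spec$texture_sd) else 0
  })
  data[m] <- hu
  vol <- image_volume(data, spacing = spec$spacing)
  list(volume = vol, mask = roi_mask(array(as.integer(m), spec$shape), vol))
}

#' Specification of a two-lung chest phantom
#'
#' A soft-tissue body ellipsoid (40 HU) in an air background (-1000 HU)
#' containing two lung ellipsoids at -850 HU.
#'
#' @param shape,spacing Grid geometry.
#' @param body_semi_mm,lung_semi_mm Body and per-lung ellipsoid semi-axes, mm.
#' @param lung_offset_mm Lung centre displacement from the body centre along
#'   x, mm.
#' @param seed RNG seed for the emphysema voxel subset.
#' @return A \code{lung_phantom_spec} list.
#' @export
lung_phantom_spec <- function(shape = c(64, 64, 56), spacing = c(1, 1, 1),
                              body_semi_mm = c(28, 24, 22),
                              lung_semi_mm = c(9, 12, 14),
                              lung_offset_mm = 13, seed = 1L) {
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 body_semi_mm = body_semi_mm, lung_semi_mm = lung_semi_mm,
                 lung_offset_mm = lung_offset_mm, seed = as.integer(seed)),
            class = "lung_phantom_spec")
}

#' Generate a chest phantom with a controllable emphysema fraction
#'
#' Within each lung ellipsoid, a random subset of exactly
#' \code{round(fraction * n)} voxels is set to -1000 HU (at or below the
#' -950 HU emphysema threshold); the rest stay at -850 HU (normal lung).
#'
#' @param emphysema_fraction Target fraction of emphysematous lung voxels in
#'   [0, 1].
#' @param spec A \code{lung_phantom_spec}.
#' @return List with \code{volume} and the ground-truth \code{left} /
#'   \code{right} lung \code{roi_mask}s.
#' @export
make_lung_phantom <- function(emphysema_fraction, spec = lung_phantom_spec()) {
  stopifnot(inherits(spec, "lung_phantom_spec"),
            emphysema_fraction >= 0, emphysema_fraction <= 1)
  ctr <- (spec$shape - 1) / 2 * spec$spacing
  body <- ellipsoid_mask(spec$shape, spec$spacing, ctr, spec$body_semi_mm)
  right <- ellipsoid_mask(spec$shape, spec$spacing,
                          ctr - c(spec$lung_offset_mm, 0, 0), spec$lung_semi_mm)
  left <- ellipsoid_mask(spec$shape, spec$spacing,
                         ctr + c(spec$lung_offset_mm, 0, 0), spec$lung_semi_mm)
  if (!all(body[right]) || !all(body[left]) || any(right & left))
    stop("invalid lung geometry: lungs must lie inside the body and be disjoint")
  data <- array(-1000, spec$shape)   # air background
  data[body] <- 40
  data[right | left] <- -850
  with_seed(spec$seed, {
    for (lung in list(right, left)) {
      idx <- which(lung)
      k <- round(emphysema_fraction * length(idx))
      if (k > 0) data[sample(idx, k)] <- -1000
    }
    NULL
  })
  vol <- image_volume(data, spacing = spec$spacing)
  list(volume = vol,
       right = roi_mask(array(as.integer(right), spec$shape), vol),
       left = roi_mask(array(as.integer(left), spec$shape), vol))
}

#' Specification of a synthetic patient cohort
#'
#' Continuous clinicoradiological features are multivariate Gaussian with the
#' stated means/sds (and optional covariance); pathway alteration labels are
#' Bernoulli with a known logistic model on named features; survival follows
#' a Weibull proportional-hazards model with exponential censoring; somatic
#' mutations are emitted so that \code{\link{map_pathways}} reproduces the
#' generated labels exactly.
#'
#' Default effect directions mirror a lung SQCC cohort: tumors whose
#' histogram is more uniform associate with redox-stress alteration, smaller
#' HU range with apoptosis alteration, smaller right lung volume with
#' proliferation alteration; prevalences default to 36.8/80.7/56.1/24.6/49.1
#' percent at the logistic intercept scale.
#'
#' @param n Number of patients.
#' @param features data.frame feature/mean/sd for the continuous features;
#'   default all 63 imaging features, standard normal.
#' @param feature_cov Optional named covariance matrix overriding the
#'   diagonal sd^2 for a subset of the features; must be symmetric positive
#'   semi-definite.
#' @param pathway_models Named list (one per pathway) of
#'   \code{list(intercept, coef)} with \code{coef} a named numeric vector
#'   over feature columns.
#' @param survival_models List with \code{dfs} and \code{os}, each
#'   \code{list(shape, scale, coef)} of a Weibull PH model (scale in months).
#' @param censor_rate Exponential censoring rate per month.
#' @param pmap A \code{pathway_map} used to emit mutations.
#' @param seed RNG seed.
#' @return A \code{cohort_spec} list.
#' @export
cohort_spec <- function(n = 57,
                        features = NULL,
                        feature_cov = NULL,
                        pathway_models = NULL,
                        survival_models = NULL,
                        censor_rate = 1 / 60,
                        pmap = default_pathway_map(),
                        seed = 1L) {
  if (is.null(features)) {
    imaging <- rbind(tumor_feature_list(), emphysema_feature_list())
    features <- data.frame(feature = imaging$feature, mean = 0, sd = 1,
                           stringsAsFactors = FALSE)
  }
  if (is.null(pathway_models)) {
    pathway_models <- list(
      redox_stress = list(intercept = stats::qlogis(0.368),
                          coef = c(energy = -0.8)),
      apoptosis = list(intercept = stats::qlogis(0.807),
                       coef = c(range = -1.0)),
      proliferation = list(intercept = stats::qlogis(0.561),
                           coef = c(right_lung_volume_ml = -0.8)),
      differentiation = list(intercept = stats::qlogis(0.246),
                             coef = c(spherical_disproportion = -0.5)),
      chromatin_remodelers = list(intercept = stats::qlogis(0.491),
                                  coef = c(maximum_probability = -0.6)))
  }
  if (is.null(survival_models)) {
    survival_models <- list(
      dfs = list(shape = 1.2, scale = 60,
                 coef = c(kurtosis = 0.5, surface_area_mm2 = 0.5)),
      os = list(shape = 1.2, scale = 80,
                coef = c(iqr = -0.5, p97.5 = 0.6)))
  }
  for (pm in pathway_models) {
    bad <- setdiff(names(pm$coef), features$feature)
    if (length(bad)) stop("pathway model coefficient on unknown feature: ",
                          paste(bad, collapse = ", "))
  }
  for (sm in survival_models) {
    bad <- setdiff(names(sm$coef), features$feature)
    if (length(bad)) stop("survival model coefficient on unknown feature: ",
                          paste(bad, collapse = ", "))
  }
  if (!is.null(feature_cov)) {
    stopifnot(is.matrix(feature_cov),
              identical(rownames(feature_cov), colnames(feature_cov)),
              all(rownames(feature_cov) %in% features$feature))
    if (any(abs(feature_cov - t(feature_cov)) > 1e-8))
      stop("invalid covariance: not symmetric")
    ev <- eigen(feature_cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("invalid covariance: not positive semi-definite")
  }
  structure(list(n = as.integer(n), features = features,
                 feature_cov = feature_cov, pathway_models = pathway_models,
                 survival_models = survival_models, censor_rate = censor_rate,
                 pmap = pmap, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort with known ground truth
#'
#' @param spec A \code{cohort_spec}.
#' @return List with \code{cohort} (one row per patient: clinical columns,
#'   feature columns, the five binary pathway columns, and
#'   \code{time_dfs}/\code{event_dfs}/\code{time_os}/\code{event_os} in
#'   months), \code{mutations} (a \code{mutation_table} reproducing the
#'   labels under \code{map_pathways}) and \code{truth} (the generating
#'   models).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    ids <- sprintf("P%03d", seq_len(n))

    # clinical features, frequencies of a surgical lung SQCC cohort
    clin <- data.frame(
      patient_id = ids,
      age = stats::rnorm(n, 65.5, 6.7),
      sex = stats::rbinom(n, 1, 3 / 57),
      smoking_status = sample(0:2, n, replace = TRUE,
                              prob = c(3, 29, 25) / 57),
      t_descriptor = sample(1:4, n, replace = TRUE,
                            prob = c(10, 37, 8, 2) / 57),
      n_descriptor = sample(1:3, n, replace = TRUE, prob = c(41, 9, 7) / 57),
      m_descriptor = stats::rbinom(n, 1, 2 / 57),
      stage = sample(1:4, n, replace = TRUE, prob = c(22, 25, 8, 2) / 57),
      adjuvant_therapy = stats::rbinom(n, 1, 13 / 57),
      palliative_therapy = stats::rbinom(n, 1, 10 / 57),
      stringsAsFactors = FALSE)
    clin$pack_years <- ifelse(clin$smoking_status == 0, 0,
                              stats::rlnorm(n, log(35), 0.5))

    # continuous imaging features
    fts <- spec$features
    X <- matrix(stats::rnorm(n * nrow(fts)), n, nrow(fts))
    X <- sweep(X, 2, fts$sd, `*`)
    X <- sweep(X, 2, fts$mean, `+`)
    colnames(X) <- fts$feature
    if (!is.null(spec$feature_cov)) {
      sub <- rownames(spec$feature_cov)
      L <- chol(spec$feature_cov + diag(1e-10, nrow(spec$feature_cov)))
      Z <- matrix(stats::rnorm(n * length(sub)), n, length(sub)) %*% L
      X[, sub] <- sweep(Z, 2, fts$mean[match(sub, fts$feature)], `+`)
    }
    cohort <- cbind(clin, as.data.frame(X))

    # pathway labels from the logistic models
    lin_pred <- function(coef) {
      lp <- rep(0, n)
      for (f in names(coef)) lp <- lp + coef[[f]] * cohort[[f]]
      lp
    }
    for (p in sqcc_pathways()) {
      pm <- spec$pathway_models[[p]]
      pr <- stats::plogis(pm$intercept + lin_pred(pm$coef))
      cohort[[p]] <- stats::rbinom(n, 1, pr)
    }

    # mutations emitted to reproduce labels exactly: sample genes unique to
    # each pathway so no cross-pathway leakage is possible
    all_genes <- unlist(spec$pmap)
    excl <- lapply(spec$pmap, function(g) g[!g %in% all_genes[duplicated(all_genes)]])
    mut <- list()
    for (p in sqcc_pathways()) {
      genes <- excl[[p]]
      if (!length(genes))
        stop("pathway '", p, "' has no genes unique to it; cannot emit ",
             "label-consistent mutations")
      hit <- which(cohort[[p]] == 1L)
      for (i in hit) {
        k <- if (length(genes) > 1L && stats::runif(1) < 0.2) 2L else 1L
        gs <- sample(genes, k)
        mut[[length(mut) + 1L]] <- data.frame(
          patient_id = ids[i], gene = gs,
          variant_class = "Missense_Mutation", stringsAsFactors = FALSE)
      }
    }
    mutations <- if (length(mut)) do.call(rbind, mut) else
      data.frame(patient_id = character(), gene = character(),
                 variant_class = character(), stringsAsFactors = FALSE)
    class(mutations) <- c("mutation_table", "data.frame")

    # Weibull proportional-hazards survival with exponential censoring
    for (ep in c("dfs", "os")) {
      sm <- spec$survival_models[[ep]]
      lp <- lin_pred(sm$coef)
      u <- stats::runif(n)
      t_event <- sm$scale * (-log(u) / exp(lp))^(1 / sm$shape)
      t_cens <- stats::rexp(n, spec$censor_rate)
      cohort[[paste0("time_", ep)]] <- pmax(pmin(t_event, t_cens), 1e-6)
      cohort[[paste0("event_", ep)]] <- as.integer(t_event <= t_cens)
    }

    list(cohort = cohort, mutations = mutations,
         truth = list(pathway_models = spec$pathway_models,
                      survival_models = spec$survival_models))
  })
}
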