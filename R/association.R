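#' The frozen clinical feature list
#'
#' Ten clinical features: age (years), sex (0 male / 1 female), smoking
#' status (0 never / 1 former / 2 current, ordinal), smoking pack-years,
#' T/N/M descriptors and overall stage as ordinal integers, and the two
#' treatment indicators.
#'
#' @return data.frame with columns \code{feature} and \code{category}
#'   (all \code{"clinical"}).
#' @export
clinical_feature_list <- function() {
  data.frame(feature = c("age", "sex", "smoking_status", "pack_years",
                         "t_descriptor", "n_descriptor", "m_descriptor",
                         "stage", "adjuvant_therapy", "palliative_therapy"),
             category = "clinical", stringsAsFactors = FALSE)
}

#' The 73 clinicoradiological features and their 8 categories
#'
#' Ten clinical features, the 52 tumor features in six imaging categories,
#' and the 11 emphysema features.
#'
#' @return data.frame with columns \code{feature} and \code{category}.
#' @export
clinicoradiological_feature_list <- function() {
  rbind(clinical_feature_list(), tumor_feature_list(), emphysema_feature_list())
}

# z-standardize a predictor unless it is binary (<= 2 distinct non-NA values);
# returns NULL for a constant (zero-variance) predictor.
standardize_predictor <- function(x) {
  ux <- unique(x[!is.na(x)])
  if (length(ux) <= 1L) return(NULL)
  if (length(ux) == 2L) return(x)
  s <- stats::sd(x, na.rm = TRUE)
  if (s == 0) return(NULL)
  (x - mean(x, na.rm = TRUE)) / s
}

# Fit y ~ x with binomial glm and classify pathologies (separation,
# non-convergence). Returns coef/se for the slope plus a flag.
fit_logistic_1 <- function(x, y) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  if (nrow(co) < 2L) return(list(flag = "constant"))
  b <- co[2, 1]; se <- co[2, 2]
  if (sep || !fit$converged || se > 50)
    return(list(flag = "separation", sign = sign(b)))
  list(flag = NULL, b = b, se = se, p = co[2, 4], fit = fit)
}

#' Univariate logistic association of one feature with a binary label
#'
#' Continuous features are z-standardized first, so the odds ratio is per one
#' standard deviation. Missing values are removed pairwise. Complete
#' separation and constant features yield a flagged result (p missing, odds
#' ratio marked infinite) rather than an error.
#'
#' @param feature Numeric vector.
#' @param label Binary 0/1 vector of the same length.
#' @return List with \code{p}, \code{or}, \code{ci} (length-2 95\% Wald
#'   interval), \code{n} and \code{flag} (NULL, \code{"separation"},
#'   \code{"constant"} or \code{"insufficient"}).
#' @export
univariate_logistic <- function(feature, label) {
  stopifnot(length(feature) == length(label))
  ok <- !is.na(feature) & !is.na(label)
  x <- feature[ok]; y <- label[ok]
  out <- list(p = NA_real_, or = NA_real_, ci = c(NA_real_, NA_real_),
              n = length(y), flag = NULL)
  if (length(y) < 4L || min(table(factor(y, levels = 0:1))) < 2L) {
    out$flag <- "insufficient"
    return(out)
  }
  z <- standardize_predictor(x)
  if (is.null(z)) {
    out$flag <- "constant"
    return(out)
  }
  f <- fit_logistic_1(z, y)
  if (!is.null(f$flag)) {
    out$flag <- f$flag
    if (identical(f$flag, "separation"))
      out$or <- if (isTRUE(f$sign < 0)) 0 else Inf
    return(out)
  }
  out$p <- f$p
  out$or <- exp(f$b)
  out$ci <- exp(f$b + c(-1, 1) * stats::qnorm(0.975) * f$se)
  out
}

#' Per-category feature selection by minimum p-value
#'
#' Within each category the feature with the smallest univariate p-value is
#' selected, provided that p-value is below \code{threshold} (default 0.2);
#' otherwise the category contributes no feature. Ties are broken by
#' lexicographic feature name; flagged/missing p-values never win.
#'
#' @param pvals data.frame with columns \code{feature}, \code{category},
#'   \code{p}.
#' @param threshold Selection gate on the univariate p-value (default 0.2).
#' @return data.frame with one row per category present in \code{pvals}:
#'   \code{category}, \code{feature} (NA when none selected), \code{p}.
#' @export
select_per_category <- function(pvals, threshold = 0.2) {
  stopifnot(all(c("feature", "category", "p") %in% names(pvals)))
  cats <- unique(pvals$category)
  rows <- lapply(cats, function(cc) {
    d <- pvals[pvals$category == cc & !is.na(pvals$p), , drop = FALSE]
    d <- d[d$p < threshold, , drop = FALSE]
    if (nrow(d) == 0L)
      return(data.frame(category = cc, feature = NA_character_, p = NA_real_,
                        stringsAsFactors = FALSE))
    d <- d[order(d$p, d$feature), , drop = FALSE]
    data.frame(category = cc, feature = d$feature[1], p = d$p[1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Multivariate logistic model on the selected features
#'
#' Jointly fits the label on all selected features (z-standardized), giving
#' per-feature odds ratios, Wald 95\% CIs and p-values, plus the in-sample
#' linear predictor and its AUC. With a single selected feature this reduces
#' to the univariate fit.
#'
#' @param data data.frame containing the feature columns and the label.
#' @param features Character vector of selected feature names.
#' @param label_col Name of the binary label column.
#' @return List with \code{terms} (data.frame feature/or/ci_low/ci_high/p/flag),
#'   \code{auc}, \code{n}, \code{linear_predictor} and \code{flag}. When
#'   \code{features} is empty, a \code{"no model"} entry.
#' @export
multivariate_logistic <- function(data, features, label_col) {
  if (length(features) == 0L)
    return(list(terms = NULL, auc = NA_real_, n = 0L,
                linear_predictor = NULL, flag = "no model"))
  stopifnot(all(features %in% names(data)), label_col %in% names(data))
  d <- data[, c(features, label_col)]
  ok <- stats::complete.cases(d)
  d <- d[ok, , drop = FALSE]
  y <- d[[label_col]]
  if (length(y) < 4L || min(table(factor(y, levels = 0:1))) < 2L)
    return(list(terms = NULL, auc = NA_real_, n = length(y),
                linear_predictor = NULL, flag = "insufficient"))
  if (length(y) <= 5L * length(features))
    warning("fewer than 5 observations per selected feature (n = ",
            length(y), ", k = ", length(features), ")")
  X <- as.data.frame(lapply(d[features], function(x) {
    z <- standardize_predictor(x)
    if (is.null(z)) x else z
  }))
  names(X) <- features
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = cbind(y = y, X), family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  terms <- lapply(features, function(f) {
    row <- paste0("`", f, "`")
    i <- match(f, rownames(co))
    if (is.na(i)) i <- match(row, rownames(co))
    if (is.na(i))
      return(data.frame(feature = f, or = NA, ci_low = NA, ci_high = NA,
                        p = NA, flag = "dropped", stringsAsFactors = FALSE))
    b <- co[i, 1]; se <- co[i, 2]
    flagged <- sep || !fit$converged || se > 50
    data.frame(feature = f,
               or = if (flagged) ifelse(b < 0, 0, Inf) else exp(b),
               ci_low = if (flagged) NA_real_ else exp(b - stats::qnorm(0.975) * se),
               ci_high = if (flagged) NA_real_ else exp(b + stats::qnorm(0.975) * se),
               p = if (flagged) NA_real_ else co[i, 4],
               flag = if (flagged) "separation" else NA_character_,
               stringsAsFactors = FALSE)
  })
  lp <- stats::predict(fit, type = "link")
  list(terms = do.call(rbind, terms),
       auc = roc_auc(lp, y),
       n = length(y),
       linear_predictor = lp,
       flag = NULL)
}

#' Area under the ROC curve
#'
#' AUC = P(score of a case exceeds the score of a control) + half the tie
#' probability, computed as the normalized Mann-Whitney statistic via
#' midranks.
#'
#' @param score Numeric vector.
#' @param label Binary 0/1 vector.
#' @return Scalar AUC in [0, 1].
#' @export
roc_auc <- function(score, label) {
  ok <- !is.na(score) & !is.na(label)
  score <- score[ok]; label <- label[ok]
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(score)
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Smoking vs pathway alteration
#'
#' Fisher's exact test on the smoking status x alteration contingency table
#' and a two-sided Wilcoxon rank-sum test on pack-years by alteration status.
#'
#' @param smoking_status Categorical vector (e.g. 0/1/2 or labels).
#' @param pack_years Numeric vector.
#' @param altered Binary 0/1 alteration labels.
#' @return List with \code{fisher_p}, \code{wilcoxon_p} and \code{flag}
#'   (non-NULL for a degenerate table).
#' @export
smoking_association <- function(smoking_status, pack_years, altered) {
  out <- list(fisher_p = NA_real_, wilcoxon_p = NA_real_, flag = NULL)
  tab <- table(smoking_status, altered)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    out$flag <- "degenerate table"
    return(out)
  }
  out$fisher_p <- stats::fisher.test(tab)$p.value
  g1 <- pack_years[altered == 1]
  g0 <- pack_years[altered == 0]
  out$wilcoxon_p <- suppressWarnings(
    stats::wilcox.test(g1, g0, alternative = "two.sided")$p.value)
  out
}

#' Full per-pathway association analysis
#'
#' Runs the category-wise pipeline for one pathway: univariate logistic
#' screening of every clinicoradiological feature, minimum-p selection per
#' category with the p < 0.2 gate, a joint multivariate logistic model on the
#' selected features, in-sample AUC of its linear predictor, and the smoking
#' analysis.
#'
#' @param cohort data.frame with one row per patient: the feature columns of
#'   \code{categories$feature} and a binary column named after the pathway.
#' @param pathway Pathway column name.
#' @param categories data.frame feature/category (default the full
#'   73-feature list).
#' @param threshold Selection gate (default 0.2).
#' @return List with \code{pathway}, \code{univariate} (data.frame),
#'   \code{selection}, \code{model} (see \code{\link{multivariate_logistic}}),
#'   \code{smoking} and \code{n_tests}.
#' @export
associate_pathway <- function(cohort, pathway,
                              categories = clinicoradiological_feature_list(),
                              threshold = 0.2) {
  stopifnot(pathway %in% names(cohort))
  feats <- intersect(categories$feature, names(cohort))
  y <- cohort[[pathway]]
  uni <- lapply(feats, function(f) {
    r <- univariate_logistic(cohort[[f]], y)
    data.frame(feature = f,
               category = categories$category[match(f, categories$feature)],
               p = r$p, or = r$or, ci_low = r$ci[1], ci_high = r$ci[2],
               n = r$n, flag = if (is.null(r$flag)) NA_character_ else r$flag,
               stringsAsFactors = FALSE)
  })
  uni <- do.call(rbind, uni)
  sel <- select_per_category(uni, threshold = threshold)
  chosen <- sel$feature[!is.na(sel$feature)]
  model <- multivariate_logistic(cohort, chosen, pathway)
  smoking <- if (all(c("smoking_status", "pack_years") %in% names(cohort)))
    smoking_association(cohort$smoking_status, cohort$pack_years, y)
  else NULL
  list(pathway = pathway, univariate = uni, selection = sel, model = model,
       smoking = smoking, n_tests = sum(!is.na(uni$p)))
}
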