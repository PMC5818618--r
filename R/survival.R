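#' Univariate Cox proportional-hazards association
#'
#' Partial-likelihood fit of the hazard on a single z-standardized feature
#' with Efron tie handling; hazard ratio per one standard deviation with Wald
#' 95\% CI and p-value. Monotone likelihood (the Cox analogue of separation)
#' is returned as a flagged result.
#'
#' @param feature Numeric vector.
#' @param time Follow-up times in months (> 0).
#' @param event Binary event indicator (1 = recurrence/death, 0 = censored).
#' @return List with \code{p}, \code{hr}, \code{ci}, \code{n_events},
#'   \code{n} and \code{flag}.
#' @export
univariate_cox <- function(feature, time, event) {
  stopifnot(length(feature) == length(time), length(time) == length(event))
  ok <- !is.na(feature) & !is.na(time) & !is.na(event)
  x <- feature[ok]; tt <- time[ok]; ev <- event[ok]
  out <- list(p = NA_real_, hr = NA_real_, ci = c(NA_real_, NA_real_),
              n_events = sum(ev), n = length(ev), flag = NULL)
  if (any(tt <= 0)) stop("survival times must be positive")
  if (sum(ev) < 2L) {
    out$flag <- "insufficient events"
    return(out)
  }
  z <- standardize_predictor(x)
  if (is.null(z)) {
    out$flag <- "constant"
    return(out)
  }
  mono <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(tt, ev) ~ z, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w), ignore.case = TRUE))
        mono <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  b <- co[1, "coef"]; se <- co[1, "se(coef)"]
  if (mono || se > 50) {
    out$flag <- "monotone likelihood"
    out$hr <- if (b < 0) 0 else Inf
    return(out)
  }
  out$p <- co[1, "Pr(>|z|)"]
  out$hr <- exp(b)
  out$ci <- exp(b + c(-1, 1) * stats::qnorm(0.975) * se)
  out
}

#' Multivariate Cox model on selected features
#'
#' Joint Efron-tie Cox fit of the selected (z-standardized) features; per
#' feature hazard ratio, Wald CI and p-value, with the linear predictor
#' retained for AUC.
#'
#' @param data data.frame containing the feature and survival columns.
#' @param features Character vector of selected features (possibly empty).
#' @param time_col,event_col Names of the survival columns.
#' @return List with \code{terms}, \code{auc} (of the linear predictor
#'   against the event indicator), \code{n}, \code{n_events},
#'   \code{linear_predictor} and \code{flag}.
#' @export
multivariate_cox <- function(data, features, time_col, event_col) {
  if (length(features) == 0L)
    return(list(terms = NULL, auc = NA_real_, n = 0L, n_events = 0L,
                linear_predictor = NULL, flag = "no model"))
  stopifnot(all(c(features, time_col, event_col) %in% names(data)))
  d <- data[, c(features, time_col, event_col)]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  tt <- d[[time_col]]; ev <- d[[event_col]]
  if (sum(ev) < 2L)
    return(list(terms = NULL, auc = NA_real_, n = nrow(d),
                n_events = sum(ev), linear_predictor = NULL,
                flag = "insufficient events"))
  X <- as.data.frame(lapply(d[features], function(x) {
    z <- standardize_predictor(x)
    if (is.null(z)) x else z
  }))
  names(X) <- features
  mono <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(tt, ev) ~ ., data = X, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w), ignore.case = TRUE))
        mono <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  terms <- lapply(features, function(f) {
    i <- match(f, rownames(co))
    if (is.na(i)) i <- match(paste0("`", f, "`"), rownames(co))
    if (is.na(i))
      return(data.frame(feature = f, hr = NA, ci_low = NA, ci_high = NA,
                        p = NA, flag = "dropped", stringsAsFactors = FALSE))
    b <- co[i, "coef"]; se <- co[i, "se(coef)"]
    flagged <- mono || se > 50
    data.frame(feature = f,
               hr = if (flagged) ifelse(b < 0, 0, Inf) else exp(b),
               ci_low = if (flagged) NA_real_ else exp(b - stats::qnorm(0.975) * se),
               ci_high = if (flagged) NA_real_ else exp(b + stats::qnorm(0.975) * se),
               p = if (flagged) NA_real_ else co[i, "Pr(>|z|)"],
               flag = if (flagged) "monotone likelihood" else NA_character_,
               stringsAsFactors = FALSE)
  })
  lp <- as.numeric(stats::predict(fit, type = "lp"))
  list(terms = do.call(rbind, terms),
       auc = survival_auc(lp, ev),
       n = nrow(d), n_events = sum(ev),
       linear_predictor = lp, flag = NULL)
}

#' AUC of a survival linear predictor
#'
#' Discriminates patients who ever experienced the event from censored
#' patients using the ordinary ROC AUC of the linear predictor. (A
#' time-dependent AUC would be the censoring-aware alternative; this simple
#' event-indicator form is what is reported here and it is labelled as such.)
#'
#' @param linear_predictor Numeric risk scores.
#' @param event Binary event indicator.
#' @return Scalar AUC.
#' @export
survival_auc <- function(linear_predictor, event) {
  roc_auc(linear_predictor, event)
}

#' Full survival analysis for one endpoint
#'
#' Same category-wise machinery as the pathway association: univariate Cox
#' p-values for every feature, minimum-p selection per category gated at
#' p < 0.2, joint multivariate Cox model, and AUC of the resulting predictor.
#'
#' @param cohort data.frame with feature columns plus \code{time_col} and
#'   \code{event_col}.
#' @param time_col,event_col Survival column names (e.g. \code{time_dfs},
#'   \code{event_dfs}).
#' @param categories Feature/category map (default the 73-feature list).
#' @param threshold Selection gate (default 0.2).
#' @return List with \code{endpoint}, \code{univariate}, \code{selection},
#'   \code{model} and \code{n_tests}.
#' @export
analyze_survival <- function(cohort, time_col, event_col,
                             categories = clinicoradiological_feature_list(),
                             threshold = 0.2) {
  stopifnot(all(c(time_col, event_col) %in% names(cohort)))
  feats <- intersect(categories$feature, names(cohort))
  uni <- lapply(feats, function(f) {
    r <- univariate_cox(cohort[[f]], cohort[[time_col]], cohort[[event_col]])
    data.frame(feature = f,
               category = categories$category[match(f, categories$feature)],
               p = r$p, hr = r$hr, ci_low = r$ci[1], ci_high = r$ci[2],
               n_events = r$n_events,
               flag = if (is.null(r$flag)) NA_character_ else r$flag,
               stringsAsFactors = FALSE)
  })
  uni <- do.call(rbind, uni)
  sel <- select_per_category(uni, threshold = threshold)
  chosen <- sel$feature[!is.na(sel$feature)]
  model <- multivariate_cox(cohort, chosen, time_col, event_col)
  list(endpoint = event_col, univariate = uni, selection = sel,
       model = model, n_tests = sum(!is.na(uni$p)))
}
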