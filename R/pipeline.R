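#' Read a pipeline run configuration from YAML
#'
#' Expected fields: \code{patients} (list/table with patient_id, volume, mask
#' and optional lung_volume paths), \code{clinical_csv}, \code{features_csv},
#' \code{mutations_tsv}, \code{pathway_map} (YAML/JSON path, optional),
#' \code{out_dir}, and the options \code{n_bins}, \code{energy_variant},
#' \code{selection_threshold}, \code{alpha}, \code{min_genes}, \code{seed}.
#'
#' @param path YAML file.
#' @return A validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' Validate / default a run configuration
#' @param cfg A config list.
#' @return The completed config list.
#' @export
validate_run_config <- function(cfg) {
  defaults <- list(n_bins = 32L, energy_variant = "uniformity",
                   selection_threshold = 0.2, alpha = 0.05, min_genes = 1L,
                   seed = 1L, out_dir = ".")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (cfg$selection_threshold <= 0 || cfg$selection_threshold >= 1)
    stop("selection_threshold must be in (0, 1)")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  cfg
}

#' Extract tumor (and optional emphysema) features for a batch of patients
#'
#' Per-patient failures are logged to stderr and skipped; the run aborts only
#' if no patient could be processed. Output is the tidy feature table
#' (patient_id, feature, category, value), also written to
#' \code{<out_dir>/features.csv} when \code{out_dir} is set.
#'
#' @param config Run config with a \code{patients} entry: data.frame or list
#'   of lists with \code{patient_id}, \code{volume}, \code{mask} and optional
#'   \code{lung_volume} file paths.
#' @param write Write the CSV to \code{config$out_dir} (default TRUE if
#'   out_dir given).
#' @return Tidy feature data.frame, invisibly also written to disk.
#' @export
run_extract <- function(config, write = !is.null(config$out_dir)) {
  config <- validate_run_config(config)
  pts <- config$patients
  if (is.null(pts)) stop("config has no patients")
  if (!is.data.frame(pts))
    pts <- do.call(rbind, lapply(pts, function(p)
      as.data.frame(p, stringsAsFactors = FALSE)))
  ec <- extraction_config(n_bins = config$n_bins,
                          energy_variant = config$energy_variant)
  rows <- list()
  for (i in seq_len(nrow(pts))) {
    pid <- pts$patient_id[i]
    res <- tryCatch({
      vol <- read_volume(pts$volume[i])
      msk <- read_mask(pts$mask[i], vol)
      fv <- extract_all(vol, msk, ec)
      df <- feature_vector_to_df(fv, patient_id = pid)
      if ("lung_volume" %in% names(pts) && !is.na(pts$lung_volume[i]) &&
          nzchar(pts$lung_volume[i])) {
        lv <- read_volume(pts$lung_volume[i])
        ef <- emphysema_features(lv, segment_lungs(lv))
        df <- rbind(df, data.frame(patient_id = pid, feature = names(ef),
                                   category = "emphysema",
                                   value = as.numeric(unlist(ef)),
                                   stringsAsFactors = FALSE))
      }
      df
    }, error = function(e) {
      message("extraction failed for patient ", pid, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("no patients could be processed")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (write) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(config$out_dir, "features.csv"),
                     row.names = FALSE)
  }
  out
}

#' Assemble the cohort table from its parts
#'
#' Joins the clinical table, the wide feature table and the pathway
#' alteration matrix by exact patient ID. The clinical table defines the
#' patient universe; patients missing from the feature table are reported and
#' kept with NA features (models drop them pairwise).
#'
#' @param clinical data.frame with a \code{patient_id} column.
#' @param features Tidy feature data.frame (patient_id, feature, category,
#'   value) or NULL.
#' @param alterations A \code{pathway_alteration_matrix} or NULL.
#' @return Cohort data.frame, one row per clinical patient.
#' @export
assemble_cohort <- function(clinical, features = NULL, alterations = NULL) {
  stopifnot("patient_id" %in% names(clinical))
  cohort <- clinical
  cohort$patient_id <- as.character(cohort$patient_id)
  if (!is.null(features)) {
    wide <- stats::reshape(features[, c("patient_id", "feature", "value")],
                           idvar = "patient_id", timevar = "feature",
                           direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    wide$patient_id <- as.character(wide$patient_id)
    missing_feat <- setdiff(cohort$patient_id, wide$patient_id)
    if (length(missing_feat))
      warning("no imaging features for patients: ",
              paste(missing_feat, collapse = ", "))
    extra <- setdiff(wide$patient_id, cohort$patient_id)
    if (length(extra))
      warning("imaging features for patients absent from the clinical table ",
              "(ignored): ", paste(extra, collapse = ", "))
    cohort <- merge(cohort, wide, by = "patient_id", all.x = TRUE, sort = TRUE)
  }
  if (!is.null(alterations)) {
    alt <- as.data.frame(alterations$altered)
    alt$patient_id <- rownames(alterations$altered)
    cohort <- merge(cohort, alt, by = "patient_id", all.x = TRUE, sort = TRUE)
  }
  cohort[order(cohort$patient_id), , drop = FALSE]
}

#' Run the pathway association stage
#'
#' Builds the cohort from the configured feature CSV, clinical CSV, mutation
#' TSV and pathway map, then runs the per-pathway association pipeline and
#' the alteration summary. Writes \code{association_report.json} and the
#' human-readable \code{association_table.csv} when \code{out_dir} is set.
#'
#' @param config Run config with \code{features_csv}, \code{clinical_csv},
#'   \code{mutations_tsv} and optional \code{pathway_map} paths.
#' @param write Write outputs to \code{config$out_dir}.
#' @return List: \code{alteration_summary}, \code{pathways} (one entry per
#'   pathway; single-class pathways carry an error message instead of a
#'   model), \code{table} (flat data.frame).
#' @export
run_associate <- function(config, write = !is.null(config$out_dir)) {
  config <- validate_run_config(config)
  clinical <- utils::read.csv(config$clinical_csv, stringsAsFactors = FALSE)
  features <- utils::read.csv(config$features_csv, stringsAsFactors = FALSE)
  muts <- read_mutations(config$mutations_tsv)
  pmap <- if (!is.null(config$pathway_map)) read_pathway_map(config$pathway_map)
          else default_pathway_map()
  alt <- map_pathways(muts, pmap, patients = clinical$patient_id,
                      min_genes = config$min_genes)
  cohort <- assemble_cohort(clinical, features, alt)
  summ <- alteration_summary(alt)
  res <- lapply(sqcc_pathways(), function(p) {
    y <- cohort[[p]]
    if (length(unique(y[!is.na(y)])) < 2L)
      return(list(pathway = p,
                  error = "single-class pathway: all patients identical"))
    associate_pathway(cohort, p,
                      threshold = config$selection_threshold)
  })
  names(res) <- sqcc_pathways()
  tab <- association_table(res)
  out <- list(alteration_summary = summ, pathways = res, table = tab)
  if (write) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    report_json <- serializable_association(out)
    jsonlite::write_json(report_json,
                         file.path(config$out_dir, "association_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
    utils::write.csv(tab, file.path(config$out_dir, "association_table.csv"),
                     row.names = FALSE)
    write_manifest(config)
  }
  out
}

# Flat table mirroring the pathway x category report layout: one row per
# pathway/category with the selected feature, univariate p, multivariate OR,
# CI and p, and the model AUC.
association_table <- function(res) {
  rows <- list()
  for (p in names(res)) {
    r <- res[[p]]
    if (!is.null(r$error)) {
      rows[[length(rows) + 1L]] <- data.frame(
        pathway = p, category = NA, feature = NA, univariate_p = NA,
        or = NA, ci_low = NA, ci_high = NA, multivariate_p = NA, auc = NA,
        note = r$error, stringsAsFactors = FALSE)
      next
    }
    for (i in seq_len(nrow(r$selection))) {
      f <- r$selection$feature[i]
      mt <- if (!is.null(r$model$terms) && !is.na(f))
        r$model$terms[r$model$terms$feature == f, , drop = FALSE]
      else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        pathway = p, category = r$selection$category[i], feature = f,
        univariate_p = r$selection$p[i],
        or = if (!is.null(mt) && nrow(mt)) mt$or else NA,
        ci_low = if (!is.null(mt) && nrow(mt)) mt$ci_low else NA,
        ci_high = if (!is.null(mt) && nrow(mt)) mt$ci_high else NA,
        multivariate_p = if (!is.null(mt) && nrow(mt)) mt$p else NA,
        auc = r$model$auc, note = NA_character_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# strip unserializable members (glm objects, linear predictors) for JSON
serializable_association <- function(out) {
  out$pathways <- lapply(out$pathways, function(r) {
    if (!is.null(r$model)) r$model$linear_predictor <- NULL
    r
  })
  out
}

#' Run the survival stage
#'
#' DFS and OS analyses with the same category-wise selection; an endpoint
#' with no events is skipped with a warning. Writes
#' \code{survival_report.json} when \code{out_dir} is set.
#'
#' @param config Run config with \code{features_csv} and \code{clinical_csv}
#'   paths (clinical must carry time_dfs/event_dfs/time_os/event_os).
#' @param write Write outputs to \code{config$out_dir}.
#' @return List with \code{dfs} and \code{os} entries (NULL when skipped).
#' @export
run_survival <- function(config, write = !is.null(config$out_dir)) {
  config <- validate_run_config(config)
  clinical <- utils::read.csv(config$clinical_csv, stringsAsFactors = FALSE)
  features <- utils::read.csv(config$features_csv, stringsAsFactors = FALSE)
  cohort <- assemble_cohort(clinical, features)
  out <- list()
  for (ep in c("dfs", "os")) {
    tc <- paste0("time_", ep); evc <- paste0("event_", ep)
    if (!all(c(tc, evc) %in% names(cohort))) {
      warning("no survival columns for endpoint ", ep, "; skipped")
      out[[ep]] <- NULL
      next
    }
    if (sum(cohort[[evc]], na.rm = TRUE) < 2L) {
      warning("fewer than two events for endpoint ", ep, "; skipped")
      out[[ep]] <- NULL
      next
    }
    out[[ep]] <- analyze_survival(cohort, tc, evc,
                                  threshold = config$selection_threshold)
  }
  if (write) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    sr <- lapply(out, function(r) {
      if (!is.null(r$model)) r$model$linear_predictor <- NULL
      r
    })
    jsonlite::write_json(sr, file.path(config$out_dir, "survival_report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
    write_manifest(config)
  }
  out
}

# Reproducibility manifest: config hash, seed and versions.
write_manifest <- function(config) {
  manifest <- list(config_hash = rlang::hash(config),
                   seed = config$seed,
                   r_version = as.character(getRversion()),
                   package_version = as.character(
                     utils::packageVersion("sqccradiomics")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}
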