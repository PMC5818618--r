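#' The five SQCC signaling pathway names
#' @return Character vector of the five pathway identifiers.
#' @export
sqcc_pathways <- function() {
  c("redox_stress", "apoptosis", "proliferation", "differentiation",
    "chromatin_remodelers")
}

#' Default pathway-to-gene map
#'
#' A deliberately minimal placeholder covering the seven genes recurrently
#' mutated in East Asian lung SQCC (TP53, RB1, PTEN, NFE2L2, KEAP1, MLL2,
#' PIK3CA) assigned to their standard pathways, completed with the canonical
#' squamous-differentiation genes (SOX2, TP63, NOTCH1) so every pathway has a
#' non-empty gene set. For a faithful analysis supply the full study map via
#' \code{\link{read_pathway_map}}.
#'
#' @return A \code{pathway_map}: named list of gene symbol vectors.
#' @export
default_pathway_map <- function() {
  pathway_map(list(
    redox_stress = c("NFE2L2", "KEAP1"),
    apoptosis = c("TP53"),
    proliferation = c("PIK3CA", "PTEN", "RB1"),
    differentiation = c("SOX2", "TP63", "NOTCH1"),
    chromatin_remodelers = c("MLL2")))
}

#' Validate and construct a pathway map
#'
#' @param x Named list mapping each of the five pathway names to a non-empty
#'   character vector of gene symbols. A gene may belong to more than one
#'   pathway.
#' @return A \code{pathway_map}.
#' @export
pathway_map <- function(x) {
  need <- sqcc_pathways()
  if (!all(need %in% names(x)))
    stop("pathway map must define all of: ", paste(need, collapse = ", "))
  x <- x[need]
  if (any(lengths(x) == 0L)) stop("pathway gene sets must be non-empty")
  x <- lapply(x, function(g) unique(as.character(g)))
  structure(x, class = "pathway_map")
}

#' Read a pathway map from YAML or JSON
#'
#' @param path File with a top-level mapping pathway name -> gene list.
#' @return A \code{pathway_map}.
#' @export
read_pathway_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  pathway_map(x)
}

#' Read a somatic mutation table
#'
#' Tab-separated with header; required columns \code{patient_id}, \code{gene},
#' \code{variant_class} or their MAF aliases \code{Tumor_Sample_Barcode},
#' \code{Hugo_Symbol}, \code{Variant_Classification}. Rows whose variant class
#' is \code{Silent} are dropped: silent variants are not counted as pathway
#' aberrations.
#'
#' @param path Path to the TSV/MAF-like file.
#' @return A \code{mutation_table}: data.frame with columns patient_id, gene,
#'   variant_class.
#' @export
read_mutations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  alias <- c(patient_id = "Tumor_Sample_Barcode", gene = "Hugo_Symbol",
             variant_class = "Variant_Classification")
  for (col in names(alias)) {
    if (!col %in% names(df) && alias[[col]] %in% names(df))
      names(df)[names(df) == alias[[col]]] <- col
  }
  missing_cols <- setdiff(names(alias), names(df))
  if (length(missing_cols))
    stop("mutation table is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  df <- df[, c("patient_id", "gene", "variant_class")]
  if (any(!nzchar(df$gene))) stop("empty gene symbol in mutation table")
  df <- df[df$variant_class != "Silent", , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("mutation_table", "data.frame")
  df
}

#' Map mutations to the pathway alteration matrix
#'
#' A pathway is called altered for a patient when at least one of its genes
#' carries a non-silent mutation in that patient (set
#' \code{min_genes = 2} for the stricter two-gene rule). Duplicate
#' (patient, gene) records collapse to one aberrant gene.
#'
#' @param muts A \code{mutation_table} (non-silent records).
#' @param pmap A \code{pathway_map}.
#' @param patients Character vector of all patients to report, including
#'   mutation-free ones. Mutations for patients outside this list are an
#'   error.
#' @param min_genes Minimum number of aberrant genes required to call a
#'   pathway altered (default 1).
#' @return A \code{pathway_alteration_matrix}: list with \code{altered}
#'   (patients x 5 binary matrix) and \code{gene_counts} (patients x 5 counts
#'   of distinct aberrant genes).
#' @export
map_pathways <- function(muts, pmap, patients, min_genes = 1L) {
  stopifnot(inherits(pmap, "pathway_map"))
  patients <- as.character(patients)
  if (anyDuplicated(patients)) stop("duplicate patient IDs")
  unknown <- setdiff(unique(muts$patient_id), patients)
  if (length(unknown))
    stop("mutations for patients absent from the patient list: ",
         paste(unknown, collapse = ", "))
  pg <- unique(muts[, c("patient_id", "gene")])
  pw <- sqcc_pathways()
  counts <- matrix(0L, length(patients), length(pw),
                   dimnames = list(patients, pw))
  for (p in pw) {
    hit <- pg[pg$gene %in% pmap[[p]], ]
    if (nrow(hit)) {
      tb <- table(hit$patient_id)
      counts[names(tb), p] <- as.integer(tb)
    }
  }
  altered <- (counts >= min_genes) * 1L
  structure(list(altered = altered, gene_counts = counts,
                 min_genes = as.integer(min_genes)),
            class = "pathway_alteration_matrix")
}

#' Summarize pathway alterations across the cohort
#'
#' @param mat A \code{pathway_alteration_matrix}.
#' @return List with \code{per_pathway} (data.frame: pathway, n_altered,
#'   percentage to one decimal) and \code{per_patient_histogram} (named counts
#'   of patients by number of altered pathways, 0..5).
#' @export
alteration_summary <- function(mat) {
  stopifnot(inherits(mat, "pathway_alteration_matrix"))
  n <- nrow(mat$altered)
  if (n < 1L) stop("no patients")
  n_alt <- colSums(mat$altered)
  per_pathway <- data.frame(pathway = colnames(mat$altered),
                            n_altered = as.integer(n_alt),
                            n_patients = n,
                            percentage = round(100 * n_alt / n, 1),
                            row.names = NULL, stringsAsFactors = FALSE)
  k <- rowSums(mat$altered)
  hist <- table(factor(k, levels = 0:ncol(mat$altered)))
  list(per_pathway = per_pathway,
       per_patient_histogram = stats::setNames(as.integer(hist), names(hist)))
}
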