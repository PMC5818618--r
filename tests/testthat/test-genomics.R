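write_mut_tsv <- function(df) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  f
}

test_that("mutation tables parse, accept MAF aliases and drop silent variants", {
  plain <- data.frame(patient_id = c("A", "A", "B"),
                      gene = c("TP53", "KEAP1", "TP53"),
                      variant_class = c("Missense_Mutation", "Silent",
                                        "Nonsense_Mutation"))
  m <- read_mutations(write_mut_tsv(plain))
  expect_equal(nrow(m), 2)
  expect_false(any(m$variant_class == "Silent"))

  maf <- plain
  names(maf) <- c("Tumor_Sample_Barcode", "Hugo_Symbol",
                  "Variant_Classification")
  m2 <- read_mutations(write_mut_tsv(maf))
  expect_equal(m2, m)

  bad <- data.frame(patient = "A", g = "TP53")
  expect_error(read_mutations(write_mut_tsv(bad)), "missing required columns")
})

test_that("pathway mapping follows the at-least-one-gene rule with counts", {
  pmap <- default_pathway_map()
  muts <- data.frame(patient_id = c("A", "B", "B", "C"),
                     gene = c("KEAP1", "PIK3CA", "PTEN", "TP53"),
                     variant_class = "Missense_Mutation")
  class(muts) <- c("mutation_table", "data.frame")
  mat <- map_pathways(muts, pmap, patients = c("A", "B", "C", "D"))
  expect_equal(mat$altered["A", "redox_stress"], 1L)
  expect_equal(sum(mat$altered["A", ]), 1)
  expect_equal(mat$altered["B", "proliferation"], 1L)
  expect_equal(mat$gene_counts["B", "proliferation"], 2L)
  expect_equal(unname(mat$altered["D", ]), rep(0L, 5))    # mutation-free patient
  expect_equal(mat$altered["C", "apoptosis"], 1L)

  # stricter two-gene rule as a switch
  mat2 <- map_pathways(muts, pmap, patients = c("A", "B", "C", "D"),
                       min_genes = 2)
  expect_equal(sum(mat2$altered), 1)
  expect_equal(mat2$altered["B", "proliferation"], 1L)

  expect_error(map_pathways(muts, pmap, patients = c("A", "B")),
               "absent from the patient list")
})

test_that("the matrix is invariant to record order and duplicates", {
  pmap <- default_pathway_map()
  muts <- data.frame(patient_id = c("A", "B", "A"),
                     gene = c("TP53", "MLL2", "NFE2L2"),
                     variant_class = "Missense_Mutation")
  class(muts) <- c("mutation_table", "data.frame")
  base <- map_pathways(muts, pmap, patients = c("A", "B"))
  shuffled <- muts[c(3, 1, 2), ]
  dup <- rbind(muts, muts[1, ])
  class(shuffled) <- class(dup) <- c("mutation_table", "data.frame")
  expect_equal(map_pathways(shuffled, pmap, c("A", "B")), base)
  expect_equal(map_pathways(dup, pmap, c("A", "B")), base)
})

test_that("alteration summary percentages and histogram are consistent", {
  set.seed(15)
  n <- 40
  alt <- matrix(rbinom(n * 5, 1, 0.4), n, 5,
                dimnames = list(sprintf("P%02d", 1:n), sqcc_pathways()))
  mat <- structure(list(altered = alt, gene_counts = alt, min_genes = 1L),
                   class = "pathway_alteration_matrix")
  s <- alteration_summary(mat)
  expect_equal(s$per_pathway$percentage,
               round(100 * colSums(alt) / n, 1), ignore_attr = TRUE)
  expect_equal(sum(s$per_patient_histogram), n)
  # direct set-membership count oracle against a single-pathway map
  expect_equal(s$per_pathway$n_altered[1], sum(alt[, 1] == 1))
})

test_that("pathway maps validate their structure", {
  expect_error(pathway_map(list(redox_stress = "KEAP1")), "must define")
  ok <- list(redox_stress = "KEAP1", apoptosis = "TP53",
             proliferation = "PTEN", differentiation = "SOX2",
             chromatin_remodelers = "MLL2")
  expect_s3_class(pathway_map(ok), "pathway_map")
  bad <- ok; bad$apoptosis <- character(0)
  expect_error(pathway_map(bad), "non-empty")

  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(ok, f)
  expect_s3_class(read_pathway_map(f), "pathway_map")
})
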