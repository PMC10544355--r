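# Shared helpers: independent oracles and hand-built records.

# Exhaustive hypergeometric upper tail: enumerate every n-subset of 1..N with
# utils::combn, call elements 1..K "gold", and count subsets with >= k gold.
# Independent of stats::phyper by construction; only feasible for small N.
enum_hypergeom_tail <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  successes <- colSums(draws <= K)
  mean(successes >= k)
}

# Attribute vectors of the three approved CRC targets as printed in the
# published ranking (used as exact regression points for the linear score).
table4_targets <- function() {
  tibble::tibble(
    ensembl_id = c("ENSG00000112715", "ENSG00000146648", "ENSG00000073756"),
    symbol = c("VEGFA", "EGFR", "PTGS2"),
    name = c("Vascular endothelial growth factor A",
             "Epidermal growth factor receptor",
             "Prostaglandin-endoperoxide synthase 2"),
    uniprot_ids = list("P15692", "P00533", "P35354"),
    n_associated_diseases = c(2188L, 1839L, 1585L),
    tractability_count = c(5L, 7L, 4L),
    tractability_flags = list(NULL, NULL, NULL),
    subcellular_location = c("Secreted", "Cell membrane", "Microsome membrane"),
    n_safety_liabilities = c(0L, 2L, 25L),
    n_unique_drugs = c(11L, 72L, 75L),
    n_approved = c(4L, 14L, 12L),
    n_phase1 = c(0L, 0L, 0L),
    n_phase2 = c(0L, 0L, 0L),
    n_phase3 = c(1L, 2L, 0L),
    n_phase4 = c(4L, 14L, 12L),
    n_pathways = c(2L, 1L, 1L)
  )
}

# A tiny hand-built snapshot with known structure for membership/mapping
# tests: 3 genes, 2 pathways, 3 drug links (one drug shared by two targets).
tiny_snapshot <- function() {
  mk_target <- function(ensg, sym, ...) {
    tibble::tibble(
      ensembl_id = ensg, symbol = sym, name = paste("Protein", sym),
      uniprot_ids = list(paste0("P", substr(ensg, 12, 15))),
      tractability_flags = list(NULL), subcellular_location = "No data",
      ...
    )
  }
  targets <- dplyr::bind_rows(
    mk_target("ENSG00000000001", "AAA1", n_associated_diseases = 10L,
              tractability_count = 2L, n_safety_liabilities = 0L,
              n_unique_drugs = 3L, n_approved = 1L, n_phase1 = 1L,
              n_phase2 = 0L, n_phase3 = 1L, n_phase4 = 1L),
    mk_target("ENSG00000000002", "BBB2", n_associated_diseases = 5L,
              tractability_count = 0L, n_safety_liabilities = 3L,
              n_unique_drugs = 0L, n_approved = 0L, n_phase1 = 0L,
              n_phase2 = 0L, n_phase3 = 0L, n_phase4 = 0L),
    mk_target("ENSG00000000003", "CCC3", n_associated_diseases = 50L,
              tractability_count = 5L, n_safety_liabilities = 1L,
              n_unique_drugs = 2L, n_approved = 2L, n_phase1 = 0L,
              n_phase2 = 0L, n_phase3 = 0L, n_phase4 = 2L)
  )
  pathways <- tibble::tibble(
    pathway_id = c("PW00001", "PW00002"),
    name = c("Alpha signaling", "Beta signaling"),
    source_db = c("Reactome", "KEGG"),
    members = list(c("ENSG00000000001", "ENSG00000000002",
                     "ENSG00000000003"),
                   c("ENSG00000000001", "ENSG00000000003"))
  )
  gene_map <- tibble::tibble(
    symbol = targets$symbol,
    ensembl_id = targets$ensembl_id,
    entrez_id = c(101L, 102L, 103L),
    uniprot_ids = targets$uniprot_ids
  )
  drugs <- tibble::tibble(
    drug_id = c("CHEMBL000002", "CHEMBL000001", "CHEMBL000001"),
    drug_name = c("drug two", "drug one", "drug one"),
    drug_type = c("small molecule", "antibody", "antibody"),
    action = c("inhibitor", "antagonist", "antagonist"),
    max_phase = c(2L, 4L, 4L),
    is_approved = c(FALSE, TRUE, TRUE),
    target_ensembl_id = c("ENSG00000000001", "ENSG00000000001",
                          "ENSG00000000003")
  )
  targetrank::snapshot(pathways, gene_map, targets, drugs)
}

expect_tbl_equal <- function(a, b) {
  testthat::expect_equal(as.data.frame(a), as.data.frame(b),
                         ignore_attr = TRUE)
}
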