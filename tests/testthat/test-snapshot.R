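test_that("snapshots survive write -> read -> write byte-identically", {
  fx <- generate_snapshot(fixture_params(seed = 7))
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_snapshot(fx$snapshot, f1)
  reread <- read_snapshot(f1)
  write_snapshot(reread, f2)
  expect_identical(readLines(f1), readLines(f2))
  # field-identical after the round trip (write_snapshot sorts rows by key)
  expect_tbl_equal(
    dplyr::arrange(reread$targets, ensembl_id),
    dplyr::arrange(fx$snapshot$targets, ensembl_id)
  )
  expect_tbl_equal(
    dplyr::arrange(reread$drugs, drug_id, target_ensembl_id),
    dplyr::arrange(fx$snapshot$drugs, drug_id, target_ensembl_id)
  )
})

test_that("an empty snapshot is valid and loadable", {
  f <- tempfile(fileext = ".json")
  write_snapshot(snapshot(), f)
  s <- read_snapshot(f)
  expect_s3_class(s, "tr_snapshot")
  expect_equal(nrow(s$pathways), 0)
  expect_equal(nrow(s$targets), 0)
})

test_that("integrity and validation violations are rejected with the offending path", {
  s <- tiny_snapshot()
  bad <- s$drugs
  bad$target_ensembl_id[1] <- "ENSG00000009999"
  expect_error(
    snapshot(s$pathways, s$gene_map, s$targets, bad),
    "ENSG00000009999", class = "targetrank_integrity_error"
  )
  badt <- s$targets
  badt$n_approved[2] <- -1L
  expect_error(
    snapshot(s$pathways, s$gene_map, badt, s$drugs),
    "n_approved", class = "targetrank_validation_error"
  )
  badt2 <- s$targets
  badt2$tractability_flags[[1]] <- c(sm_approved = TRUE)  # incomplete key set
  expect_error(
    snapshot(s$pathways, s$gene_map, badt2, s$drugs),
    "tractability_flags", class = "targetrank_validation_error"
  )
  badp <- s$pathways
  badp$members[[1]] <- c("ENSG00000000001", "not-an-accession")
  expect_error(
    snapshot(badp, s$gene_map, s$targets, s$drugs),
    "member", class = "targetrank_validation_error"
  )
})

test_that("pathway membership resolves by id, falls back to name, and warns on misses", {
  s <- tiny_snapshot()
  m <- pathway_members(s, tibble::tibble(pathway_id = "PW00002",
                                         name = "whatever"))
  expect_equal(sort(m$ensembl_id), c("ENSG00000000001", "ENSG00000000003"))

  m2 <- pathway_members(s, tibble::tibble(pathway_id = NA_character_,
                                          name = "Alpha signaling"))
  expect_equal(nrow(m2), 3)

  expect_warning(
    m3 <- pathway_members(s, tibble::tibble(pathway_id = "PW99999",
                                            name = "Unknown pathway")),
    "not found"
  )
  expect_equal(nrow(m3), 0)
})

test_that("membership on fixtures matches the generator's ground truth", {
  fx <- generate_snapshot(fixture_params(n_genes = 30, n_pathways = 10,
                                         seed = 3))
  pw <- fx$snapshot$pathways
  m <- pathway_members(fx$snapshot,
                       tibble::tibble(pathway_id = pw$pathway_id,
                                      name = pw$name))
  for (i in seq_len(nrow(pw))) {
    expect_setequal(m$ensembl_id[m$pathway_id == pw$pathway_id[i]],
                    unlist(pw$members[[i]]))
  }
})

test_that("gene id mapping is partial, reversible and rejects unknown spaces", {
  s <- tiny_snapshot()
  m <- map_gene_ids(s, c("AAA1", "CCC3"), from = "symbol", to = "ensembl")
  expect_equal(m$output, c("ENSG00000000001", "ENSG00000000003"))

  expect_message(
    m2 <- map_gene_ids(s, c("AAA1", "NOPE"), from = "symbol", to = "entrez"),
    "could not be mapped"
  )
  expect_equal(nrow(m2), 1)
  expect_equal(m2$output, "101")

  expect_equal(nrow(map_gene_ids(s, character(0), "symbol", "ensembl")), 0)
  expect_error(map_gene_ids(s, "X", from = "hgnc", to = "ensembl"),
               class = "targetrank_usage_error")

  # symbol -> ensembl -> symbol is the identity over the whole gene map
  fx <- generate_snapshot(fixture_params(n_genes = 25, seed = 5))
  fwd <- map_gene_ids(fx$snapshot, fx$snapshot$gene_map$symbol,
                      "symbol", "ensembl")
  back <- map_gene_ids(fx$snapshot, fwd$output, "ensembl", "symbol")
  expect_equal(back$output, fx$snapshot$gene_map$symbol)

  # uniprot accessions resolve back to their gene
  up <- unlist(s$gene_map$uniprot_ids[1])
  expect_equal(map_gene_ids(s, up, "uniprot", "symbol")$output, "AAA1")
})

test_that("target records are returned verbatim; unknown ids error or skip", {
  s <- tiny_snapshot()
  r <- target_records(s, "ENSG00000000003")
  expect_equal(r$symbol, "CCC3")
  expect_equal(r$n_approved, 2L)
  expect_error(target_records(s, "ENSG00000009999"),
               class = "targetrank_not_found_error")
  expect_message(
    skipped <- target_records(s, c("ENSG00000000001", "ENSG00000009999"),
                              missing = "skip"),
    "Skipping 1"
  )
  expect_equal(skipped$ensembl_id, "ENSG00000000001")

  fx <- generate_snapshot(fixture_params(n_genes = 15, seed = 9))
  all_recs <- target_records(fx$snapshot, fx$snapshot$targets$ensembl_id)
  expect_tbl_equal(all_recs, fx$snapshot$targets)
})

test_that("drug links come back sorted by drug id; unknown or undrugged targets give none", {
  s <- tiny_snapshot()
  d <- drugs_for_target(s, "ENSG00000000001")
  expect_equal(d$drug_id, c("CHEMBL000001", "CHEMBL000002"))
  expect_equal(nrow(drugs_for_target(s, "ENSG00000000002")), 0)
  expect_equal(nrow(drugs_for_target(s, "ENSG00000009999")), 0)
})

test_that("a target seeded with the published EGFR attribute profile is retrievable verbatim", {
  t4 <- table4_targets()
  s <- snapshot(targets = dplyr::select(t4, -n_pathways))
  egfr <- target_records(s, "ENSG00000146648")
  expect_equal(egfr$n_unique_drugs, 72L)
  expect_equal(egfr$n_approved, 14L)
  expect_equal(egfr$n_safety_liabilities, 2L)
})
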