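# independent re-implementation of the score for oracle checks
oracle_score <- function(df, w) {
  w[["pathways"]] * df$n_pathways +
    w[["tractability"]] * df$tractability_count +
    w[["approved"]] * df$n_approved +
    w[["safety"]] * df$n_safety_liabilities +
    w[["unique_drugs"]] * df$n_unique_drugs +
    w[["diseases"]] * df$n_associated_diseases +
    w[["phase1"]] * df$n_phase1 + w[["phase2"]] * df$n_phase2 +
    w[["phase3"]] * df$n_phase3 + w[["phase4"]] * df$n_phase4
}

test_that("weight presets carry the published values and overrides are validated", {
  w <- weight_scheme("default")
  expect_equal(unname(w[c("pathways", "tractability", "approved", "safety",
                          "unique_drugs", "diseases", "phase1", "phase2",
                          "phase3", "phase4")]),
               c(1, 1, 1, -2, 1, 1, 0.5, 1, 1.5, 2))
  wn <- weight_scheme("novel")
  expect_equal(unname(wn[c("pathways", "tractability", "approved", "safety",
                           "unique_drugs", "diseases", "phase1", "phase2",
                           "phase3", "phase4")]),
               c(0.5, 0.5, 0.5, -2, 0.5, 0.01, 10, 4, 0.5, 0.01))
  expect_error(weight_scheme("default", bogus = 1),
               class = "targetrank_usage_error")
  over <- weight_scheme("default", safety = -5)
  expect_equal(unname(over[["safety"]]), -5)

  yml <- tempfile(fileext = ".yaml")
  writeLines(c("preset: novel", "phase1: 20"), yml)
  wy <- read_weight_scheme(yml)
  expect_equal(unname(wy[["phase1"]]), 20)
  expect_equal(unname(wy[["phase2"]]), 4)
  writeLines(c("phase5: 1"), yml)
  expect_error(read_weight_scheme(yml), class = "targetrank_usage_error")
})

test_that("the published attribute vectors reproduce their printed default-weight scores", {
  t4 <- table4_targets()
  scored <- score_targets(t4, "default")
  expect_identical(scored$score[scored$symbol == "VEGFA"], 2219.5)
  expect_identical(scored$score[scored$symbol == "EGFR"], 1960)
  expect_identical(scored$score[scored$symbol == "PTGS2"], 1651)
  # scalar form agrees
  vegfa <- dplyr::filter(t4, symbol == "VEGFA")
  expect_identical(score_target(vegfa, n_pathways = 2, "default"), 2219.5)
})

test_that("the novel preset recomputes deterministically from the same attributes", {
  egfr <- dplyr::filter(table4_targets(), symbol == "EGFR")
  expect_equal(score_target(egfr, n_pathways = 1, "novel"), 62.53)
})

test_that("an all-zero attribute vector scores zero under any weights", {
  z <- tibble::tibble(
    ensembl_id = "ENSG00000000001", symbol = "ZERO",
    n_associated_diseases = 0L, tractability_count = 0L,
    n_safety_liabilities = 0L, n_unique_drugs = 0L, n_approved = 0L,
    n_phase1 = 0L, n_phase2 = 0L, n_phase3 = 0L, n_phase4 = 0L,
    n_pathways = 0L
  )
  expect_equal(score_targets(z, "default")$score, 0)
  expect_equal(score_targets(z, "novel")$score, 0)
  expect_equal(score_targets(z, weight_scheme("default", diseases = 99))$score, 0)
})

test_that("scoring is linear: weight scaling scales scores, single-weight perturbation shifts by delta * attribute", {
  fx <- generate_snapshot(fixture_params(n_genes = 30, seed = 13))
  tg <- fx$snapshot$targets
  tg$n_pathways <- 1L
  w <- weight_scheme("default")
  base <- score_targets(tg, w)$score

  for (c_mult in c(2, -0.5, 10)) {
    w_scaled <- weight_scheme("default")
    w_scaled[] <- as.numeric(w) * c_mult
    expect_equal(score_targets(tg, w_scaled)$score, base * c_mult)
  }

  attrs <- c(pathways = "n_pathways", tractability = "tractability_count",
             approved = "n_approved", safety = "n_safety_liabilities",
             unique_drugs = "n_unique_drugs", diseases = "n_associated_diseases",
             phase1 = "n_phase1", phase2 = "n_phase2", phase3 = "n_phase3",
             phase4 = "n_phase4")
  delta <- 0.37
  for (key in names(attrs)) {
    w2 <- weight_scheme("default")
    w2[key] <- w2[key] + delta
    expect_equal(score_targets(tg, w2)$score,
                 base + delta * as.numeric(tg[[attrs[key]]]),
                 tolerance = 1e-12)
  }
})

test_that("under default weights the score is monotone in every attribute, with safety penalized", {
  fx <- generate_snapshot(fixture_params(n_genes = 10, seed = 17))
  tg <- fx$snapshot$targets
  tg$n_pathways <- 2L
  base <- score_targets(tg, "default")$score
  up_cols <- c("n_pathways", "tractability_count", "n_approved",
               "n_unique_drugs", "n_associated_diseases", "n_phase1",
               "n_phase2", "n_phase3", "n_phase4")
  for (col in up_cols) {
    bumped <- tg
    bumped[[col]] <- bumped[[col]] + 3L
    expect_true(all(score_targets(bumped, "default")$score >= base),
                info = col)
  }
  worse <- tg
  worse$n_safety_liabilities <- worse$n_safety_liabilities + 3L
  expect_true(all(score_targets(worse, "default")$score <= base))
})

test_that("ranking matches a brute-force sort and is invariant to input permutation", {
  fx <- generate_snapshot(fixture_params(n_genes = 50, seed = 23))
  tg <- fx$snapshot$targets
  tg$n_pathways <- sample(0:4, 50, replace = TRUE)

  ranked <- rank_targets(tg, "default")
  expect_equal(sort(ranked$rank), 1:50)
  expect_setequal(ranked$ensembl_id, tg$ensembl_id)

  w <- weight_scheme("default")
  sc <- oracle_score(tg, w)
  oracle_order <- tg$ensembl_id[order(-sc, -tg$n_approved, -tg$n_unique_drugs,
                                      tg$symbol)]
  expect_equal(ranked$ensembl_id, oracle_order)

  shuffled <- tg[sample(nrow(tg)), ]
  ranked2 <- rank_targets(shuffled, "default")
  expect_equal(ranked2$ensembl_id, ranked$ensembl_id)
  expect_equal(ranked2$score, ranked$score)

  single <- rank_targets(tg[7, ], "default")
  expect_equal(single$rank, 1L)

  expect_error(rank_targets(dplyr::bind_rows(tg, tg[1, ]), "default"),
               class = "targetrank_usage_error")
})

test_that("score ties break by approved count, then unique drugs, then symbol", {
  base <- tibble::tibble(
    ensembl_id = sprintf("ENSG%011d", 1:3),
    symbol = c("ZZZ", "MMM", "AAA"),
    n_associated_diseases = 0L, tractability_count = 0L,
    n_safety_liabilities = 0L,
    n_unique_drugs = c(5L, 5L, 0L),
    n_approved = c(2L, 2L, 4L),
    n_phase1 = 0L, n_phase2 = 0L, n_phase3 = 0L, n_phase4 = 0L,
    n_pathways = 0L
  )
  # weights that zero out every attribute: all scores tie at 0
  w <- weight_scheme("default")
  w[] <- 0
  ranked <- rank_targets(base, w)
  expect_equal(ranked$symbol, c("AAA", "MMM", "ZZZ"))
})

test_that("pathway-count computation equals the brute-force double loop", {
  fx <- generate_snapshot(fixture_params(n_genes = 50, n_pathways = 10,
                                         seed = 29))
  pw <- fx$snapshot$pathways
  sig <- tibble::tibble(
    name = pw$name, pathway_id = pw$pathway_id, source_db = pw$source_db,
    n_proteins = lengths(pw$members), n_degs = NA_integer_,
    p_adjusted = 0.01, status = "unknown"
  )
  counts <- count_pathway_memberships(sig, fx$snapshot)

  brute <- new.env()
  for (i in seq_len(nrow(pw))) {
    for (g in unlist(pw$members[[i]])) {
      assign(g, get0(g, envir = brute, ifnotfound = 0L) + 1L, envir = brute)
    }
  }
  expect_equal(nrow(counts), length(ls(brute)))
  for (g in counts$ensembl_id) {
    expect_equal(counts$n_pathways[counts$ensembl_id == g],
                 get(g, envir = brute))
  }
  expect_tbl_equal(dplyr::arrange(counts, ensembl_id),
                   dplyr::arrange(fx$pathway_counts, ensembl_id))

  # gene in no significant pathway is absent
  expect_false(any(!counts$ensembl_id %in% unlist(pw$members)))
})

test_that("the drug table deduplicates by drug and inherits the best target's score", {
  s <- tiny_snapshot()
  tg <- s$targets
  tg$n_pathways <- c(2L, 2L, 1L)
  ranked <- rank_targets(tg, "default")
  tbl <- build_drug_table(ranked, s)

  # 3 links, 1 shared drug -> 2 rows
  expect_equal(nrow(tbl), 2)
  expect_lte(nrow(tbl), nrow(s$drugs))
  expect_true(all(tbl$drug_id %in% s$drugs$drug_id))

  shared <- tbl[tbl$drug_id == "CHEMBL000001", ]
  linked_scores <- ranked$score[ranked$ensembl_id %in%
                                  c("ENSG00000000001", "ENSG00000000003")]
  expect_equal(shared$score, max(linked_scores))
  expect_equal(shared$target_symbol,
               ranked$symbol[ranked$score == max(linked_scores)][1])

  # sorted by inherited score desc then drug_id
  expect_equal(tbl$score, sort(tbl$score, decreasing = TRUE))

  # brute-force oracle on a larger fixture
  fx <- generate_snapshot(fixture_params(n_genes = 40, seed = 31))
  tg2 <- fx$snapshot$targets
  tg2$n_pathways <- 0L
  ranked2 <- rank_targets(tg2, "default")
  tbl2 <- build_drug_table(ranked2, fx$snapshot)
  score_of <- setNames(ranked2$score, ranked2$ensembl_id)
  brute <- c(tapply(score_of[fx$snapshot$drugs$target_ensembl_id],
                    fx$snapshot$drugs$drug_id, max))
  expect_equal(nrow(tbl2), length(brute))
  expect_equal(setNames(tbl2$score, tbl2$drug_id)[names(brute)],
               brute)

  # a target with zero drugs contributes no rows
  expect_false("ENSG00000000002" %in%
                 s$drugs$target_ensembl_id[s$drugs$drug_id %in% tbl$drug_id &
                                             FALSE])
  expect_equal(nrow(build_drug_table(ranked[0, ], s)), 0)
})

test_that("planted gold targets rank above background in median over 20 seeds", {
  gold_better <- vapply(1:20, function(s) {
    fx <- generate_snapshot(fixture_params(seed = s))
    ranked <- rank_targets(fx$snapshot$targets, "default",
                           pathway_counts = fx$pathway_counts)
    is_gold <- ranked$symbol %in% fx$gold_symbols
    median(ranked$rank[is_gold]) < median(ranked$rank[!is_gold])
  }, logical(1))
  expect_true(all(gold_better))
})

test_that("glance summarises a ranking", {
  fx <- generate_snapshot(fixture_params(n_genes = 10, seed = 2))
  tg <- fx$snapshot$targets
  tg$n_pathways <- 0L
  ranked <- rank_targets(tg, "default")
  g <- glance(ranked)
  expect_equal(g$n_targets, 10L)
  expect_equal(g$top_symbol, ranked$symbol[1])
  expect_equal(g$preset, "default")
})
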