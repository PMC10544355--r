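# Deterministic synthetic-data generator. It emulates the inputs the pipeline
# consumes in production — a pathway enrichment table and an Open
# Targets-style annotation snapshot — with a planted "gold" subset of targets
# whose drug-development attributes are inflated, so that ranking quality can
# be benchmarked offline.
#
# Attributes are not drawn independently: real target annotations are
# internally consistent, and the generator reproduces that structure.
# Per-phase therapeutic counts are drawn first; the approved count equals the
# phase-4 count (an approved drug's maximum phase is post-approval); the
# unique-drug count is the sum of the per-phase counts plus shelved compounds
# that never reached a recorded phase; and the associated-disease count grows
# with drug-development intensity (heavily drugged targets are heavily
# studied), saturating at the magnitude observed for flagship oncology
# targets (~2500).

#' Parameters for the fixture generator
#'
#' @param n_pathways Number of synthetic pathways.
#' @param n_genes Number of genes/targets.
#' @param genes_per_pathway Integer range `c(lo, hi)` of members per pathway.
#' @param n_gold Number of planted gold targets (`<= n_genes`).
#' @param gold_attribute_inflation Multiplier applied to the approved (hence
#'   phase-4) and shelved-compound draws of gold targets, inflating their
#'   approved, phase-4 and unique-drug counts.
#' @param attribute_ranges Named list of integer ranges `c(lo, hi)` for the
#'   base draws: `n_approved`, `n_phase1`, `n_phase2`, `n_phase3`,
#'   `n_shelved`, `tractability_count`, `n_safety_liabilities`,
#'   `disease_base`.
#' @param disease_gain Additional associated diseases per unique drug.
#' @param disease_cap Saturation ceiling for the associated-disease count.
#' @param drug_links_per_target Integer range of drug links per target.
#' @param seed Integer seed; the whole generation is a deterministic function
#'   of the parameters.
#' @return A validated list of class `tr_fixture_params`.
#' @export
fixture_params <- function(n_pathways = 10,
                           n_genes = 50,
                           genes_per_pathway = c(5, 15),
                           n_gold = 5,
                           gold_attribute_inflation = 10,
                           attribute_ranges = list(),
                           disease_gain = 15,
                           disease_cap = 2500,
                           drug_links_per_target = c(0, 4),
                           seed = 1) {
  defaults <- list(
    n_approved = c(0, 15), n_phase1 = c(0, 15), n_phase2 = c(0, 15),
    n_phase3 = c(0, 15), n_shelved = c(0, 60),
    tractability_count = c(0, 12), n_safety_liabilities = c(0, 25),
    disease_base = c(0, 1000)
  )
  bad <- setdiff(names(attribute_ranges), names(defaults))
  if (length(bad) > 0) {
    abort(paste0("Unknown attribute range(s): ", paste(bad, collapse = ", ")),
          class = "targetrank_usage_error")
  }
  defaults[names(attribute_ranges)] <- attribute_ranges

  p <- list(
    n_pathways = as.integer(n_pathways), n_genes = as.integer(n_genes),
    genes_per_pathway = as.integer(genes_per_pathway),
    n_gold = as.integer(n_gold),
    gold_attribute_inflation = as.numeric(gold_attribute_inflation),
    attribute_ranges = lapply(defaults, as.integer),
    disease_gain = as.numeric(disease_gain),
    disease_cap = as.integer(disease_cap),
    drug_links_per_target = as.integer(drug_links_per_target),
    seed = as.integer(seed)
  )
  if (p$n_genes < 1 || p$n_pathways < 0 || p$n_gold < 0 ||
      p$n_gold > p$n_genes) {
    abort("Require n_genes >= 1, n_pathways >= 0, 0 <= n_gold <= n_genes.",
          class = "targetrank_usage_error")
  }
  if (p$gold_attribute_inflation <= 0) {
    abort("`gold_attribute_inflation` must be positive.",
          class = "targetrank_usage_error")
  }
  check_range <- function(r, what) {
    if (length(r) != 2 || any(is.na(r)) || r[1] > r[2] || r[1] < 0) {
      abort(paste0("Invalid range for ", what, "."),
            class = "targetrank_usage_error")
    }
  }
  check_range(p$genes_per_pathway, "genes_per_pathway")
  check_range(p$drug_links_per_target, "drug_links_per_target")
  purrr::iwalk(p$attribute_ranges, check_range)
  if (p$n_pathways > 0 && p$genes_per_pathway[2] > p$n_genes) {
    p$genes_per_pathway[2] <- p$n_genes
    p$genes_per_pathway[1] <- min(p$genes_per_pathway)
  }
  structure(p, class = "tr_fixture_params")
}

# right-skewed integer draw within [lo, hi]: most annotation counts sit far
# below their observed maxima
draw_count <- function(n, range, shape2 = 3) {
  lo <- range[1]; hi <- range[2]
  lo + pmin(hi - lo, floor((hi - lo + 1) * rbeta(n, 1, shape2)))
}

.fixture_locations <- c(
  "Cell membrane", "Cytoplasm", "Nucleus", "Secreted", "Cytosol",
  "Endoplasmic reticulum membrane", "Mitochondrion", "No data"
)
.fixture_pathway_themes <- c(
  "signaling by receptor tyrosine kinases", "cell cycle checkpoint control",
  "rRNA processing", "oxidative stress response", "apoptotic execution",
  "chromatin remodeling", "innate immune activation", "lipid metabolism",
  "DNA replication licensing", "translation elongation", "autophagy",
  "hypoxia response", "WNT pathway regulation", "MAPK cascade",
  "proteasomal degradation", "interferon signaling"
)
.fixture_drug_types <- c("small molecule", "antibody", "protein",
                         "oligonucleotide")
.fixture_actions <- c("inhibitor", "agonist", "antagonist", "modulator",
                      "binding agent")

#' Generate a synthetic snapshot with planted gold targets
#'
#' Builds a schema-valid snapshot of `n_genes` targets, `n_pathways` pathways
#' with random member sets, a complete gene identifier map and randomly linked
#' drug records. `n_gold` targets are planted with their approved/phase-4 and
#' shelved-compound draws multiplied by `gold_attribute_inflation`, which
#' inflates exactly the approved, phase-4 and unique-drug counts relative to
#' the background — the signal a ranking benchmark should recover.
#'
#' The generator consumes one pseudo-random stream seeded from
#' `params$seed`; identical parameters give identical output (the caller's RNG
#' state is left untouched).
#'
#' @param params A `tr_fixture_params` from [fixture_params()].
#' @return A list of class `tr_fixture`: `snapshot` (a `tr_snapshot`),
#'   `gold_symbols`, `pathway_counts` (ground-truth per-gene significant
#'   pathway counts, assuming all generated pathways significant) and
#'   `params`.
#' @export
generate_snapshot <- function(params = fixture_params()) {
  stopifnot(inherits(params, "tr_fixture_params"))
  # private RNG stream: seed deterministically, restore the caller's state
  old_seed <- .GlobalEnv$.Random.seed
  on.exit({
    if (is.null(old_seed)) {
      suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
    } else {
      assign(".Random.seed", old_seed, envir = .GlobalEnv)
    }
  })
  set.seed(params$seed)

  ng <- params$n_genes
  ensembl <- sprintf("ENSG%011d", seq_len(ng))
  symbol <- sprintf("GENE%04d", seq_len(ng))
  gene_map <- tibble(
    symbol = symbol,
    ensembl_id = ensembl,
    entrez_id = 100000L + seq_len(ng),
    uniprot_ids = map(seq_len(ng), ~ sprintf("P%05d", 10000L + .x))
  )

  gold_idx <- if (params$n_gold > 0) sort(sample(ng, params$n_gold)) else integer(0)
  infl <- params$gold_attribute_inflation
  rng <- params$attribute_ranges

  n_phase1 <- draw_count(ng, rng$n_phase1)
  n_phase2 <- draw_count(ng, rng$n_phase2)
  n_phase3 <- draw_count(ng, rng$n_phase3)
  n_approved <- draw_count(ng, rng$n_approved)
  n_shelved <- draw_count(ng, rng$n_shelved)
  # background unique-drug count: every phase-counted drug plus shelved
  # compounds; approved drugs are the phase-4 drugs
  n_unique <- n_phase1 + n_phase2 + n_phase3 + n_approved + n_shelved
  # planted signal: the approved, phase-4 and unique-drug counts of gold
  # targets are the background draws times the inflation factor
  n_approved[gold_idx] <- as.integer(round(n_approved[gold_idx] * infl))
  n_unique[gold_idx] <- as.integer(round(n_unique[gold_idx] * infl))
  n_phase4 <- n_approved

  disease_base <- draw_count(ng, rng$disease_base)
  n_diseases <- pmin(params$disease_cap,
                     disease_base + as.integer(round(params$disease_gain * n_unique)))

  flags <- map(seq_len(ng), function(i) {
    stats::setNames(runif(12) < 0.2, .tractability_keys)
  })

  targets <- tibble(
    ensembl_id = ensembl,
    symbol = symbol,
    name = paste("Synthetic protein", seq_len(ng)),
    uniprot_ids = gene_map$uniprot_ids,
    n_associated_diseases = as.integer(n_diseases),
    tractability_count = as.integer(draw_count(ng, rng$tractability_count)),
    tractability_flags = flags,
    subcellular_location = sample(.fixture_locations, ng, replace = TRUE),
    n_safety_liabilities = as.integer(draw_count(ng, rng$n_safety_liabilities)),
    n_unique_drugs = as.integer(n_unique),
    n_approved = as.integer(n_approved),
    n_phase1 = as.integer(n_phase1), n_phase2 = as.integer(n_phase2),
    n_phase3 = as.integer(n_phase3), n_phase4 = as.integer(n_phase4)
  )

  np <- params$n_pathways
  if (np > 0) {
    dbs <- sample(c("KEGG", "Reactome", "PID", "BioCarta", "Panther"),
                  np, replace = TRUE)
    themes <- sample(.fixture_pathway_themes, np, replace = TRUE)
    sizes <- sample(seq(params$genes_per_pathway[1],
                        params$genes_per_pathway[2]), np, replace = TRUE)
    pathways <- tibble(
      pathway_id = sprintf("PW%05d", seq_len(np)),
      name = sprintf("Synthetic pathway %d: %s", seq_len(np), themes),
      source_db = dbs,
      members = map(sizes, ~ sort(sample(ensembl, .x)))
    )
  } else {
    pathways <- empty_pathways_tbl()
  }

  link_counts <- sample(
    seq(params$drug_links_per_target[1], params$drug_links_per_target[2]),
    ng, replace = TRUE
  )
  drug_pool <- character(0)
  links <- vector("list", ng)
  next_id <- 1L
  for (i in seq_len(ng)) {
    k <- link_counts[i]
    if (k == 0) next
    ids <- character(k)
    for (j in seq_len(k)) {
      if (length(drug_pool) > 0 && runif(1) < 0.2) {
        ids[j] <- sample(drug_pool, 1) # shared drug: hits several targets
      } else {
        ids[j] <- sprintf("CHEMBL%06d", next_id)
        drug_pool <- c(drug_pool, ids[j])
        next_id <- next_id + 1L
      }
    }
    ids <- unique(ids)
    phases <- sample(0:4, length(ids), replace = TRUE)
    links[[i]] <- tibble(
      drug_id = ids,
      drug_name = paste("Compound", sub("^CHEMBL0*", "", ids)),
      drug_type = sample(.fixture_drug_types, length(ids), replace = TRUE),
      action = sample(.fixture_actions, length(ids), replace = TRUE),
      max_phase = as.integer(phases),
      is_approved = phases == 4L & runif(length(ids)) < 0.8,
      target_ensembl_id = ensembl[i]
    )
  }
  drugs <- list_rbind(purrr::compact(links))
  if (is.null(drugs) || nrow(drugs) == 0) drugs <- empty_drugs_tbl()

  snap <- snapshot(pathways, gene_map, targets, drugs)

  truth_counts <- if (np > 0) {
    tibble(pathway_id = rep(pathways$pathway_id, lengths(pathways$members)),
           ensembl_id = unlist(pathways$members)) |>
      dplyr::distinct() |>
      dplyr::count(.data$ensembl_id, name = "n_pathways")
  } else {
    tibble(ensembl_id = character(), n_pathways = integer())
  }

  structure(
    list(snapshot = snap,
         gold_symbols = symbol[gold_idx],
         pathway_counts = truth_counts,
         params = params),
    class = "tr_fixture"
  )
}

#' Write a snapshot's pathway inventory as an enrichment table
#'
#' Emits a file in either supported dialect that the corresponding reader
#' parses back into the snapshot's pathways, with supplied (or deterministic
#' default) adjusted p-values attached. Used to exercise the full pipeline on
#' generated data.
#'
#' @param snapshot A `tr_snapshot`.
#' @param path Output file path.
#' @param dialect `"spia"` or `"enrichr"`.
#' @param p_values Optional numeric vector of adjusted p-values, one per
#'   pathway (snapshot order). Defaults to an evenly spaced grid inside
#'   (0, 0.05), i.e. all significant at the conventional threshold.
#' @param deg_fraction Fraction of each pathway's members reported as
#'   differentially expressed (fills the DEG-count column).
#' @return `path`, invisibly.
#' @export
write_pathway_table <- function(snapshot, path,
                                dialect = c("spia", "enrichr"),
                                p_values = NULL, deg_fraction = 0.8) {
  stopifnot(inherits(snapshot, "tr_snapshot"))
  dialect <- rlang::arg_match(dialect)
  pw <- snapshot$pathways
  np <- nrow(pw)
  if (is.null(p_values)) {
    p_values <- if (np > 0) 0.05 * seq_len(np) / (np + 1) else numeric(0)
  }
  if (length(p_values) != np) {
    abort("`p_values` must have one entry per snapshot pathway.",
          class = "targetrank_usage_error")
  }
  n_prot <- lengths(pw$members)
  n_deg <- pmin(n_prot, floor(n_prot * deg_fraction))
  status <- rep(c("Activated", "Inhibited"), length.out = max(np, 1))[seq_len(np)]

  if (dialect == "spia") {
    out <- tibble(
      Name = pw$name, ID = pw$pathway_id, pSize = n_prot, NDE = n_deg,
      pGFdr = p_values, Status = status, SourceDB = pw$source_db
    )
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    sym_of <- stats::setNames(snapshot$gene_map$symbol,
                              snapshot$gene_map$ensembl_id)
    genes <- map_chr(pw$members, function(m) {
      s <- sym_of[unlist(m)]
      paste(s[!is.na(s)], collapse = ";")
    })
    out <- tibble(
      Term = paste(pw$name, pw$pathway_id),
      Overlap = paste0(n_deg, "/", pmax(n_prot, 1)),
      `Adjusted P-value` = p_values,
      Genes = genes
    )
    readr::write_tsv(out, path, progress = FALSE)
  }
  invisible(path)
}
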