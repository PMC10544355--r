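# End-to-end orchestration: parse -> filter -> resolve members -> score ->
# rank -> drug table -> (optional) gold-set enrichment, with all artifacts
# written to an output directory.

#' Run the full prioritization pipeline
#'
#' Reads a pathway enrichment table, keeps significant pathways, resolves
#' member targets against the snapshot, scores and ranks them under the chosen
#' weight scheme, derives the prioritized-therapeutics table and, when a gold
#' set is supplied, tests top-k enrichment. Writes `targets.tsv`, `drugs.tsv`,
#' `manifest.json` and (with a gold set) `enrichment.json` into `out_dir`.
#'
#' Both TSVs start with a `#` provenance line carrying the package version and
#' a hash of the weight scheme. Targets present in a significant pathway but
#' absent from the snapshot are skipped with a logged count: public pathway
#' membership routinely exceeds annotation coverage. A run in which no pathway
#' passes the threshold still succeeds, writing empty tables and a prominent
#' warning.
#'
#' @param input Path to the pathway enrichment table.
#' @param snapshot A `tr_snapshot` or the path to a snapshot JSON file.
#' @param out_dir Output directory (created if needed).
#' @param dialect Input dialect, `"spia"` or `"enrichr"`.
#' @param alpha Significance threshold on the adjusted p-value.
#' @param weights Weight scheme: preset name, YAML path, or `tr_weights`.
#' @param top_k Top-list size for the enrichment test.
#' @param gold Optional gold set: character vector of symbols or a file path.
#' @param column_map Optional SPIA column mapping (see
#'   [read_spia_pathways()]).
#' @param delim Field delimiter of the input table.
#' @param quiet Suppress progress messages.
#' @return The run manifest (a list), invisibly.
#' @export
run_pipeline <- function(input, snapshot, out_dir,
                         dialect = c("spia", "enrichr"),
                         alpha = 0.05, weights = "default", top_k = 15,
                         gold = NULL, column_map = NULL, delim = "\t",
                         quiet = FALSE) {
  dialect <- rlang::arg_match(dialect)
  w <- as_weights(weights)
  say <- function(...) if (!quiet) inform(paste0(...))

  if (is.character(snapshot)) {
    snapshot <- read_snapshot(snapshot)
  }
  stopifnot(inherits(snapshot, "tr_snapshot"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  pathways_in <- read_pathway_table(input, dialect = dialect,
                                    column_map = column_map, delim = delim)
  say("Parsed ", nrow(pathways_in), " pathway record(s) from ", input)

  sig <- filter_significant(pathways_in, alpha)
  say(nrow(sig), " pathway(s) significant at alpha = ", alpha)

  if (nrow(sig) == 0) {
    warn(paste0("No pathway passed the significance threshold (alpha = ",
                alpha, "); writing empty outputs."))
    members <- tibble(pathway_id = character(), name = character(),
                      ensembl_id = character())
    ranked <- rank_targets(score_input(empty_targets_tbl(), NULL), w)
  } else {
    members <- pathway_members(snapshot, sig)
    counts <- count_pathway_memberships(sig, snapshot)
    recs <- target_records(snapshot, counts$ensembl_id, missing = "skip")
    n_skipped <- nrow(counts) - nrow(recs)
    say(nrow(recs), " target(s) resolved; ", n_skipped, " skipped")
    ranked <- rank_targets(recs, w, pathway_counts = counts)
  }

  drug_tbl <- build_drug_table(ranked, snapshot)

  stamp <- paste0("# targetrank ", utils::packageVersion("targetrank"),
                  "; weights ", scheme_hash(w))
  targets_path <- file.path(out_dir, "targets.tsv")
  drugs_path <- file.path(out_dir, "drugs.tsv")
  write_stamped_tsv(flatten_ranking(ranked), targets_path, stamp)
  write_stamped_tsv(drug_tbl, drugs_path, stamp)

  enrichment <- NULL
  if (!is.null(gold) && nrow(ranked) > 0) {
    gold_syms <- if (is.character(gold) && length(gold) == 1 &&
                     file.exists(gold)) read_gold_set(gold) else gold
    k_eff <- min(top_k, nrow(ranked))
    enrichment <- evaluate_topk(ranked, gold_syms, k = k_eff)
    jsonlite::write_json(as.list(tidy(enrichment)),
                         file.path(out_dir, "enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
    say("Top-", k_eff, " enrichment p = ",
        format(enrichment$p_value, digits = 4))
  }

  manifest <- list(
    tool = "targetrank",
    version = as.character(utils::packageVersion("targetrank")),
    config = list(
      input = input, dialect = dialect, alpha = alpha, top_k = top_k,
      weights = stats::setNames(as.list(as.numeric(w)), names(w)),
      weight_preset = attr(w, "preset") %||% "custom",
      weight_hash = scheme_hash(w),
      gold = if (is.character(gold) && length(gold) == 1) gold else
        if (is.null(gold)) NULL else "(inline)"
    ),
    counts = list(
      pathways_in = nrow(pathways_in),
      pathways_significant = nrow(sig),
      pathways_matched = length(unique(members$pathway_id)),
      targets_in_pathways = length(unique(members$ensembl_id)),
      targets_scored = nrow(ranked),
      drugs = nrow(drug_tbl)
    ),
    enrichment = if (is.null(enrichment)) NULL else as.list(tidy(enrichment))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}

# join target records with pathway counts so an empty run still has the full
# column inventory
score_input <- function(targets, counts) {
  if (!"n_pathways" %in% names(targets)) {
    targets$n_pathways <- integer(nrow(targets))
  }
  targets
}

# flatten list-columns for TSV output: uniprot ids joined by ';', the 12
# tractability flags as logical columns
flatten_ranking <- function(ranked) {
  out <- as_tibble(ranked)
  out$uniprot_ids <- map_chr(out$uniprot_ids,
                             ~ paste(unlist(.x), collapse = ";"))
  flags <- out$tractability_flags
  for (key in .tractability_keys) {
    out[[key]] <- map_lgl(flags, function(fl) {
      if (is.null(fl)) NA else isTRUE(fl[[key]])
    })
  }
  out$tractability_flags <- NULL
  out
}

write_stamped_tsv <- function(x, path, stamp) {
  writeLines(stamp, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read back a pipeline output table
#'
#' Reads `targets.tsv` / `drugs.tsv` written by [run_pipeline()], skipping the
#' provenance comment line.
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_output_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
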