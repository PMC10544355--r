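# Query construction for a live Open Targets-style GraphQL backend, and
# conversion of recorded responses into the snapshot structure. Only query
# text and response parsing live here; executing queries over HTTP is left to
# the caller so that everything in this package runs offline.

.live_query_fields <- '
query targetAnnotation($ensemblIds: [String!]!) {
  targets(ensemblIds: $ensemblIds) {
    id
    approvedSymbol
    approvedName
    proteinIds { id source }
    associatedDiseases { count }
    tractability { modality label value }
    subcellularLocations { location }
    safetyLiabilities { event }
    knownDrugs {
      uniqueDrugs
      rows {
        phase
        mechanismOfAction
        drug { id name drugType isApproved }
      }
    }
  }
}'

#' Build a batched GraphQL query plan for target annotation
#'
#' Produces the query document requesting exactly the fields a snapshot
#' stores, plus a pagination plan splitting the accessions into batches of at
#' most `page_size`. No network request is made.
#'
#' @param ensembl_ids Nonempty character vector of Ensembl gene accessions.
#' @param page_size Maximum accessions per batch.
#' @return A `tr_live_query`: list with `query` (the GraphQL document),
#'   `pages` (list of accession batches) and `page_size`.
#' @export
#' @examples
#' plan <- build_live_query(sprintf("ENSG%011d", 1:250), page_size = 100)
#' length(plan$pages) # 3
build_live_query <- function(ensembl_ids, page_size = 100) {
  if (length(ensembl_ids) == 0) {
    abort("`ensembl_ids` must be nonempty.", class = "targetrank_usage_error")
  }
  if (!is.numeric(page_size) || page_size < 1) {
    abort("`page_size` must be a positive integer.",
          class = "targetrank_usage_error")
  }
  ensembl_ids <- as.character(ensembl_ids)
  page <- ceiling(seq_along(ensembl_ids) / page_size)
  structure(
    list(query = .live_query_fields,
         pages = unname(split(ensembl_ids, page)),
         page_size = as.integer(page_size)),
    class = "tr_live_query"
  )
}

#' @export
print.tr_live_query <- function(x, ...) {
  cat("<tr_live_query>", sum(lengths(x$pages)), "accession(s) in",
      length(x$pages), "batch(es) of <=", x$page_size, "\n")
  invisible(x)
}

# label/modality vocabulary used by the tractability buckets we flag; buckets
# outside this vocabulary still contribute to tractability_count, which is why
# the count can exceed the number of TRUE flags.
.tractability_label_map <- c(
  "Approved Drug" = "approved",
  "Advanced Clinical" = "advanced_trial",
  "Phase 1 Clinical" = "phase1"
)
.tractability_modality_map <- c(
  SMALL_MOLECULE = "sm", ANTIBODY = "ab", PROTAC = "pr", OTHER = "oc"
)

#' Convert a recorded GraphQL response into a snapshot
#'
#' Takes the JSON body of a target-annotation query response (a file path or
#' an already-parsed list) and converts it into a `tr_snapshot` holding the
#' same target records and drug links the live platform would supply. Pathway
#' membership is not part of the response, so the resulting snapshot has an
#' empty pathway table.
#'
#' Per-phase therapeutic counts are derived from the drug rows: each distinct
#' drug is counted once under its maximum clinical phase, and the approved
#' count is the number of distinct approved drugs. The tractability count is
#' the number of tractability buckets reported true, while the 12 stored flags
#' cover only the approved/advanced-trial/phase-1 buckets of the four
#' modalities.
#'
#' @param response Path to a JSON file, or a parsed list with a
#'   `data$targets` array.
#' @return A validated `tr_snapshot` with empty `pathways`.
#' @export
snapshot_from_response <- function(response) {
  if (is.character(response)) {
    response <- jsonlite::fromJSON(response, simplifyVector = FALSE)
  }
  targets_js <- response$data$targets
  if (is.null(targets_js)) {
    abort("Response has no `data.targets` array.",
          class = "targetrank_format_error")
  }

  parse_one <- function(t) {
    uniprot <- purrr::map_chr(
      purrr::keep(t$proteinIds, ~ identical(.x$source, "uniprot_swissprot")),
      "id"
    )
    tract <- t$tractability
    n_tract <- sum(map_lgl(tract, ~ isTRUE(.x$value)))
    flags <- stats::setNames(rep(FALSE, 12), .tractability_keys)
    for (b in tract) {
      stage <- .tractability_label_map[b$label]
      modality <- .tractability_modality_map[b$modality]
      if (!is.na(stage) && !is.na(modality)) {
        flags[paste(modality, stage, sep = "_")] <- isTRUE(b$value)
      }
    }
    loc <- if (length(t$subcellularLocations) > 0) {
      as.character(t$subcellularLocations[[1]]$location)
    } else "No data"

    rows <- t$knownDrugs$rows %||% list()
    drug_tbl <- if (length(rows) == 0) empty_drugs_tbl() else tibble(
      drug_id = map_chr(rows, ~ as.character(.x$drug$id)),
      drug_name = map_chr(rows, ~ as.character(.x$drug$name)),
      drug_type = map_chr(rows, ~ as.character(.x$drug$drugType)),
      action = map_chr(rows, ~ as.character(.x$mechanismOfAction)),
      max_phase = map_int(rows, ~ as.integer(.x$phase)),
      is_approved = map_lgl(rows, ~ isTRUE(.x$drug$isApproved)),
      target_ensembl_id = as.character(t$id)
    ) |>
      # one link per drug: keep its maximum phase
      dplyr::group_by(.data$drug_id) |>
      dplyr::arrange(dplyr::desc(.data$max_phase), .by_group = TRUE) |>
      dplyr::slice_head(n = 1) |>
      dplyr::ungroup()

    phase_counts <- vapply(1:4, function(p) {
      sum(drug_tbl$max_phase == p)
    }, integer(1))

    record <- tibble(
      ensembl_id = as.character(t$id),
      symbol = as.character(t$approvedSymbol),
      name = as.character(t$approvedName),
      uniprot_ids = list(uniprot),
      n_associated_diseases = as.integer(t$associatedDiseases$count %||% 0L),
      tractability_count = as.integer(n_tract),
      tractability_flags = list(flags),
      subcellular_location = loc,
      n_safety_liabilities = length(t$safetyLiabilities),
      n_unique_drugs = as.integer(t$knownDrugs$uniqueDrugs %||% nrow(drug_tbl)),
      n_approved = sum(drug_tbl$is_approved),
      n_phase1 = phase_counts[1], n_phase2 = phase_counts[2],
      n_phase3 = phase_counts[3], n_phase4 = phase_counts[4]
    )
    list(record = record, drugs = drug_tbl,
         gene = tibble(symbol = record$symbol, ensembl_id = record$ensembl_id,
                       entrez_id = NA_integer_, uniprot_ids = list(uniprot)))
  }

  parsed <- map(targets_js, parse_one)
  snapshot(
    pathways = empty_pathways_tbl(),
    gene_map = list_rbind(map(parsed, "gene")),
    targets = list_rbind(map(parsed, "record")),
    drugs = list_rbind(map(parsed, "drugs"))
  )
}
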