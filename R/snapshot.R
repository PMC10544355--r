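# Offline snapshot of target annotations: pathway membership, gene identifier
# maps, per-target attributes and drug links. The snapshot is the reference
# backend; a live GraphQL client can populate the same structure but nothing
# in the pipeline requires network access.

.tractability_modalities <- c("sm", "ab", "pr", "oc")
.tractability_stages <- c("approved", "advanced_trial", "phase1")
.tractability_keys <- as.character(t(outer(.tractability_modalities,
                                           .tractability_stages,
                                           paste, sep = "_")))

target_count_fields <- c(
  "n_associated_diseases", "tractability_count", "n_safety_liabilities",
  "n_unique_drugs", "n_approved", "n_phase1", "n_phase2", "n_phase3",
  "n_phase4"
)

empty_pathways_tbl <- function() {
  tibble(pathway_id = character(), name = character(),
         source_db = character(), members = list())
}

empty_gene_map_tbl <- function() {
  tibble(symbol = character(), ensembl_id = character(),
         entrez_id = integer(), uniprot_ids = list())
}

empty_targets_tbl <- function() {
  tibble(
    ensembl_id = character(), symbol = character(), name = character(),
    uniprot_ids = list(),
    n_associated_diseases = integer(), tractability_count = integer(),
    tractability_flags = list(), subcellular_location = character(),
    n_safety_liabilities = integer(), n_unique_drugs = integer(),
    n_approved = integer(), n_phase1 = integer(), n_phase2 = integer(),
    n_phase3 = integer(), n_phase4 = integer()
  )
}

empty_drugs_tbl <- function() {
  tibble(drug_id = character(), drug_name = character(),
         drug_type = character(), action = character(),
         max_phase = integer(), is_approved = logical(),
         target_ensembl_id = character())
}

#' Construct a target-annotation snapshot
#'
#' Bundles pathway membership, a gene identifier map, per-target attribute
#' records and drug links into a single validated object that the scoring
#' pipeline can query offline.
#'
#' @param pathways Tibble with columns `pathway_id`, `name`, `source_db` and a
#'   `members` list-column of Ensembl gene accessions.
#' @param gene_map Tibble with columns `symbol`, `ensembl_id`, `entrez_id` and
#'   a `uniprot_ids` list-column.
#' @param targets Tibble of target attribute records (one row per Ensembl id);
#'   see [target_records()] for the column inventory.
#' @param drugs Tibble of drug links with columns `drug_id`, `drug_name`,
#'   `drug_type`, `action`, `max_phase`, `is_approved`, `target_ensembl_id`.
#' @param schema_version Schema version string stored in the file.
#' @param validate Run [validate_snapshot()] before returning.
#'
#' @return An object of class `tr_snapshot`.
#' @export
snapshot <- function(pathways = empty_pathways_tbl(),
                     gene_map = empty_gene_map_tbl(),
                     targets = empty_targets_tbl(),
                     drugs = empty_drugs_tbl(),
                     schema_version = "1.0",
                     validate = TRUE) {
  out <- structure(
    list(schema_version = schema_version,
         pathways = as_tibble(pathways),
         gene_map = as_tibble(gene_map),
         targets = as_tibble(targets),
         drugs = as_tibble(drugs)),
    class = "tr_snapshot"
  )
  if (validate) validate_snapshot(out)
  out
}

#' @export
print.tr_snapshot <- function(x, ...) {
  cat("<tr_snapshot> schema", x$schema_version, "\n")
  cat("  pathways:", nrow(x$pathways),
      " targets:", nrow(x$targets),
      " gene map entries:", nrow(x$gene_map),
      " drug links:", nrow(x$drugs), "\n")
  invisible(x)
}

#' Validate a snapshot
#'
#' Checks field-level invariants (nonnegative counts, Ensembl accession
#' patterns, complete tractability flag sets, clinical phases in 0–4) and
#' referential integrity (every drug link points at a stored target; gene-map
#' Ensembl ids unique). The first few violations are reported with a
#' JSON-pointer-style path into the snapshot.
#'
#' @param snapshot A `tr_snapshot`.
#' @return The snapshot, invisibly, if valid; otherwise an error of class
#'   `targetrank_validation_error` or `targetrank_integrity_error`.
#' @export
validate_snapshot <- function(snapshot) {
  stopifnot(inherits(snapshot, "tr_snapshot"))
  problems <- character()
  add <- function(p) problems <<- c(problems, p)

  pw <- snapshot$pathways
  if (nrow(pw) > 0) {
    if (anyDuplicated(pw$pathway_id)) add("pathways: duplicate pathway_id")
    bad_members <- purrr::imap(pw$members, function(m, i) {
      m <- unlist(m)
      if (length(m) > 0 && !all(is_ensg(m))) {
        paste0("pathways/", pw$pathway_id[i], "/member_ensembl_ids")
      } else NULL
    })
    purrr::walk(purrr::compact(bad_members), add)
  }

  gm <- snapshot$gene_map
  if (nrow(gm) > 0) {
    if (anyDuplicated(gm$ensembl_id)) add("gene_map: duplicate ensembl_id")
    if (!all(is_ensg(gm$ensembl_id))) add("gene_map/ensembl_id: bad accession")
  }

  tg <- snapshot$targets
  if (nrow(tg) > 0) {
    if (anyDuplicated(tg$ensembl_id)) add("targets: duplicate ensembl_id")
    bad <- which(!is_ensg(tg$ensembl_id))
    if (length(bad) > 0) add(paste0("targets/", tg$ensembl_id[bad[1]],
                                    "/ensembl_id: bad accession"))
    for (f in target_count_fields) {
      bad <- which(is.na(tg[[f]]) | tg[[f]] < 0)
      if (length(bad) > 0) {
        add(paste0("targets/", tg$ensembl_id[bad[1]], "/", f,
                   ": negative or missing count"))
      }
    }
    flag_bad <- purrr::imap(tg$tractability_flags, function(fl, i) {
      if (is.null(fl)) return(NULL)
      fl <- unlist(fl)
      if (!setequal(names(fl), .tractability_keys) ||
          length(fl) != length(.tractability_keys)) {
        paste0("targets/", tg$ensembl_id[i], "/tractability_flags: ",
               "expected the 12 modality x stage keys")
      } else NULL
    })
    purrr::walk(purrr::compact(flag_bad), add)
  }

  if (length(problems) > 0) {
    abort(c("Snapshot failed validation:",
            stats::setNames(head(problems, 5), rep("x", min(5, length(problems))))),
          class = "targetrank_validation_error")
  }

  dg <- snapshot$drugs
  if (nrow(dg) > 0) {
    if (any(is.na(dg$max_phase) | dg$max_phase < 0 | dg$max_phase > 4)) {
      abort("drugs/max_phase: must lie in 0..4",
            class = "targetrank_validation_error")
    }
    dangling <- setdiff(dg$target_ensembl_id, tg$ensembl_id)
    if (length(dangling) > 0) {
      abort(paste0("Dangling drug link: target ", dangling[1],
                   " is not present in targets"),
            class = "targetrank_integrity_error")
    }
  }
  invisible(snapshot)
}

#' Read a snapshot from its JSON file
#'
#' @param path Path to a snapshot JSON file (see [write_snapshot()] for the
#'   layout).
#' @return A validated `tr_snapshot`.
#' @export
read_snapshot <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Snapshot file not found: ", path),
          class = "targetrank_io_error")
  }
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("schema_version", "pathways", "gene_map", "targets", "drugs")) {
    if (!field %in% names(js)) {
      abort(paste0("Snapshot is missing required field `/", field, "`"),
            class = "targetrank_validation_error")
    }
  }

  chr1 <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  int1 <- function(x) if (is.null(x)) NA_integer_ else as.integer(x)

  pathways <- if (length(js$pathways) == 0) empty_pathways_tbl() else tibble(
    pathway_id = names(js$pathways),
    name = map_chr(js$pathways, ~ chr1(.x$name)),
    source_db = map_chr(js$pathways, ~ chr1(.x$source_db)),
    members = map(js$pathways, ~ as.character(unlist(.x$member_ensembl_ids)))
  )

  gene_map <- if (length(js$gene_map) == 0) empty_gene_map_tbl() else tibble(
    symbol = map_chr(js$gene_map, ~ chr1(.x$symbol)),
    ensembl_id = map_chr(js$gene_map, ~ chr1(.x$ensembl_id)),
    entrez_id = map_int(js$gene_map, ~ int1(.x$entrez_id)),
    uniprot_ids = map(js$gene_map, ~ as.character(unlist(.x$uniprot_ids)))
  )

  targets <- if (length(js$targets) == 0) empty_targets_tbl() else tibble(
    ensembl_id = names(js$targets),
    symbol = map_chr(js$targets, ~ chr1(.x$symbol)),
    name = map_chr(js$targets, ~ chr1(.x$name)),
    uniprot_ids = map(js$targets, ~ as.character(unlist(.x$uniprot_ids))),
    n_associated_diseases = map_int(js$targets, ~ int1(.x$n_associated_diseases)),
    tractability_count = map_int(js$targets, ~ int1(.x$tractability_count)),
    tractability_flags = map(js$targets, function(t) {
      fl <- t$tractability_flags
      if (is.null(fl)) return(NULL)
      fl <- unlist(lapply(fl, isTRUE))
      # canonical modality x stage order when the full key set is present
      if (setequal(names(fl), .tractability_keys)) fl[.tractability_keys]
      else fl
    }),
    subcellular_location = map_chr(js$targets, ~ chr1(.x$subcellular_location)),
    n_safety_liabilities = map_int(js$targets, ~ int1(.x$n_safety_liabilities)),
    n_unique_drugs = map_int(js$targets, ~ int1(.x$n_unique_drugs)),
    n_approved = map_int(js$targets, ~ int1(.x$n_approved)),
    n_phase1 = map_int(js$targets, ~ int1(.x$n_phase1)),
    n_phase2 = map_int(js$targets, ~ int1(.x$n_phase2)),
    n_phase3 = map_int(js$targets, ~ int1(.x$n_phase3)),
    n_phase4 = map_int(js$targets, ~ int1(.x$n_phase4))
  )

  drugs <- if (length(js$drugs) == 0) empty_drugs_tbl() else tibble(
    drug_id = map_chr(js$drugs, ~ chr1(.x$drug_id)),
    drug_name = map_chr(js$drugs, ~ chr1(.x$drug_name)),
    drug_type = map_chr(js$drugs, ~ chr1(.x$drug_type)),
    action = map_chr(js$drugs, ~ chr1(.x$action)),
    max_phase = map_int(js$drugs, ~ int1(.x$max_phase)),
    is_approved = map_lgl(js$drugs, ~ isTRUE(.x$is_approved)),
    target_ensembl_id = map_chr(js$drugs, ~ chr1(.x$target_ensembl_id))
  )

  snapshot(pathways, gene_map, targets, drugs,
           schema_version = as.character(js$schema_version))
}

#' Write a snapshot to canonical JSON
#'
#' Serialization is canonical: object keys are sorted, pathways/targets are
#' keyed and ordered by accession, gene-map rows are ordered by Ensembl id and
#' drug links by (drug_id, target). Writing the same snapshot twice therefore
#' produces byte-identical files, and load -> save -> load round-trips exactly.
#'
#' @param snapshot A `tr_snapshot`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(snapshot, path) {
  stopifnot(inherits(snapshot, "tr_snapshot"))

  pw <- dplyr::arrange(snapshot$pathways, .data$pathway_id)
  pathways <- stats::setNames(
    pmap(list(pw$name, pw$source_db, pw$members), function(nm, db, mm) {
      list(member_ensembl_ids = as.list(unlist(mm)),
           name = nm, source_db = db)
    }),
    pw$pathway_id
  )

  gm <- dplyr::arrange(snapshot$gene_map, .data$ensembl_id)
  gene_map <- pmap(
    list(gm$symbol, gm$ensembl_id, gm$entrez_id, gm$uniprot_ids),
    function(sy, en, ez, up) {
      list(ensembl_id = en, entrez_id = ez, symbol = sy,
           uniprot_ids = as.list(unlist(up)))
    }
  )

  tg <- dplyr::arrange(snapshot$targets, .data$ensembl_id)
  targets <- stats::setNames(
    lapply(seq_len(nrow(tg)), function(i) {
      fl <- tg$tractability_flags[[i]]
      list(
        n_approved = tg$n_approved[i],
        n_associated_diseases = tg$n_associated_diseases[i],
        n_phase1 = tg$n_phase1[i], n_phase2 = tg$n_phase2[i],
        n_phase3 = tg$n_phase3[i], n_phase4 = tg$n_phase4[i],
        n_safety_liabilities = tg$n_safety_liabilities[i],
        n_unique_drugs = tg$n_unique_drugs[i],
        name = tg$name[i],
        subcellular_location = tg$subcellular_location[i],
        symbol = tg$symbol[i],
        tractability_count = tg$tractability_count[i],
        tractability_flags = if (is.null(fl)) NULL else
          as.list(fl[sort(names(fl))]),
        uniprot_ids = as.list(unlist(tg$uniprot_ids[[i]]))
      )
    }),
    tg$ensembl_id
  )

  dg <- dplyr::arrange(snapshot$drugs, .data$drug_id, .data$target_ensembl_id)
  drugs <- pmap(
    list(dg$drug_id, dg$drug_name, dg$drug_type, dg$action, dg$max_phase,
         dg$is_approved, dg$target_ensembl_id),
    function(id, nm, ty, ac, ph, ap, tgt) {
      list(action = ac, drug_id = id, drug_name = nm, drug_type = ty,
           is_approved = ap, max_phase = ph, target_ensembl_id = tgt)
    }
  )

  doc <- list(
    drugs = drugs,
    gene_map = gene_map,
    pathways = pathways,
    schema_version = snapshot$schema_version,
    targets = targets
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2, digits = NA,
                           null = "null", na = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Resolve pathway members from a snapshot
#'
#' For each input pathway, looks up its member gene products in the snapshot,
#' matching by `pathway_id` first and, failing that, by exact name. Pathways
#' absent from the snapshot contribute no rows and are reported in a single
#' warning: enrichment inputs routinely cover more pathways than any one
#' annotation source.
#'
#' @param snapshot A `tr_snapshot`.
#' @param pathways A pathway tibble (from [read_pathway_table()]) or a
#'   character vector of pathway ids/names.
#' @return A tibble with one row per (pathway, member): columns `pathway_id`,
#'   `name`, `ensembl_id`.
#' @export
pathway_members <- function(snapshot, pathways) {
  stopifnot(inherits(snapshot, "tr_snapshot"))
  if (is.character(pathways)) {
    pathways <- tibble(pathway_id = pathways, name = pathways)
  }
  pw <- snapshot$pathways

  idx <- match(pathways$pathway_id, pw$pathway_id)
  by_name <- match(pathways$name, pw$name)
  idx[is.na(idx)] <- by_name[is.na(idx)]

  missing <- which(is.na(idx))
  if (length(missing) > 0) {
    warn(paste0(length(missing), " pathway(s) not found in snapshot: ",
                paste(head(pathways$name[missing], 5), collapse = "; "),
                if (length(missing) > 5) " ..." else ""))
  }

  hit <- which(!is.na(idx))
  if (length(hit) == 0) {
    return(tibble(pathway_id = character(), name = character(),
                  ensembl_id = character()))
  }
  tibble(
    pathway_id = pw$pathway_id[idx[hit]],
    name = pathways$name[hit],
    members = pw$members[idx[hit]]
  ) |>
    tidyr::unnest_longer("members", values_to = "ensembl_id") |>
    dplyr::select("pathway_id", "name", "ensembl_id")
}

#' Map gene identifiers between id spaces
#'
#' Translates identifiers through the snapshot's gene map. The result is a
#' partial mapping: inputs with no translation are absent from the output (a
#' message reports how many). When a gene carries several UniProt accessions,
#' the lexicographically first is used as the representative.
#'
#' @param snapshot A `tr_snapshot`.
#' @param ids Character vector of identifiers.
#' @param from,to Id spaces: one of `"symbol"`, `"ensembl"`, `"entrez"`,
#'   `"uniprot"`.
#' @return A tibble with columns `input` and `output`, one row per mapped id.
#' @export
map_gene_ids <- function(snapshot, ids, from, to) {
  stopifnot(inherits(snapshot, "tr_snapshot"))
  spaces <- c("symbol", "ensembl", "entrez", "uniprot")
  if (!from %in% spaces || !to %in% spaces) {
    abort(paste0("Unknown id space; use one of: ",
                 paste(spaces, collapse = ", ")),
          class = "targetrank_usage_error")
  }
  ids <- as.character(ids)
  if (length(ids) == 0) return(tibble(input = character(), output = character()))

  gm <- snapshot$gene_map
  col_of <- function(space) {
    switch(space,
      symbol = gm$symbol,
      ensembl = gm$ensembl_id,
      entrez = as.character(gm$entrez_id),
      uniprot = map_chr(gm$uniprot_ids, function(u) {
        u <- unlist(u)
        if (length(u) == 0) NA_character_ else sort(u)[1]
      })
    )
  }
  if (from == "uniprot") {
    # match any accession in the list, not only the representative
    row_idx <- map_int(ids, function(id) {
      hit <- which(map_lgl(gm$uniprot_ids, ~ id %in% unlist(.x)))
      if (length(hit) == 0) NA_integer_ else hit[1]
    })
  } else {
    row_idx <- match(ids, col_of(from))
  }
  out_vals <- col_of(to)[row_idx]
  keep <- !is.na(row_idx) & !is.na(out_vals)
  if (any(!keep)) {
    inform(paste0(sum(!keep), " of ", length(ids),
                  " id(s) could not be mapped from ", from, " to ", to, "."))
  }
  tibble(input = ids[keep], output = out_vals[keep])
}

#' Fetch target attribute records
#'
#' @param snapshot A `tr_snapshot`.
#' @param ensembl_ids Character vector of Ensembl gene accessions.
#' @param missing `"error"` (default) to fail on an unknown accession, or
#'   `"skip"` to drop unknown accessions with a message — pathway membership
#'   routinely exceeds target-annotation coverage.
#' @return A tibble of target records in input order (columns `ensembl_id`,
#'   `symbol`, `name`, `uniprot_ids`, `n_associated_diseases`,
#'   `tractability_count`, `tractability_flags`, `subcellular_location`,
#'   `n_safety_liabilities`, `n_unique_drugs`, `n_approved`,
#'   `n_phase1`..`n_phase4`).
#' @export
target_records <- function(snapshot, ensembl_ids,
                           missing = c("error", "skip")) {
  stopifnot(inherits(snapshot, "tr_snapshot"))
  missing <- rlang::arg_match(missing)
  idx <- match(ensembl_ids, snapshot$targets$ensembl_id)
  if (anyNA(idx)) {
    absent <- ensembl_ids[is.na(idx)]
    if (missing == "error") {
      abort(paste0("Target not found in snapshot: ", absent[1]),
            class = "targetrank_not_found_error")
    }
    inform(paste0("Skipping ", length(absent),
                  " target(s) absent from the snapshot."))
    idx <- idx[!is.na(idx)]
  }
  snapshot$targets[idx, ]
}

#' Drug links for one target
#'
#' @param snapshot A `tr_snapshot`.
#' @param ensembl_id One Ensembl gene accession.
#' @return Tibble of drug links sorted by `drug_id`; zero rows when the target
#'   is unknown or undrugged.
#' @export
drugs_for_target <- function(snapshot, ensembl_id) {
  stopifnot(inherits(snapshot, "tr_snapshot"), length(ensembl_id) == 1)
  snapshot$drugs |>
    dplyr::filter(.data$target_ensembl_id == ensembl_id) |>
    dplyr::arrange(.data$drug_id)
}
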