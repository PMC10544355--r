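# Weighted linear scoring and ranking of targets, and the derived table of
# prioritized therapeutics. The score of a target is the inner product of its
# ten attributes with the weight scheme:
#
#   score = w_pathways * n_pathways + w_tractability * tractability_count
#         + w_approved * n_approved + w_safety * n_safety_liabilities
#         + w_unique_drugs * n_unique_drugs + w_diseases * n_associated_diseases
#         + w_phase1 * n_phase1 + w_phase2 * n_phase2
#         + w_phase3 * n_phase3 + w_phase4 * n_phase4

# attribute column backing each weight key
.score_attr_cols <- c(
  pathways = "n_pathways", tractability = "tractability_count",
  approved = "n_approved", safety = "n_safety_liabilities",
  unique_drugs = "n_unique_drugs", diseases = "n_associated_diseases",
  phase1 = "n_phase1", phase2 = "n_phase2", phase3 = "n_phase3",
  phase4 = "n_phase4"
)

#' Count significant pathways containing each gene
#'
#' For every gene appearing in at least one significant pathway's member list,
#' counts the number of distinct significant pathways containing it. This
#' per-run count is the `pathways` attribute of the score: it reflects the
#' input enrichment result, not a global pathway-database count.
#'
#' @param pathways Significant pathways (tibble from [filter_significant()]).
#' @param snapshot A `tr_snapshot` supplying membership.
#' @return Tibble with columns `ensembl_id`, `n_pathways`; genes in no
#'   significant pathway are absent.
#' @export
count_pathway_memberships <- function(pathways, snapshot) {
  members <- pathway_members(snapshot, pathways)
  if (nrow(members) == 0) {
    return(tibble(ensembl_id = character(), n_pathways = integer()))
  }
  members |>
    dplyr::distinct(.data$pathway_id, .data$ensembl_id) |>
    dplyr::count(.data$ensembl_id, name = "n_pathways")
}

#' Score targets with a weight scheme
#'
#' Adds a `score` column: the weighted linear combination of the ten scored
#' attributes. The input must carry the target attribute columns (see
#' [target_records()]) plus `n_pathways` (see [count_pathway_memberships()]);
#' a missing `n_pathways` column is treated as zero for every row.
#'
#' @param targets Tibble of target records with an `n_pathways` column.
#' @param weights A `tr_weights`, preset name, or YAML path.
#' @return `targets` with a `score` column appended.
#' @export
score_targets <- function(targets, weights = "default") {
  w <- as_weights(weights)
  if (!"n_pathways" %in% names(targets)) {
    targets$n_pathways <- 0L
  }
  missing_cols <- setdiff(unname(.score_attr_cols), names(targets))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing attribute column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "targetrank_usage_error")
  }
  mat <- as.matrix(targets[, unname(.score_attr_cols)])
  storage.mode(mat) <- "double"
  targets$score <- as.numeric(mat %*% as.numeric(w[names(.score_attr_cols)]))
  targets
}

#' Score a single target record
#'
#' Convenience scalar form of [score_targets()].
#'
#' @param record A one-row target tibble (or named list) with the attribute
#'   fields of [target_records()].
#' @param n_pathways Number of significant pathways containing the target.
#' @param weights A `tr_weights`, preset name, or YAML path.
#' @return The numeric score.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   tractability_count = 5L, n_approved = 4L, n_safety_liabilities = 0L,
#'   n_unique_drugs = 11L, n_associated_diseases = 2188L,
#'   n_phase1 = 0L, n_phase2 = 0L, n_phase3 = 1L, n_phase4 = 4L
#' )
#' score_target(rec, n_pathways = 2) # 2219.5
score_target <- function(record, n_pathways, weights = "default") {
  record <- as_tibble(as.list(record)[setdiff(names(record), "n_pathways")])
  record$n_pathways <- as.numeric(n_pathways)
  score_targets(record, weights)$score
}

#' Rank targets by weighted score
#'
#' Scores and sorts targets. Ties on the score are broken by approved-drug
#' count (descending), then unique-drug count (descending), then symbol
#' (ascending), so ranking is a deterministic function of the set of inputs —
#' permuting the input rows cannot change the ranked order.
#'
#' @inheritParams score_targets
#' @param pathway_counts Optional tibble from [count_pathway_memberships()];
#'   joined on `ensembl_id` when `targets` lacks an `n_pathways` column
#'   (targets in no significant pathway get 0).
#' @return A `tr_ranking` tibble: the input columns plus `n_pathways`, `score`
#'   and `rank` (1 = best), sorted by rank. The weight scheme is stored in the
#'   `weights` attribute.
#' @export
rank_targets <- function(targets, weights = "default", pathway_counts = NULL) {
  w <- as_weights(weights)
  if (anyDuplicated(targets$ensembl_id)) {
    abort("Duplicate ensembl_id in `targets`.",
          class = "targetrank_usage_error")
  }
  if (!"n_pathways" %in% names(targets) && !is.null(pathway_counts)) {
    targets <- dplyr::left_join(targets, pathway_counts, by = "ensembl_id")
    targets$n_pathways[is.na(targets$n_pathways)] <- 0L
  }
  scored <- score_targets(targets, w) |>
    dplyr::arrange(desc(.data$score), desc(.data$n_approved),
                   desc(.data$n_unique_drugs), .data$symbol) |>
    dplyr::mutate(rank = dplyr::row_number())
  structure(scored, class = c("tr_ranking", class(scored)),
            weights = w)
}

#' Derive the prioritized-therapeutics table
#'
#' One row per unique drug across the ranked targets' drug links. Each drug
#' inherits the maximum score among its linked scored targets (a drug is as
#' promising as its best target) and records that target's symbol. Rows are
#' sorted by inherited score (descending), then `drug_id`.
#'
#' @param ranked A `tr_ranking` from [rank_targets()].
#' @param snapshot The `tr_snapshot` holding drug links.
#' @return Tibble with columns `drug_id`, `drug_name`, `drug_type`, `action`,
#'   `max_phase`, `is_approved`, `score`, `target_symbol`, `target_rank`.
#' @export
build_drug_table <- function(ranked, snapshot) {
  stopifnot(inherits(snapshot, "tr_snapshot"))
  scores <- tibble(
    target_ensembl_id = ranked$ensembl_id,
    target_symbol = ranked$symbol,
    score = ranked$score,
    target_rank = ranked$rank
  )
  linked <- dplyr::inner_join(snapshot$drugs, scores,
                              by = "target_ensembl_id")
  if (nrow(linked) == 0) {
    return(tibble(drug_id = character(), drug_name = character(),
                  drug_type = character(), action = character(),
                  max_phase = integer(), is_approved = logical(),
                  score = numeric(), target_symbol = character(),
                  target_rank = integer()))
  }
  linked |>
    dplyr::group_by(.data$drug_id) |>
    dplyr::arrange(.data$target_rank, .by_group = TRUE) |>
    dplyr::slice_head(n = 1) |>
    dplyr::ungroup() |>
    dplyr::select("drug_id", "drug_name", "drug_type", "action",
                  "max_phase", "is_approved", "score", "target_symbol",
                  "target_rank") |>
    dplyr::arrange(desc(.data$score), .data$drug_id)
}

#' @rdname rank_targets
#' @param x A `tr_ranking`.
#' @param ... Unused.
#' @method glance tr_ranking
#' @export
glance.tr_ranking <- function(x, ...) {
  w <- attr(x, "weights")
  tibble(
    n_targets = nrow(x),
    top_symbol = if (nrow(x) > 0) x$symbol[1] else NA_character_,
    top_score = if (nrow(x) > 0) x$score[1] else NA_real_,
    preset = attr(w, "preset") %||% "custom",
    weight_hash = scheme_hash(w)
  )
}
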