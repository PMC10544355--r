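#' Read a SPIA-style pathway enrichment table
#'
#' Parses the tab-separated output of a SPIA run (or any table with compatible
#' columns) into a tibble of pathway records, one row per input row, in file
#' order. Only the pathway name and an adjusted p-value column are required;
#' everything else is optional and filled with `NA`/`"unknown"`/`"other"` when
#' absent.
#'
#' The default column mapping follows standard SPIA output: `Name` -> `name`,
#' `ID` -> `pathway_id`, `pSize` -> `n_proteins`, `NDE` -> `n_degs`, the first
#' of `pGFWER`, `pGFdr`, `pG` -> `p_adjusted`, `Status` -> `status`. A source
#' database column (`SourceDB`, `Database` or `source_db`) is picked up when
#' present, since upstream runs may merge several pathway databases.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Optional named character vector overriding the default
#'   mapping; names are canonical fields (`name`, `pathway_id`, `n_proteins`,
#'   `n_degs`, `p_adjusted`, `status`, `source_db`), values are column names
#'   in the file.
#' @param delim Field delimiter, tab by default.
#'
#' @return A tibble with columns `name`, `pathway_id`, `source_db`,
#'   `n_proteins`, `n_degs`, `p_adjusted`, `status`.
#' @seealso [read_enrichr_pathways()], [filter_significant()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("Name\tID\tpSize\tNDE\tpGFdr\tStatus",
#'              "Cell cycle\t04110\t124\t80\t0.001\tActivated"), tf)
#' read_spia_pathways(tf)
read_spia_pathways <- function(path, column_map = NULL, delim = "\t") {
  raw <- read_raw_table(path, delim)

  map <- c(
    name = "Name", pathway_id = "ID", n_proteins = "pSize", n_degs = "NDE",
    p_adjusted = NA_character_, status = "Status", source_db = NA_character_
  )
  # p-value column: most conservative adjusted column available wins
  for (cand in c("pGFWER", "pGFdr", "pG")) {
    if (cand %in% names(raw)) {
      map[["p_adjusted"]] <- cand
      break
    }
  }
  for (cand in c("SourceDB", "Database", "source_db")) {
    if (cand %in% names(raw)) {
      map[["source_db"]] <- cand
      break
    }
  }
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), names(map))
    if (length(bad) > 0) {
      abort(paste0("Unknown field(s) in `column_map`: ",
                   paste(bad, collapse = ", ")),
            class = "targetrank_usage_error")
    }
    map[names(column_map)] <- column_map
  }

  for (req in c("name", "p_adjusted")) {
    col <- map[[req]]
    if (is.na(col) || !col %in% names(raw)) {
      abort(
        paste0("Required column for `", req, "` not found in ", path,
               if (!is.na(col)) paste0(" (looked for `", col, "`)") else ""),
        class = "targetrank_format_error"
      )
    }
  }

  take <- function(field) {
    col <- map[[field]]
    if (!is.na(col) && col %in% names(raw)) raw[[col]] else NULL
  }

  n <- nrow(raw)
  out <- tibble(
    name       = as.character(take("name") %||% character(n)),
    pathway_id = as.character(take("pathway_id") %||% rep(NA_character_, n)),
    source_db  = normalize_source_db(take("source_db") %||%
                                       rep("other", n)),
    n_proteins = parse_count_column(take("n_proteins"), n),
    n_degs     = parse_count_column(take("n_degs"), n),
    p_adjusted = parse_p_column(take("p_adjusted"), path),
    status     = normalize_status(take("status") %||% rep("unknown", n))
  )
  validate_pathway_tbl(out)
}

#' Read an enrichr-style enrichment table
#'
#' Parses an enrichr export (columns `Term`, `Overlap`, `Adjusted P-value`,
#' optionally `Genes`). The term becomes the pathway name; the overlap
#' fraction `k/m` supplies the DEG count (numerator) and pathway size
#' (denominator); pathway status is always `"unknown"` since enrichr is an
#' over-representation test with no directionality. The source database is
#' inferred from an accession suffix in the term (`R-HSA-…` -> Reactome,
#' `hsa…` -> KEGG, `WP…` -> other) when one is present.
#'
#' @inheritParams read_spia_pathways
#' @return A tibble with the same columns as [read_spia_pathways()].
#' @export
read_enrichr_pathways <- function(path, delim = "\t") {
  raw <- read_raw_table(path, delim)

  term_col <- intersect(c("Term", "term"), names(raw))[1]
  p_col <- intersect(c("Adjusted P-value", "Adjusted.P.value", "Adj.P",
                       "adjusted_p_value"), names(raw))[1]
  overlap_col <- intersect(c("Overlap", "overlap"), names(raw))[1]
  if (is.na(term_col)) {
    abort(paste0("Required column `Term` not found in ", path),
          class = "targetrank_format_error")
  }
  if (is.na(p_col)) {
    abort(paste0("Required adjusted p-value column not found in ", path),
          class = "targetrank_format_error")
  }

  n <- nrow(raw)
  term <- as.character(raw[[term_col]])

  n_degs <- rep(NA_integer_, n)
  n_proteins <- rep(NA_integer_, n)
  if (!is.na(overlap_col) && n > 0) {
    parts <- strsplit(as.character(raw[[overlap_col]]), "/", fixed = TRUE)
    ok <- lengths(parts) == 2
    nums <- suppressWarnings(
      vapply(parts, function(p) as.integer(p[1]), integer(1))
    )
    dens <- suppressWarnings(
      vapply(parts, function(p) if (length(p) >= 2) as.integer(p[2]) else NA_integer_,
             integer(1))
    )
    bad <- which(!ok | is.na(nums) | is.na(dens))
    if (length(bad) > 0) {
      abort(paste0("Malformed `Overlap` field in ", path, " at data row ",
                   bad[1], ": ", as.character(raw[[overlap_col]])[bad[1]]),
            class = "targetrank_format_error")
    }
    n_degs <- nums
    n_proteins <- dens
  }

  # a trailing accession token betrays the source database for some libraries
  acc_re <- "(R-HSA-[0-9]+|hsa[0-9]{5}|WP[0-9]+|PW[0-9]+)$"
  pathway_id <- rep(NA_character_, n)
  has_acc <- grepl(acc_re, term)
  pathway_id[has_acc] <- regmatches(term, regexpr(acc_re, term))

  source_db <- rep("other", n)
  source_db[grepl("^R-HSA-", pathway_id)] <- "Reactome"
  source_db[grepl("^hsa", pathway_id)] <- "KEGG"

  out <- tibble(
    name       = term,
    pathway_id = pathway_id,
    source_db  = source_db,
    n_proteins = n_proteins,
    n_degs     = n_degs,
    p_adjusted = parse_p_column(raw[[p_col]], path),
    status     = rep("unknown", n)
  )
  validate_pathway_tbl(out)
}

#' Read a pathway enrichment table in either supported dialect
#'
#' @inheritParams read_spia_pathways
#' @param dialect `"spia"` or `"enrichr"`.
#' @return A pathway tibble; see [read_spia_pathways()].
#' @export
read_pathway_table <- function(path, dialect = c("spia", "enrichr"),
                               column_map = NULL, delim = "\t") {
  dialect <- rlang::arg_match(dialect)
  switch(dialect,
    spia    = read_spia_pathways(path, column_map = column_map, delim = delim),
    enrichr = read_enrichr_pathways(path, delim = delim)
  )
}

#' Keep significant pathways
#'
#' Retains pathways whose adjusted p-value is strictly below `alpha`,
#' preserving input order. Input p-values are expected to be already corrected
#' for multiple testing by the upstream tool; no further correction is
#' applied.
#'
#' @param pathways A pathway tibble from [read_pathway_table()].
#' @param alpha Significance threshold in (0, 1]; rows with
#'   `p_adjusted < alpha` are kept.
#' @return The filtered tibble.
#' @export
filter_significant <- function(pathways, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha > 1) {
    abort("`alpha` must be a single number in (0, 1].",
          class = "targetrank_usage_error")
  }
  dplyr::filter(pathways, !is.na(.data$p_adjusted), .data$p_adjusted < alpha)
}

# ---- internals --------------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

read_raw_table <- function(path, delim) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "targetrank_io_error")
  }
  readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), trim_ws = TRUE, comment = "#", progress = FALSE,
    show_col_types = FALSE
  )
}

parse_p_column <- function(x, path) {
  if (is.null(x)) return(numeric(0))
  p <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(p) & !is.na(x))
  if (length(bad) > 0) {
    abort(paste0("Unparseable p-value in ", path, " at data row ", bad[1],
                 ": '", x[bad[1]], "'"),
          class = "targetrank_format_error")
  }
  p
}

parse_count_column <- function(x, n) {
  if (is.null(x)) return(rep(NA_integer_, n))
  suppressWarnings(as.integer(round(as.numeric(x))))
}

validate_pathway_tbl <- function(x) {
  if (nrow(x) == 0) return(x)
  if (any(!is.na(x$p_adjusted) & (x$p_adjusted < 0 | x$p_adjusted > 1))) {
    abort("Adjusted p-values must lie in [0, 1].",
          class = "targetrank_format_error")
  }
  if (any(is.na(x$name) | x$name == "")) {
    abort("Pathway names must be nonempty.", class = "targetrank_format_error")
  }
  both <- !is.na(x$n_degs) & !is.na(x$n_proteins)
  if (any(both & x$n_degs > x$n_proteins)) {
    abort("DEG count exceeds pathway protein count.",
          class = "targetrank_format_error")
  }
  x
}
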