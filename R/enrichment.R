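# Over-representation of a curated "gold" target set among the top-k ranked
# targets, assessed with the hypergeometric upper tail. The universe is the
# run's own prediction list (all scored targets), so the test asks: are gold
# targets concentrated near the top of *this* ranking?

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` where `X` is the number of gold items in `n` draws without
#' replacement from a universe of `N` items containing `K` gold. Computed via
#' [stats::phyper()], which works in log space and is numerically stable for
#' large arguments. `P(X >= 0)` is exactly 1.
#'
#' @param k Observed successes (nonnegative, at most `min(n, K)` achievable;
#'   any `k <= n` is accepted).
#' @param n Number of draws (top-k size).
#' @param K Gold items in the universe.
#' @param N Universe size.
#' @return Upper-tail probability; vectorized over its arguments.
#' @export
#' @examples
#' hypergeom_tail(2, 5, 3, 10) # 0.5
hypergeom_tail <- function(k, n, K, N) {
  args <- vctrs_recycle(k = k, n = n, K = K, N = N)
  with(args, {
    if (any(N < 1 | K < 0 | K > N | n < 1 | n > N | k < 0 | k > n)) {
      abort("Require 0 <= k <= n <= N and 0 <= K <= N.",
            class = "targetrank_usage_error")
    }
    ifelse(k == 0, 1, phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
}

# minimal common-length recycling for scalar-or-vector args
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, function(a) {
    if (length(a) == n) a
    else if (length(a) == 1) rep(a, n)
    else abort("Arguments must have length 1 or a common length.",
               class = "targetrank_usage_error")
  })
}

#' Test gold-target enrichment among the top-k ranked targets
#'
#' Counts how many gold symbols land in the top `k` of the ranking and returns
#' the hypergeometric upper-tail p-value. The universe is the full set of
#' scored targets from the run; `K` is the number of gold symbols present in
#' that universe (gold symbols outside it cannot be drawn and are ignored).
#' Symbols match case-insensitively.
#'
#' @param ranked A `tr_ranking` from [rank_targets()].
#' @param gold Character vector of gold gene symbols (or a file path readable
#'   by [read_gold_set()]).
#' @param k Top-list size (default 15).
#' @return A `tr_enrichment`: list with `k_hits`, `n_drawn`, `K_gold`,
#'   `N_universe`, `p_value`, and the matched symbols `hits`.
#' @export
evaluate_topk <- function(ranked, gold, k = 15) {
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1) {
    abort("`k` must be a positive integer.", class = "targetrank_usage_error")
  }
  k <- as.integer(k)
  N <- nrow(ranked)
  if (k > N) {
    abort(paste0("`k` (", k, ") exceeds the number of scored targets (",
                 N, ")."), class = "targetrank_usage_error")
  }
  if (is.character(gold) && length(gold) == 1 && file.exists(gold)) {
    gold <- read_gold_set(gold)
  }
  gold_lc <- unique(tolower(gold))
  universe <- tolower(ranked$symbol)
  top <- universe[ranked$rank <= k]

  K <- sum(universe %in% gold_lc)
  hits <- top[top %in% gold_lc]
  p <- if (K == 0) 1 else hypergeom_tail(length(hits), k, K, N)

  structure(
    list(k_hits = length(hits), n_drawn = k, K_gold = K, N_universe = N,
         p_value = p,
         hits = ranked$symbol[ranked$rank <= k][top %in% gold_lc]),
    class = "tr_enrichment"
  )
}

#' @export
print.tr_enrichment <- function(x, ...) {
  cat("<tr_enrichment> ", x$k_hits, "/", x$n_drawn,
      " gold targets in the top list (", x$K_gold, " gold in a universe of ",
      x$N_universe, ")\n", sep = "")
  cat("  upper-tail p-value:", format(x$p_value, digits = 4), "\n")
  if (x$k_hits > 0) cat("  hits:", paste(x$hits, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname evaluate_topk
#' @param x A `tr_enrichment`.
#' @param ... Unused.
#' @method tidy tr_enrichment
#' @export
tidy.tr_enrichment <- function(x, ...) {
  tibble(
    k_hits = x$k_hits, n_drawn = x$n_drawn, K_gold = x$K_gold,
    N_universe = x$N_universe, p_value = x$p_value
  )
}

#' @rdname evaluate_topk
#' @method glance tr_enrichment
#' @export
glance.tr_enrichment <- function(x, ...) tidy(x)

#' Read a gold target set
#'
#' Plain text, one gene symbol per line; blank lines and `#` comments are
#' ignored.
#'
#' @param path File path.
#' @return Character vector of symbols.
#' @export
read_gold_set <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Gold set file not found: ", path),
          class = "targetrank_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Write a gold target set
#'
#' @param symbols Character vector of gene symbols.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gold_set <- function(symbols, path) {
  writeLines(c("# gold target set (one symbol per line)", symbols), path)
  invisible(path)
}
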