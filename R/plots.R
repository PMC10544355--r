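# ggplot2 views of the two result types.

#' Plot a target ranking
#'
#' Lollipop chart of the weighted scores of the top-ranked targets, best at
#' the top.
#'
#' @param object A `tr_ranking` from [rank_targets()].
#' @param top_n How many targets to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tr_ranking
#' @export
autoplot.tr_ranking <- function(object, top_n = 20, ...) {
  df <- as_tibble(object) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::mutate(symbol = factor(.data$symbol, levels = rev(.data$symbol)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$symbol)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$score,
                                       yend = .data$symbol),
                          color = "grey60") +
    ggplot2::geom_point(size = 2.4, color = "#2166ac") +
    ggplot2::labs(x = "Weighted score", y = NULL,
                  title = paste0("Top ", nrow(df), " prioritized targets")) +
    ggplot2::theme_minimal()
}

#' Plot a top-k enrichment result
#'
#' Shows the hypergeometric null distribution of gold hits in the top list
#' with the observed hit count marked; the shaded bars are the upper tail that
#' the p-value sums.
#'
#' @param object A `tr_enrichment` from [evaluate_topk()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tr_enrichment
#' @export
autoplot.tr_enrichment <- function(object, ...) {
  kk <- 0:min(object$n_drawn, object$K_gold)
  pmf <- stats::dhyper(kk, object$K_gold,
                       object$N_universe - object$K_gold, object$n_drawn)
  df <- tibble(k = kk, p = pmf, tail = kk >= object$k_hits)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$p,
                                   fill = .data$tail)) +
    ggplot2::geom_col(width = 0.85, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey75",
                                          `TRUE` = "#b2182b")) +
    ggplot2::geom_vline(xintercept = object$k_hits, linetype = 2) +
    ggplot2::labs(
      x = "Gold targets in top list", y = "Null probability",
      title = sprintf("Observed %d/%d gold hits, p = %.3g",
                      object$k_hits, object$n_drawn, object$p_value)
    ) +
    ggplot2::theme_minimal()
}
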