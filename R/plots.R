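#' Reactivity bar chart
#'
#' Unique cross-linked peptide counts per cross-link-site residue, the
#' standard summary of nucleophile reactivity for this chemistry.
#'
#' @param object A `gecx_reactivity` tibble from [count_by_residue()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gecx_reactivity
#' @export
autoplot.gecx_reactivity <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$residue <- factor(df$residue, levels = df$residue[order(-df$n)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue, y = .data$n,
                                   fill = .data$residue == "C")) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#D55E00",
                                          `FALSE` = "grey40")) +
    ggplot2::labs(x = "cross-link site residue",
                  y = "unique cross-linked peptides") +
    ggplot2::theme_minimal()
}

#' Score distributions of target and decoy PSMs
#'
#' @param psms PSM tibble with `score` and `is_decoy`.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(psms, bins = 40) {
  ggplot2::ggplot(psms, ggplot2::aes(x = .data$score, fill = .data$is_decoy)) +
    ggplot2::geom_histogram(bins = bins, position = "identity", alpha = 0.6) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "#0072B2",
                                          `TRUE` = "#999999"),
                               name = "decoy") +
    ggplot2::labs(x = "PSM score (-log10 binomial tail, both chains)",
                  y = "PSMs") +
    ggplot2::theme_minimal()
}

#' Motif log-odds heatmap
#'
#' Position-specific log2 odds of each residue around the cross-link site
#' (position 0); elevated cells mark sequence preferences such as the
#' CXXC-type context of zinc-finger binders.
#'
#' @param object A `gecx_motif_windows` object from [extract_windows()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gecx_motif_windows
#' @export
autoplot.gecx_motif_windows <- function(object, ...) {
  lo <- object$log_odds
  df <- tibble::as_tibble(as.table(lo), .name_repair = "minimal")
  names(df) <- c("position", "residue", "log_odds")
  df$position <- as.integer(as.integer(factor(df$position,
                                              levels = unique(df$position)))) -
    object$flank - 1L
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$residue,
                                   fill = .data$log_odds)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#0072B2", mid = "white",
                                  high = "#D55E00", name = "log2 odds") +
    ggplot2::labs(x = "offset from cross-link site", y = "residue") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
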