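# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_tile
#'   facet_grid facet_wrap labs scale_fill_gradient2 theme_minimal
NULL

#' Plot dominance group percentages
#'
#' Bar chart of collapsed-group percentages per stage and omic, the usual
#' way dominance tables are summarised.
#'
#' @param object A `dominance_summary` tibble ([dominance_summary()]).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.dominance_summary <- function(object, ...) {
  ggplot(object, aes(x = .data$group, y = .data$percent, fill = .data$group)) +
    geom_col() +
    facet_grid(omic ~ stage) +
    labs(x = NULL, y = "% of classified features", fill = "group") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.dominance_summary
#' @param calls A `dominance_calls` tibble.
#' @export
plot_dominance_summary <- function(calls, ...) {
  autoplot(dominance_summary(calls), ...)
}

#' Volcano plot for differential results
#'
#' @param object A `de_results` tibble ([call_de()]).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.de_results <- function(object, ...) {
  ggplot(object, aes(x = .data$log2fc, y = -log10(pmax(.data$padj, 1e-300)),
                     colour = .data$is_de)) +
    geom_point(size = 0.5, alpha = 0.6) +
    facet_grid(stage ~ contrast) +
    labs(x = "log2 fold change", y = "-log10 adjusted p",
         colour = "padj < 0.05") +
    theme_minimal()
}

#' Methylation difference along chromosomes for a DMR set
#'
#' @param object A `dmr_set` tibble ([call_dmrs()]).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.dmr_set <- function(object, ...) {
  ggplot(object, aes(x = (.data$start + .data$end) / 2e6, y = .data$delta,
                     colour = .data$direction)) +
    geom_point(size = 0.8) +
    facet_grid(context ~ chrom, scales = "free_x") +
    labs(x = "position (Mbp)", y = "methylation difference",
         colour = NULL) +
    theme_minimal()
}

#' Segment bias Z-score heatmap
#'
#' @param object A `segment_set` tibble ([find_segments()]).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.segment_set <- function(object, ...) {
  object$window <- sprintf("%s:%0.1fM", object$chrom, object$start / 1e6)
  ggplot(object, aes(x = .data$window,
                     y = interaction(.data$genotype, .data$stage),
                     fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    labs(x = "500-kbp window", y = NULL, fill = "Z") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
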