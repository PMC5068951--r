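# ggplot2 displays for the main result types.

#' @describeIn score_screen Volcano-style display of one screen: GI score
#'   against robust Z, coloured by FDR threshold.
#' @param object A `gi_screen`.
#' @param fdr_cutoff Threshold used for colouring (default 0.1).
#' @param ... Ignored.
#' @export
autoplot.gi_screen <- function(object, fdr_cutoff = 0.1, ...) {
  df <- as_tibble(object) |> filter(!is.na(.data$gi))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gi, y = .data$z)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$fdr <= fdr_cutoff),
                        alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
      name = sprintf("FDR <= %.2g", fdr_cutoff)
    ) +
    ggplot2::labs(x = "GI score", y = "robust Z",
                  title = attr(object, "screen_id")) +
    ggplot2::theme_minimal()
}

#' @describeIn enrich_table Dot plot of fold enrichment vs term, sized by hit
#'   count and coloured by q-value.
#' @param object An `enrichment_result`.
#' @param top Number of top terms to show.
#' @param ... Ignored.
#' @export
autoplot.enrichment_result <- function(object, top = 20, ...) {
  df <- head(as_tibble(object), top)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold, y = .data$term)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$k, colour = .data$q_value)) +
    ggplot2::scale_colour_gradient(low = "firebrick", high = "grey70") +
    ggplot2::labs(x = "fold enrichment", y = NULL,
                  size = "hits", colour = "q") +
    ggplot2::theme_minimal()
}

#' Plot OD600 growth curves by dose
#'
#' @param curves Long tibble with columns `dose`, `time_hr`, `od`.
#' @param log_od Plot OD on a log2 axis (default TRUE), making the
#'   exponential phase a straight line.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(curves, log_od = TRUE) {
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$time_hr, y = .data$od,
                                    colour = factor(.data$dose))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (hr)", y = "OD600", colour = "dose") +
    ggplot2::theme_minimal()
  if (log_od) p <- p + ggplot2::scale_y_continuous(trans = "log2")
  p
}

#' Plot a clustered GI-profile heat map
#'
#' @param gi_matrix Tibble with `mutant_id` + screen columns.
#' @param dendro Optional `barseq_dendrogram`; rows are reordered by its leaf
#'   order when supplied.
#' @return A ggplot object (tile heat map).
#' @export
plot_gi_heatmap <- function(gi_matrix, dendro = NULL) {
  if (!is.null(dendro)) gi_matrix <- ordered_gi_matrix(gi_matrix, dendro)
  long <- tidyr::pivot_longer(gi_matrix, -"mutant_id",
                              names_to = "screen", values_to = "gi")
  long$mutant_id <- factor(long$mutant_id, levels = rev(gi_matrix$mutant_id))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$screen, y = .data$mutant_id,
                                     fill = .data$gi)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  na.value = "grey85") +
    ggplot2::labs(x = NULL, y = NULL, fill = "GI") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
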