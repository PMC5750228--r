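# ggplot2 displays for the main result types.

#' Heatmap of row-normalized metabolite dynamics
#'
#' Tiles of per-(stage, time) normalized mean peak areas, rows ordered by
#' the clustering dendrogram when cluster labels are supplied.
#'
#' @param normalized Output of [row_normalize()].
#' @param clusters Optional output of [cluster_metabolites()].
#' @return A ggplot.
#' @export
plot_metabolite_heatmap <- function(normalized, clusters = NULL) {
  assert_columns(normalized, c("metabolite_id", "stage", "time", "value"))
  dat <- normalized
  if (!is.null(clusters)) {
    ord <- attr(clusters, "order") %||% clusters$metabolite_id
    dat <- dat %>%
      dplyr::left_join(clusters, by = "metabolite_id") %>%
      dplyr::mutate(metabolite_id = factor(.data$metabolite_id, levels = ord))
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$time),
                                         y = .data$metabolite_id,
                                         fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$stage)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey85") +
    ggplot2::labs(x = "hours after wetting", y = NULL,
                  fill = "row-normalized\nmean peak area")
  if (!is.null(clusters)) {
    p <- p + ggplot2::facet_grid(rows = ggplot2::vars(.data$cluster),
                                 cols = ggplot2::vars(.data$stage),
                                 scales = "free_y", space = "free_y")
  }
  p
}

#' @describeIn pca_ordinate Scatter of the first two PCs, colored by time,
#'   shaped by stage.
#' @param object A `"wetup_pca"`.
#' @param ... Unused.
#' @export
autoplot.wetup_pca <- function(object, ...) {
  ev <- object$explained_variance
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$time, shape = .data$stage)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ev[2]),
      colour = "hours", shape = "stage"
    )
}

#' @describeIn evaluate_concordance Bar chart of concordant vs discordant
#'   relationships per predicted class.
#' @param object An `"exo_concordance"`.
#' @param ... Unused.
#' @export
autoplot.exo_concordance <- function(object, ...) {
  dat <- tidy(object) %>%
    dplyr::filter(.data$evaluable) %>%
    dplyr::count(.data$exo_class, .data$concordant)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$exo_class, y = .data$n,
                                    fill = .data$concordant)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "isolate-based prediction", y = "relationships",
                  fill = "expected\ndirectionality")
}

#' Bipartite foodweb plot
#'
#' Taxa on the left, metabolites on the right; solid segments are
#' concordant edges, dotted discordant, width proportional to `|rho|`,
#' starred edges (FDR-significant) drawn opaque.
#'
#' @param edges Output of [build_foodweb()].
#' @return A ggplot.
#' @export
plot_foodweb <- function(edges) {
  assert_columns(edges, c("taxon_id", "metabolite_id", "predicted", "style",
                          "weight", "starred"))
  taxa <- sort(unique(edges$taxon_id))
  mets <- sort(unique(edges$metabolite_id))
  dat <- edges %>%
    dplyr::mutate(
      y_taxon = match(.data$taxon_id, taxa) * (length(mets) / max(1, length(taxa))),
      y_met = match(.data$metabolite_id, mets)
    )
  ggplot2::ggplot(dat) +
    ggplot2::geom_segment(
      ggplot2::aes(x = 0, xend = 1, y = .data$y_taxon, yend = .data$y_met,
                   colour = .data$predicted, linetype = .data$style,
                   linewidth = .data$weight, alpha = .data$starred)
    ) +
    ggplot2::scale_linetype_identity() +
    ggplot2::scale_colour_manual(values = c(consumed = "#3366bb",
                                            released = "#cc3333")) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.45),
                                labels = c(`TRUE` = "FDR < 0.05",
                                           `FALSE` = "n.s.")) +
    ggplot2::scale_linewidth(range = c(0.2, 2), limits = c(0, 1)) +
    ggplot2::annotate("text", x = 0, y = seq_along(taxa) *
                        (length(mets) / max(1, length(taxa))),
                      label = taxa, hjust = 1.05, size = 3) +
    ggplot2::annotate("text", x = 1, y = seq_along(mets), label = mets,
                      hjust = -0.05, size = 3) +
    ggplot2::scale_x_continuous(limits = c(-0.5, 1.5), breaks = NULL) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = NULL, y = NULL, colour = "prediction",
                  linewidth = "|rho|", alpha = NULL) +
    ggplot2::theme_minimal()
}
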