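#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
#' @method autoplot network_embedding
autoplot.network_embedding <- function(object, highlight = character(), ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(colour = "grey60", size = 1) +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2",
                  title = "Gene-network similarity embedding") +
    ggplot2::theme_minimal()
  if (length(highlight) > 0) {
    hl <- object[object$gene %in% highlight, , drop = FALSE]
    p <- p +
      ggplot2::geom_point(data = hl, colour = "firebrick", size = 2) +
      ggplot2::geom_text(data = hl, ggplot2::aes(label = .data$gene),
                         vjust = -0.8, size = 3, colour = "firebrick")
  }
  p
}

#' Violin comparison of test genes against a reference signature
#'
#' One violin per test gene, showing its distribution of similarities to the
#' members of the reference signature; the red line marks the median, blue
#' lines the quartiles. Overlapping violins indicate similar networks; a
#' violin sitting near zero is a negative control.
#'
#' @param s A `network_similarity` matrix.
#' @param sig Reference [extract_signature()].
#' @param test_genes Character vector of genes to compare.
#' @return A ggplot object.
#' @export
plot_signature_violin <- function(s, sig, test_genes) {
  dists <- purrr::map_dfr(test_genes, function(g) {
    tidy(signature_distribution(s, sig, g))
  })
  dists$test_gene <- factor(dists$test_gene, levels = test_genes)
  ggplot2::ggplot(dists, ggplot2::aes(x = .data$test_gene, y = .data$score)) +
    ggplot2::geom_violin(fill = "grey85", colour = "grey40") +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.5, colour = "red", linewidth = 0.3) +
    ggplot2::stat_summary(
      fun.min = function(v) stats::quantile(v, 0.25),
      fun.max = function(v) stats::quantile(v, 0.75),
      fun = stats::median,
      geom = "errorbar", width = 0.3, colour = "blue", linewidth = 0.3
    ) +
    ggplot2::labs(
      x = NULL,
      y = sprintf("Similarity to %s signature members", attr(sig, "query"))
    ) +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot gsea_result
autoplot.gsea_result <- function(object, nes_cutoff = 1.4, ...) {
  df <- tibble::as_tibble(object)
  df$set <- factor(df$set, levels = rev(df$set))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nes, y = .data$set,
                                   fill = .data$fdr_q)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = c(-nes_cutoff, nes_cutoff),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_fill_gradient(low = "firebrick", high = "grey70",
                                 name = "FDR q") +
    ggplot2::labs(x = "Normalized enrichment score", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot enrichment_score
autoplot.enrichment_score <- function(object, ...) {
  rs <- object$running_sum
  ggplot2::ggplot(rs, ggplot2::aes(x = .data$rank, y = .data$running)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_rug(data = rs[rs$hit, ], sides = "b", length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(x = "Rank in profile", y = "Running enrichment score",
                  title = sprintf("ES = %.3f", object$es)) +
    ggplot2::theme_minimal()
}

#' Bar chart of marker positivity per condition
#'
#' @param tbl Output of [positivity_fraction()].
#' @return A ggplot object.
#' @export
plot_positivity <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$condition,
                                    y = .data$percent_1dp)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$percent_1dp)),
                       vjust = -0.4, size = 3.5) +
    ggplot2::labs(x = NULL, y = "Cells positive (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
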