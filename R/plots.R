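#' Volcano plot of differential-expression results
#'
#' log2 fold change against -log10 p, colored by significance class, with
#' the fold-change guide lines at `±fc_line` and a horizontal line at the
#' largest p still significant at the FDR threshold.
#'
#' @param results DE results tibble for one scope (from [fit_global()] or
#'   one region of [fit_regional()]).
#' @param alpha FDR threshold defining significance.
#' @param fc_line Fold-change guide line (log2 units).
#' @return A ggplot object.
#' @export
plot_volcano <- function(results, alpha = 0.05, fc_line = 0.26) {
  sig <- results$q < alpha
  results$class <- dplyr::case_when(
    sig & abs(results$log2fc) >= fc_line ~ "significant, |log2FC| beyond line",
    sig ~ "significant",
    TRUE ~ "not significant"
  )
  p_line <- if (any(sig)) max(results$p[sig]) else NA_real_
  gg <- ggplot2::ggplot(results,
                        ggplot2::aes(x = .data$log2fc,
                                     y = -log10(.data$p),
                                     colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-fc_line, fc_line),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_colour_manual(values = c(
      "significant, |log2FC| beyond line" = "purple",
      "significant" = "steelblue",
      "not significant" = "grey70"
    )) +
    ggplot2::labs(x = "log2 fold change (case - comparison)",
                  y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.na(p_line)) {
    gg <- gg + ggplot2::geom_hline(yintercept = -log10(p_line),
                                   linetype = "dotted", colour = "grey40")
  }
  gg
}

#' Boxplots of cell-type fractions by diagnosis
#'
#' @param fractions Long fractions tibble (`subject` or `sample`,
#'   `cell_type`, `fraction`).
#' @param meta Metadata supplying `diagnosis`.
#' @return A ggplot object.
#' @export
plot_fractions <- function(fractions, meta) {
  key <- if ("subject" %in% names(fractions)) "subject" else "sample"
  dat <- dplyr::left_join(fractions,
                          dplyr::distinct(meta, .data[[key]],
                                          .keep_all = TRUE),
                          by = key)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cell_type,
                                    y = .data$fraction,
                                    fill = .data$diagnosis)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "estimated fraction", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Downregulated-fraction summary per gene-set cluster
#'
#' @param frac_down Per-set downregulated DEG fractions.
#' @param cluster_labels Cluster label per set.
#' @return A ggplot object (points + cluster means, reference line at 0.5).
#' @export
plot_directionality <- function(frac_down, cluster_labels) {
  dat <- tibble::tibble(frac_down = frac_down,
                        cluster = factor(cluster_labels))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$cluster,
                                    y = .data$frac_down)) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar",
                          width = 0.4, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "gene-set cluster",
                  y = "fraction of downregulated DEGs") +
    ggplot2::theme_minimal()
}
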