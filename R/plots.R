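#' Plot the treated-minus-control allelic ratio along the chromosome
#'
#' One point per gene at its TSS; reactivated genes stand out as positive
#' deviations of the cast (Xi) expression share.
#'
#' @param profile Tibble from [delta_ratio_profile()].
#' @param classes Optional `xcr_classification` for colouring by status.
#' @return A ggplot object.
#' @export
plot_delta_ratio <- function(profile, classes = NULL) {
  df <- profile
  if (!is.null(classes)) {
    df <- left_join(df, select(as_tibble(classes), "gene_id", "status"),
                    by = "gene_id")
  } else {
    df$status <- "informative"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tss / 1e6, y = .data$delta_ratio,
                                   colour = .data$status)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 0.9, alpha = 0.8) +
    ggplot2::labs(x = "position on chrX (Mb)",
                  y = "Δ cast / (cast + Bl6), treated - control",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.xcr_classification <- function(object, ...) {
  df <- as_tibble(unclass_first(object)) %>%
    filter(.data$status != "uninformative")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tss / 1e6, y = .data$delta_ratio,
                                   colour = .data$status)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 0.9, alpha = 0.8) +
    ggplot2::labs(x = "position on chrX (Mb)",
                  y = "Δ cast ratio (treated - control)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.xcr_tad_enrichment <- function(object, ...) {
  df <- as_tibble(unclass_first(object)) %>%
    mutate(mid = (.data$start + .data$end) / 2e6,
           flag = dplyr::case_when(.data$significant_enriched ~ "enriched",
                                   .data$significant_depleted ~ "depleted",
                                   TRUE ~ "ns"))
  cutoff <- -log10(attr(object, "alpha") %||% 0.05)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid,
                                   y = .data$signed_minus_log10_p,
                                   colour = .data$flag)) +
    ggplot2::geom_hline(yintercept = c(-cutoff, cutoff),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mid, yend = 0)) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::scale_colour_manual(values = c(enriched = "#d1495b",
                                            depleted = "#00798c",
                                            ns = "grey60")) +
    ggplot2::labs(x = "TAD midpoint on chrX (Mb)",
                  y = "signed -log10 binomial p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Violin plot of a per-gene feature by classification status
#'
#' @param features Feature tibble from [build_feature_table()].
#' @param classes `xcr_classification` tibble.
#' @param feature Name of the feature column to plot.
#' @param statuses Statuses shown (default the two compared classes).
#' @return A ggplot object.
#' @export
plot_feature_violin <- function(features, classes, feature,
                                statuses = c("non_reactivated", "reactivated")) {
  df <- features %>%
    left_join(select(as_tibble(classes), "gene_id", "status"), by = "gene_id") %>%
    filter(.data$status %in% statuses)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$status, y = .data[[feature]],
                                   fill = .data$status)) +
    ggplot2::geom_violin(alpha = 0.7, show.legend = FALSE) +
    ggplot2::geom_boxplot(width = 0.12, outlier.size = 0.5,
                          show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = feature) +
    ggplot2::theme_minimal()
}

#' Line plot of a metagene profile
#'
#' @param profile Tibble from [metagene_profile()], optionally row-bound
#'   across gene classes with a `class` column.
#' @return A ggplot object.
#' @export
plot_metagene <- function(profile) {
  aes <- if ("class" %in% names(profile)) {
    ggplot2::aes(x = .data$bin, y = .data$mean_signal, colour = .data$class)
  } else {
    ggplot2::aes(x = .data$bin, y = .data$mean_signal)
  }
  ggplot2::ggplot(profile, aes) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "bin", y = "mean signal") +
    ggplot2::theme_minimal()
}
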