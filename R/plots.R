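#' Radar-style plot of pathway activities
#'
#' Activities of the assessable pathways on the \[0,1\] scale around a
#' polar axis, with the medium band \[0.4, 0.6\] shaded.
#'
#' @param object `pathway_activity` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pathway_activity
#' @export
autoplot.pathway_activity <- function(object, ...) {
  df <- as_tibble(object) %>% filter(assessable)
  df$pathway_id <- factor(df$pathway_id, levels = df$pathway_id)
  ggplot2::ggplot(df, ggplot2::aes(x = pathway_id, y = activity,
                                   group = 1)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = 0.4,
                      ymax = 0.6, alpha = 0.15, fill = "grey40") +
    ggplot2::geom_col(ggplot2::aes(fill = label), width = 0.8) +
    ggplot2::scale_fill_manual(values = c(low = "#4575b4",
                                          medium = "#bdbdbd",
                                          high = "#d73027")) +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "pathway activity", fill = "label") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 7))
}

#' @rdname autoplot.pathway_activity
#' @export
plot_radar <- autoplot.pathway_activity

#' Scatter plot of a cohort embedding
#'
#' @param object `embedding` tibble from [embed_samples()].
#' @param ... Unused.
#' @return A ggplot object; the query sample is drawn as a black diamond.
#' @method autoplot embedding
#' @export
autoplot.embedding <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df[!df$is_query, ],
                  ggplot2::aes(x = dim1, y = dim2, colour = subtype)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_point(data = df[df$is_query, ], colour = "black",
                        shape = 18, size = 4) +
    ggplot2::labs(x = paste(attr(object, "method"), "1"),
                  y = paste(attr(object, "method"), "2"),
                  colour = "subtype") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.embedding
#' @export
plot_embedding <- autoplot.embedding

#' Cohort TMB histogram with the query sample marked
#'
#' @param result `tmb_result` row.
#' @param cohort_tmbs Numeric cohort TMB vector.
#' @return A ggplot object.
#' @export
plot_tmb <- function(result, cohort_tmbs) {
  df <- tibble(tmb = cohort_tmbs)
  ggplot2::ggplot(df, ggplot2::aes(x = tmb)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = result$tmb, colour = "#d73027",
                        linewidth = 1) +
    ggplot2::labs(x = "somatic mutations per Mb exon", y = "samples",
                  subtitle = sprintf("query TMB %.2f (percentile %.1f)",
                                     result$tmb,
                                     result$cohort_percentile)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
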