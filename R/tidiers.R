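# broom-style tidy()/glance() and ggplot2 autoplot() methods for the
# package's result objects.

#' @exportS3Method generics::tidy
tidy.de_result <- function(x, ...) {
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.de_result <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(
    n_features = nrow(x),
    n_significant = sum(x$significant),
    n_up = sum(x$significant & x$direction == "up"),
    n_down = sum(x$significant & x$direction == "down"),
    alpha = cfg$alpha, test = cfg$test
  )
}

#' @exportS3Method generics::tidy
tidy.venn_partition <- function(x, ...) {
  tibble(region = x$region, count = x$count, percentage = x$percentage)
}

#' @exportS3Method generics::glance
glance.venn_partition <- function(x, ...) {
  tibble(n_regions = nrow(x), union_size = sum(x$count),
         denominator = attr(x, "denominator"))
}

#' @exportS3Method generics::tidy
tidy.ora_result <- function(x, ...) {
  as_tibble(x)
}

#' @exportS3Method generics::glance
glance.ora_result <- function(x, alpha = 0.05, ...) {
  tibble(n_terms = nrow(x), n_significant = sum(x$p_adj < alpha),
         min_p_adj = if (nrow(x)) min(x$p_adj) else NA_real_)
}

#' @exportS3Method generics::tidy
tidy.cv_report <- function(x, ...) {
  x$per_fold
}

#' @exportS3Method generics::glance
glance.cv_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble(folds = x$config$folds, repeats = x$config$repeats,
           n_candidates = length(x$candidates)),
    as_tibble(x$means))
}

#' Volcano plot of a DE result
#'
#' @param object A `de_result` tibble.
#' @param ... Unused.
#' @return A ggplot object: log2 fold change vs -log10 p, significant
#'   features highlighted.
#' @exportS3Method ggplot2::autoplot
autoplot.de_result <- function(object, ...) {
  df <- volcano_table(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = .data$neg_log10_p,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Bar chart of Venn region counts
#'
#' @param object A `venn_partition`.
#' @param ... Unused.
#' @return A ggplot object of region counts with percentage labels.
#' @exportS3Method ggplot2::autoplot
autoplot.venn_partition <- function(object, ...) {
  df <- tidy.venn_partition(object)
  df$region <- factor(df$region, levels = df$region)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$percentage)),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = "Venn region", y = "features") +
    ggplot2::theme_minimal()
}

#' Enrichment dot plot
#'
#' The study's comparative convention: one column per condition, dot size
#' is GeneRatio, colour is the adjusted p-value, filter-excluded terms
#' are cross-marked.
#'
#' @param object A `dotplot_table` from [comparative_dotplot()].
#' @param max_terms Show at most this many terms, by best adjusted p
#'   (default 25).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.dotplot_table <- function(object, max_terms = 25, ...) {
  keep <- object |>
    group_by(.data$term_id) |>
    summarise(best = min(.data$p_adj)) |>
    arrange(.data$best) |>
    head(max_terms) |>
    pull(.data$term_id)
  df <- object[object$term_id %in% keep, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$name,
                                        size = .data$gene_ratio_num,
                                        colour = .data$p_adj)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "firebrick", high = "steelblue") +
    ggplot2::labs(size = "GeneRatio", colour = "adjusted p",
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (any(df$excluded)) {
    p <- p + ggplot2::geom_point(data = df[df$excluded, ], shape = 4,
                                 colour = "black", size = 3)
  }
  p
}

#' Per-fold metric plot for a CV report
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot object of per-fold metric values.
#' @exportS3Method ggplot2::autoplot
autoplot.cv_report <- function(object, ...) {
  df <- object$per_fold |>
    tidyr::pivot_longer(c("f1", "specificity", "sensitivity",
                          "balanced_accuracy"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "held-out value") +
    ggplot2::theme_minimal()
}
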