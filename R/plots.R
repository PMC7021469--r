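# ggplot2 figures for design results.

#' Plot a guide design result
#'
#' Two views: `"recovery"` shows the percent of genes with at least one
#' guide at primary stringency and cumulatively after each relaxation
#' combination (in the fixed search order); `"distance"` shows the TSS
#' distance distribution of the top hits (negative = promoter), split by
#' targeting strand.
#'
#' @param object A `guide_design`.
#' @param type `"recovery"` or `"distance"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.guide_design <- function(object, type = c("recovery", "distance"),
                                  ...) {
  type <- arg_match(type)
  if (type == "recovery") {
    n <- object$genome$n_genes
    rep <- object$iteration$report
    df <- bind_rows(
      tibble(stage = "primary",
             pct = 100 * length(object$genes_with_guides_primary) / n),
      tibble(stage = rep$combo,
             pct = 100 * (length(object$genes_with_guides_primary) +
                            rep$cumulative_recovered) / n)
    ) %>%
      mutate(stage = factor(.data$stage, levels = unique(.data$stage)))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$pct)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::coord_cartesian(ylim = c(0, 100)) +
      ggplot2::labs(x = "relaxation combination (cumulative)",
                    y = "% genes with ≥ 1 guide",
                    title = object$genome$label) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                         hjust = 1))
  } else {
    ggplot2::ggplot(object$top_hits,
                    ggplot2::aes(x = .data$distance_fraction,
                                 fill = .data$strand)) +
      ggplot2::geom_histogram(bins = 30, position = "stack") +
      ggplot2::geom_vline(xintercept = 0, linetype = 2) +
      ggplot2::labs(x = "distance from TSS (fraction of gene length)",
                    y = "top hits", title = object$genome$label) +
      ggplot2::theme_minimal()
  }
}

#' @rdname autoplot.guide_design
#' @param x A `guide_design`.
#' @export
plot.guide_design <- function(x, type = c("recovery", "distance"), ...) {
  print(autoplot.guide_design(x, type = type, ...))
  invisible(x)
}
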