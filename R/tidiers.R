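# broom-style accessors for guide_design objects.

#' Tidy a guide design result into a tibble
#'
#' @param x A `guide_design` from [run_pipeline()].
#' @param what Which table: `"top_hits"` (default; ranked per-gene guides),
#'   `"pairs"`, `"candidates"` (all candidates with filter verdicts),
#'   `"scrambles"`, or `"iteration"` (per-combination recovery counts).
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
#' @export
tidy.guide_design <- function(x, what = c("top_hits", "pairs", "candidates",
                                          "scrambles", "iteration"), ...) {
  what <- arg_match(what)
  switch(
    what,
    top_hits = select(
      x$top_hits, "gene_id", "rank", "protospacer", "pam", "length",
      "strand", "genome_start", "genome_end", "distance_fraction",
      "gc_percent", "iteration_label"),
    pairs = x$pairs,
    candidates = x$candidates,
    scrambles = x$scrambles %||% tibble(sequence = character(),
                                        gc_percent = numeric(),
                                        rng_seed_used = integer()),
    iteration = x$iteration$report
  )
}

#' One-row summary of a guide design run
#'
#' @param x A `guide_design`.
#' @param ... Unused.
#' @return A one-row tibble: gene counts and the percent of genes with at
#'   least one guide at primary parameters, after relaxation, and with at
#'   least one qualifying pair.
#' @exportS3Method generics::glance
#' @export
glance.guide_design <- function(x, ...) {
  n <- x$genome$n_genes
  genes_final <- unique(x$selected$gene_id)
  genes_paired <- unique(x$pairs$gene_id)
  tibble(
    genes_total = n,
    genome_size = x$genome$stats$size,
    genome_gc = x$genome$stats$gc_percent,
    n_top_hits = nrow(x$top_hits),
    n_pairs = nrow(x$pairs),
    genes_with_guides_primary = length(x$genes_with_guides_primary),
    genes_with_guides_final = length(genes_final),
    genes_with_pairs = length(genes_paired),
    pct_genes_with_guides_primary =
      100 * length(x$genes_with_guides_primary) / n,
    pct_genes_with_guides_final = 100 * length(genes_final) / n,
    pct_genes_with_pairs = 100 * length(genes_paired) / n
  )
}

#' @export
print.guide_design <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<guide_design> %s (%s bp, %.1f%% GC)\n", x$genome$label,
              format(g$genome_size, big.mark = ","), g$genome_gc))
  cat(sprintf("  genes: %d | with guides: %d primary (%.1f%%), %d after relaxation (%.1f%%)\n",
              g$genes_total, g$genes_with_guides_primary,
              g$pct_genes_with_guides_primary, g$genes_with_guides_final,
              g$pct_genes_with_guides_final))
  cat(sprintf("  top hits: %d | pairs: %d (%d genes, %.1f%%)\n",
              g$n_top_hits, g$n_pairs, g$genes_with_pairs,
              g$pct_genes_with_pairs))
  if (length(x$genes_without_guides)) {
    cat(sprintf("  still without guides: %s\n",
                paste(head(x$genes_without_guides, 8), collapse = ", ")))
  }
  invisible(x)
}
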