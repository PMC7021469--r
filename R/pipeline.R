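# Pipeline orchestration: load/preprocess -> enumerate -> filter -> select
# -> iterate -> (optional) scramble, with per-stage accounting.

#' Run the full guide design pipeline on a genome model
#'
#' Executes enumeration, filtering, per-PAM selection, TSS-proximity ranking,
#' pair construction, and (by default) iterative parameter relaxation for
#' genes that produced no guide; scramble controls are added when
#' `params$scramble_n > 0`. Aside from scramble generation (seeded by
#' `params$scramble_seed`) the pipeline is fully deterministic: identical
#' inputs give identical outputs.
#'
#' @param model A `genome_model` from [load_complete_genome()],
#'   [load_draft_genome()], [genome_model()] or [generate_synthetic_genome()].
#' @param params A [design_params()] object.
#' @param relax Run the relaxation iteration for guide-less genes.
#' @param verbose Log per-stage counts with [message()].
#' @return An object of class `"guide_design"`; see [tidy.guide_design()],
#'   [glance.guide_design()] and [autoplot.guide_design()].
#' @export
run_pipeline <- function(model, params = design_params(), relax = TRUE,
                         verbose = FALSE) {
  stopifnot(inherits(model, "genome_model"), inherits(params, "design_params"))
  say <- function(...) if (verbose) inform(sprintf(...))
  n_genes <- nrow(model$genes)
  say("genome %s: %d bp, %d genes", model$source_label, model$length, n_genes)

  candidates <- enumerate_guides(model)
  say("enumeration: %d raw candidates from %d PAM-site/strand combinations",
      nrow(candidates),
      nrow(distinct(candidates, .data$gene_id, .data$strand,
                    .data$pam_offset)))
  index <- build_seed_index(model)
  say("off-target index: %d PAM sites genome-wide", index$n_sites)

  filtered <- apply_filters(candidates, params, index)
  rejections <- tibble(
    filter = c("homopolymer", "tss_distance", "bad_seed", "restriction",
               "offtarget"),
    n_failing = c(
      sum(!filtered$pass_homopolymer & params$homopolymer_filter_on),
      sum(!filtered$pass_tss), sum(!filtered$pass_bad_seed),
      sum(!filtered$pass_restriction), sum(!filtered$pass_offtarget))
  )
  say("filtering: %d of %d candidates accepted", sum(filtered$accepted),
      nrow(filtered))

  selected_primary <- select_per_pam(filtered, params$gc_min)
  if (nrow(selected_primary)) selected_primary$iteration_label <- "primary"
  genes_with_primary <- unique(selected_primary$gene_id)
  genes_without <- setdiff(model$genes$gene_id, genes_with_primary)
  say("selection: %d guides selected; %d/%d genes with guides at primary parameters",
      nrow(selected_primary), length(genes_with_primary), n_genes)

  if (relax && length(genes_without)) {
    iteration <- iterate_relaxations(filtered, params, genes_without)
    say("iteration: %d gene(s) recovered, %d still without guides",
        sum(iteration$report$genes_recovered),
        length(iteration$genes_still_without_guides))
  } else {
    iteration <- structure(
      list(recovered = tibble(), report = mutate(
             tibble(combo = names(relaxation_combos())),
             n_relaxations = lengths(relaxation_combos()),
             genes_recovered = 0L, cumulative_recovered = 0L),
           genes_still_without_guides = genes_without,
           recovered_labels = character(0)),
      class = "iteration_report")
  }
  final_selected <- bind_rows(selected_primary, iteration$recovered)
  if (nrow(final_selected) == 0L) {
    final_selected <- mutate(apply_filters(empty_guides_tbl(), params, index),
                             iteration_label = character())
  }
  top_hits <- rank_top_hits(final_selected, params$max_guides_per_gene)
  pairs <- build_pairs(final_selected, params$pair_min_separation)
  say("outputs: %d top hits, %d pairs across %d gene(s)",
      nrow(top_hits), nrow(pairs), length(unique(pairs$gene_id)))

  scrambles <- NULL
  if (params$scramble_n > 0L) {
    scrambles <- generate_scrambles(index, n = params$scramble_n,
                                    length = params$scramble_length,
                                    rng_seed = params$scramble_seed)
    say("scrambles: %d non-targeting controls", nrow(scrambles))
  }

  structure(
    list(top_hits = top_hits, pairs = pairs, selected = final_selected,
         candidates = filtered,
         genes_without_guides = iteration$genes_still_without_guides,
         genes_with_guides_primary = genes_with_primary,
         iteration = iteration, scrambles = scrambles,
         rejections = rejections, params = params,
         genome = list(label = model$source_label, stats = genome_stats(model),
                       n_genes = n_genes, gene_ids = model$genes$gene_id)),
    class = "guide_design"
  )
}

#' Design guides directly from input files
#'
#' File-level wrapper around the pipeline: supply either a complete genome
#' (`annotation` + `fasta`) or a draft genome (`contigs` + `cds`). When
#' `output_dir` is given, all result tables are written there with
#' [write_design()].
#'
#' @param annotation,fasta Complete-genome inputs: annotation (GenBank flat
#'   file or TSV gene table) and single-sequence FASTA.
#' @param contigs,cds Draft-genome inputs: contig multi-FASTA and CDS
#'   multi-FASTA.
#' @param params A [design_params()].
#' @param output_dir Optional output directory.
#' @param relax,verbose Passed to [run_pipeline()].
#' @return A `"guide_design"` object (invisibly when writing outputs).
#' @export
design_guides <- function(annotation = NULL, fasta = NULL, contigs = NULL,
                          cds = NULL, params = design_params(),
                          output_dir = NULL, relax = TRUE, verbose = FALSE) {
  complete <- !is.null(annotation) && !is.null(fasta)
  draft <- !is.null(contigs) && !is.null(cds)
  if (complete == draft) {
    abort("supply either annotation+fasta (complete) or contigs+cds (draft)",
          class = "guidebac_input_error")
  }
  model <- if (complete) {
    load_complete_genome(annotation, fasta, promoter_len = params$promoter_len)
  } else {
    load_draft_genome(contigs, cds, promoter_len = params$promoter_len,
                      spacer_len = params$spacer_len,
                      output_dir = output_dir)
  }
  res <- run_pipeline(model, params, relax = relax, verbose = verbose)
  if (!is.null(output_dir)) {
    write_design(res, output_dir)
    return(invisible(res))
  }
  res
}

#' Write all result tables of a design run
#'
#' Writes `top_hits.tsv`, `pairs.tsv`, `genes_without_guides.txt`,
#' `iteration_report.tsv`, and, when present, `scrambles.tsv`; with
#' `all_candidates = TRUE` also the unfiltered candidate table
#' `all_candidates.tsv`. Identical runs produce byte-identical files.
#'
#' @param x A `guide_design`.
#' @param dir Output directory (created if needed).
#' @param all_candidates Also write the intermediate candidate table.
#' @export
write_design <- function(x, dir, all_candidates = FALSE) {
  stopifnot(inherits(x, "guide_design"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tidy(x, "top_hits"), file.path(dir, "top_hits.tsv"),
                   progress = FALSE)
  readr::write_tsv(tidy(x, "pairs"), file.path(dir, "pairs.tsv"),
                   progress = FALSE)
  writeLines(x$genes_without_guides,
             file.path(dir, "genes_without_guides.txt"))
  readr::write_tsv(x$iteration$report, file.path(dir, "iteration_report.tsv"),
                   progress = FALSE)
  if (!is.null(x$scrambles)) {
    readr::write_tsv(x$scrambles, file.path(dir, "scrambles.tsv"),
                     progress = FALSE)
  }
  if (all_candidates) {
    readr::write_tsv(
      select(x$candidates, "gene_id", "protospacer", "pam", "length",
             "strand", "genome_start", "genome_end"),
      file.path(dir, "all_candidates.tsv"), progress = FALSE)
  }
  invisible(dir)
}

#' Summarise several design runs into a benchmark table
#'
#' One row per genome: percent of genes with at least one guide at primary
#' parameters, percent after relaxation, percent with at least one qualifying
#' pair, plus a `recovery` list-column holding the per-combination iteration
#' report.
#'
#' @param results A named list of `guide_design` objects.
#' @return A tibble.
#' @export
benchmark_report <- function(results) {
  stopifnot(length(results) >= 1)
  if (is.null(names(results))) {
    names(results) <- purrr::map_chr(results, ~ .x$genome$label)
  }
  purrr::imap(results, function(x, nm) {
    g <- glance(x)
    mutate(g, genome = nm, .before = 1) %>%
      mutate(recovery = list(x$iteration$report))
  }) %>% bind_rows()
}
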