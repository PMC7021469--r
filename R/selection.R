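# Final guide selection: per-PAM choice of the longest guide meeting the GC
# minimum, TSS-proximity ranking into a capped top-hits list, paired-guide
# construction under a steric spacing constraint, and the iterative
# relaxation engine for genes that produce no guide at primary stringency.

RELAXATION_ORDER <- c("GC", "TSS", "homopolymer", "offtarget")

#' Enumerate relaxation combinations in fixed search order
#'
#' Singles first (GC, TSS, homopolymer, off-target), then pairs, triples and
#' finally all four, each level in lexicographic order of the fixed single
#' order. The iteration engine tries these in order and stops at the first
#' combination that yields a guide, keeping stringency maximal per gene.
#'
#' @return A named list of character vectors; names are labels like
#'   `"GC+TSS"`.
#' @export
relaxation_combos <- function() {
  out <- list()
  for (m in seq_along(RELAXATION_ORDER)) {
    cmb <- utils::combn(RELAXATION_ORDER, m, simplify = FALSE)
    names(cmb) <- purrr::map_chr(cmb, paste, collapse = "+")
    out <- c(out, cmb)
  }
  out
}

# Acceptance under possibly-relaxed parameters, recomputed from the verdict
# and metric columns that apply_filters() stored (thresholds only; no
# re-querying of the index).
accepted_under <- function(filtered, params) {
  active <- if (params$offtarget_mode == "strict") filtered$strict_count else
    filtered$relaxed_count
  filtered$pass_length &
    (filtered$pass_homopolymer | !params$homopolymer_filter_on) &
    (filtered$distance_fraction <= params$tss_max_fraction) &
    filtered$pass_bad_seed & filtered$pass_restriction &
    (active < 2L)
}

#' Select the final guide for each PAM site
#'
#' Among a PAM site's accepted candidates whose GC content meets `gc_min`,
#' the guide of the greatest length is kept; if none qualifies the PAM
#' yields nothing. Input may hold candidates for many PAM sites and genes; a
#' PAM site is identified by (gene, strand, PAM offset within the region).
#'
#' @param candidates Filtered candidates from [apply_filters()] (must carry
#'   `accepted`).
#' @param gc_min GC minimum, percent.
#' @return Tibble with at most one row per PAM site.
#' @export
select_per_pam <- function(candidates, gc_min) {
  stopifnot("accepted" %in% names(candidates))
  candidates %>%
    filter(.data$accepted, .data$gc_percent >= gc_min) %>%
    group_by(.data$gene_id, .data$strand, .data$pam_offset) %>%
    slice_max(.data$length, n = 1L, with_ties = FALSE) %>%
    ungroup()
}

# Deterministic ordering used for ranking and tie-breaks: ascending TSS
# distance, then (strand, protospacer) lexicographically.
order_guides <- function(tbl) {
  arrange(tbl, .data$distance_fraction, .data$strand, .data$protospacer)
}

#' Rank a gene's selected guides into a top-hits list
#'
#' Guides are sorted by ascending distance from the TSS (promoter guides,
#' with negative distances, first), ties broken by (strand, protospacer) for
#' reproducibility, and the list truncated to `max_n` per gene.
#'
#' @param selected Selected guides (any number of genes).
#' @param max_n Maximum guides per gene.
#' @return Tibble with a 1-based `rank` column, contiguous within each gene.
#' @export
rank_top_hits <- function(selected, max_n) {
  selected %>%
    group_by(.data$gene_id) %>%
    order_guides() %>%
    mutate(rank = row_number()) %>%
    slice_head(n = as.integer(max_n)) %>%
    ungroup() %>%
    arrange(.data$gene_id, .data$rank)
}

#' Build qualifying guide pairs for dual targeting of one gene
#'
#' Every pair of a gene's selected guides whose occupied genomic footprints
#' (protospacer + PAM) are separated by a gap of at least `min_sep` bases
#' qualifies; the gap models the dCas9 footprint, so it is measured between
#' interval ends, not centers. `guide_a` is the TSS-proximal member. Pairs
#' are ordered by (distance of guide_a, distance of guide_b).
#'
#' @param selected Selected guides (any number of genes).
#' @param min_sep Minimum footprint gap, bases.
#' @return Tibble with `gene_id`, `a_*` and `b_*` guide columns and
#'   `separation` (the realized gap).
#' @export
build_pairs <- function(selected, min_sep) {
  cols <- c("protospacer", "pam", "length", "strand", "genome_start",
            "genome_end", "footprint_start", "footprint_end",
            "distance_fraction", "gc_percent")
  one_gene <- function(tbl) {
    k <- nrow(tbl)
    if (k < 2L) return(NULL)
    tbl <- order_guides(tbl)
    ij <- which(upper.tri(diag(k)), arr.ind = TRUE)
    a <- tbl[ij[, "row"], cols]
    b <- tbl[ij[, "col"], cols]
    gap <- pmax(a$footprint_start, b$footprint_start) -
      pmin(a$footprint_end, b$footprint_end) - 1L
    keep <- gap >= min_sep
    if (!any(keep)) return(NULL)
    out <- bind_cols(
      rename_with_prefix(a[keep, ], "a_"),
      rename_with_prefix(b[keep, ], "b_")
    )
    out$separation <- as.integer(gap[keep])
    out$gene_id <- tbl$gene_id[1]
    arrange(out, .data$a_distance_fraction, .data$b_distance_fraction)
  }
  out <- selected %>%
    split(selected$gene_id) %>%
    purrr::map(one_gene) %>%
    bind_rows()
  if (nrow(out) == 0L) {
    out <- tibble(gene_id = character(), separation = integer())
  }
  select(out, "gene_id", dplyr::starts_with("a_"), dplyr::starts_with("b_"),
         dplyr::any_of("separation"))
}

rename_with_prefix <- function(tbl, prefix) {
  names(tbl) <- paste0(prefix, names(tbl))
  tbl
}

#' Iteratively relax parameters for genes without guides
#'
#' For each gene that produced no selected guide at primary stringency, the
#' relaxation combinations from [relaxation_combos()] are tried in order;
#' the first combination yielding at least one selected guide is recorded as
#' that gene's `iteration_label` and its guides are returned. Genes
#' exhausting all combinations land in `genes_still_without_guides`.
#'
#' @param filtered Candidates for the whole genome after [apply_filters()]
#'   with the primary parameters (the stored counts and verdicts are
#'   re-thresholded per combination; the index is not re-queried).
#' @param params The primary [design_params()].
#' @param genes_without Character vector of gene ids lacking guides.
#' @return A list of class `"iteration_report"`: `recovered` (selected
#'   guides with `iteration_label`), `report` (per-combination recovered and
#'   cumulative gene counts), `genes_still_without_guides`, and
#'   `recovered_labels` (named by gene).
#' @export
iterate_relaxations <- function(filtered, params, genes_without) {
  combos <- relaxation_combos()
  recovered <- list()
  labels <- character(0)
  per_combo <- stats::setNames(integer(length(combos)), names(combos))
  still <- character(0)
  for (g in genes_without) {
    cand_g <- filter(filtered, .data$gene_id == g)
    hit <- FALSE
    if (nrow(cand_g) > 0L) {
      for (lab in names(combos)) {
        p_r <- relax_params(params, combos[[lab]])
        cand_g$accepted <- accepted_under(cand_g, p_r)
        sel <- select_per_pam(cand_g, p_r$gc_min)
        if (nrow(sel) > 0L) {
          sel$iteration_label <- lab
          recovered[[g]] <- sel
          labels[[g]] <- lab
          per_combo[[lab]] <- per_combo[[lab]] + 1L
          hit <- TRUE
          break
        }
      }
    }
    if (!hit) still <- c(still, g)
  }
  report <- tibble(
    combo = names(combos),
    n_relaxations = lengths(combos),
    genes_recovered = unname(per_combo),
    cumulative_recovered = cumsum(unname(per_combo))
  )
  structure(
    list(recovered = bind_rows(recovered), report = report,
         genes_still_without_guides = still, recovered_labels = labels),
    class = "iteration_report"
  )
}

#' @export
print.iteration_report <- function(x, ...) {
  n_rec <- sum(x$report$genes_recovered)
  cat(sprintf("<iteration_report> %d gene(s) recovered by relaxation, %d still without guides\n",
              n_rec, length(x$genes_still_without_guides)))
  hit <- filter(x$report, .data$genes_recovered > 0L)
  if (nrow(hit)) print(hit)
  invisible(x)
}
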