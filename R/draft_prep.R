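# Draft-genome preprocessing: concatenate contigs with N spacers and locate
# each CDS on the concatenation, producing the coordinate table the main
# pipeline consumes.

#' Concatenate contigs into one sequence with N spacers
#'
#' Contig order is preserved as given. The spacer must be at least as long as
#' a protospacer + PAM window (25 bases) so that no guide candidate can ever
#' bridge two contigs (any window touching a spacer contains N and is skipped
#' by enumeration).
#'
#' @param contigs Data frame with columns `id` and `sequence` (as returned by
#'   the internal FASTA reader), or a named character vector of sequences.
#' @param spacer_len Number of N's inserted between consecutive contigs.
#' @return A list with `sequence` (the concatenation) and `concat_map`, a
#'   tibble with per-contig `contig_id`, `offset` (1-based start within the
#'   concatenation) and `length`.
#' @export
concatenate_contigs <- function(contigs, spacer_len = 50) {
  if (is.character(contigs)) {
    contigs <- tibble(id = names(contigs) %||% paste0("contig_", seq_along(contigs)),
                      sequence = unname(contigs))
  }
  contigs <- as_tibble(contigs)
  if (nrow(contigs) == 0L) {
    abort("empty contig set", class = "guidebac_input_error")
  }
  if (any(!nzchar(contigs$sequence))) {
    abort("contig sequences must be non-empty", class = "guidebac_input_error")
  }
  if (anyDuplicated(contigs$id)) {
    abort("contig ids must be unique", class = "guidebac_input_error")
  }
  spacer_len <- as.integer(spacer_len)
  if (spacer_len < 25L && nrow(contigs) > 1L) {
    abort("spacer_len must be >= 25 so no guide window can bridge contigs",
          class = "guidebac_param_error")
  }
  lens <- nchar(contigs$sequence)
  offsets <- 1L + cumsum(c(0L, head(lens, -1L) + spacer_len))
  sequence <- paste(contigs$sequence,
                    collapse = strrep("N", spacer_len))
  list(
    sequence = sequence,
    concat_map = tibble(contig_id = contigs$id, offset = offsets,
                        length = lens, spacer_len = spacer_len)
  )
}

#' Locate CDS sequences on a concatenated draft genome
#'
#' Each CDS is searched as an exact substring on the forward strand, then (if
#' absent) as its exact reverse complement. The reported `start` is always
#' the smaller genomic coordinate, with the strand recorded. A CDS with no
#' match lands in the `unmapped` table; one with two or more matches is
#' assigned to its first occurrence with a warning and is flagged in the
#' `multi_hit` table.
#'
#' @param concat_sequence The concatenated genome string.
#' @param cds_records Data frame with columns `id` and `sequence`, or a named
#'   character vector of CDS sequences.
#' @return A list with `genes` (tibble `gene_id`, `start`, `end`, `strand`),
#'   `unmapped` (tibble `gene_id`) and `multi_hit` (tibble `gene_id`,
#'   `n_hits`).
#' @export
map_cds_coordinates <- function(concat_sequence, cds_records) {
  if (is.character(cds_records)) {
    cds_records <- tibble(id = names(cds_records), sequence = unname(cds_records))
  }
  cds_records <- as_tibble(cds_records)
  one <- function(id, cds) {
    hits_f <- stringi::stri_locate_all_fixed(concat_sequence, cds,
                                             overlap = TRUE)[[1]]
    hits_r <- stringi::stri_locate_all_fixed(concat_sequence, revcomp(cds),
                                             overlap = TRUE)[[1]]
    n_f <- sum(!is.na(hits_f[, 1]))
    n_r <- sum(!is.na(hits_r[, 1]))
    if (n_f > 0L) {
      tibble(gene_id = id, start = hits_f[1, 1], end = hits_f[1, 2],
             strand = "+", n_hits = n_f + n_r)
    } else if (n_r > 0L) {
      tibble(gene_id = id, start = hits_r[1, 1], end = hits_r[1, 2],
             strand = "-", n_hits = n_f + n_r)
    } else {
      tibble(gene_id = id, start = NA_integer_, end = NA_integer_,
             strand = NA_character_, n_hits = 0L)
    }
  }
  res <- purrr::map2(cds_records$id, toupper(cds_records$sequence), one) %>%
    bind_rows()
  unmapped <- res %>% filter(.data$n_hits == 0L) %>% select("gene_id")
  multi <- res %>% filter(.data$n_hits >= 2L) %>% select("gene_id", "n_hits")
  if (nrow(multi)) {
    warn(sprintf("%d CDS with multiple exact matches assigned to first occurrence: %s",
                 nrow(multi), paste(head(multi$gene_id, 5), collapse = ", ")))
  }
  list(
    genes = res %>% filter(.data$n_hits > 0L) %>%
      mutate(start = as.integer(.data$start), end = as.integer(.data$end)) %>%
      select("gene_id", "start", "end", "strand"),
    unmapped = unmapped,
    multi_hit = multi
  )
}

#' Load a draft genome from contig and CDS multi-FASTA files
#'
#' Preprocesses a draft assembly for the main pipeline: contigs are
#' concatenated with N spacers ([concatenate_contigs()]) and each CDS is
#' located on the concatenation by exact match ([map_cds_coordinates()]).
#'
#' @param contig_fasta Path to the multi-FASTA of contigs.
#' @param cds_fasta Path to the multi-FASTA of coding sequences.
#' @param promoter_len Upstream promoter window, bases.
#' @param spacer_len N-spacer length between contigs.
#' @param output_dir Optional directory; when given, the concatenated FASTA
#'   (`concatenated.fasta`), the gene coordinate TSV (`gene_table.tsv`) and
#'   the unmapped-CDS TSV (`unmapped_cds.tsv`) are written there.
#' @return A `"genome_model"`; the `concat_map`, `unmapped` and `multi_hit`
#'   tables are attached as attributes of the same names.
#' @export
load_draft_genome <- function(contig_fasta, cds_fasta, promoter_len = 100,
                              spacer_len = 50, output_dir = NULL) {
  contigs <- read_fasta_tbl(contig_fasta)
  cds <- read_fasta_tbl(cds_fasta)
  cc <- concatenate_contigs(contigs, spacer_len = spacer_len)
  mp <- map_cds_coordinates(cc$sequence, cds)
  model <- genome_model(cc$sequence, mp$genes, promoter_len = promoter_len,
                        source_label = paste0(
                          tools::file_path_sans_ext(basename(contig_fasta)),
                          "_concat"))
  attr(model, "concat_map") <- cc$concat_map
  attr(model, "unmapped") <- mp$unmapped
  attr(model, "multi_hit") <- mp$multi_hit
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(model$source_label, cc$sequence,
                file.path(output_dir, "concatenated.fasta"))
    write_gene_table(model, file.path(output_dir, "gene_table.tsv"))
    readr::write_tsv(mp$unmapped, file.path(output_dir, "unmapped_cds.tsv"),
                     progress = FALSE)
  }
  model
}
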