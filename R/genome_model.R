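# GenomeModel: one (possibly concatenated) genome sequence plus per-gene
# coordinate records with promoter-extended windows. All external coordinates
# are 1-based inclusive (GenBank convention).

# Add promoter_start/promoter_end/cds_length to a gene table. The promoter
# window abuts the translation start in gene orientation and is clipped at
# the genome boundaries; an empty window is represented with end < start.
compute_promoters <- function(genes, promoter_len, genome_len) {
  plus <- genes$strand == "+"
  genes$promoter_start <- ifelse(plus,
                                 pmax(1L, genes$cds_start - promoter_len),
                                 genes$cds_end + 1L)
  genes$promoter_end <- ifelse(plus,
                               genes$cds_start - 1L,
                               pmin(genome_len, genes$cds_end + promoter_len))
  genes$promoter_start <- as.integer(genes$promoter_start)
  genes$promoter_end <- as.integer(genes$promoter_end)
  genes$cds_length <- genes$cds_end - genes$cds_start + 1L
  genes
}

#' Construct a genome model from an in-memory sequence and gene table
#'
#' The workhorse constructor behind [load_complete_genome()] and the draft
#' preprocessing path; also the entry point for synthetic genomes. Gene
#' records are extended upstream (in gene orientation) by `promoter_len`
#' bases, clipped at the genome boundaries.
#'
#' @param sequence Single nucleotide string over A/C/G/T/N.
#' @param genes Data frame with columns `gene_id`, `start`, `end`, `strand`
#'   (`+`/`-`); coordinates 1-based inclusive with `start <= end`.
#' @param promoter_len Upstream promoter window length, bases.
#' @param source_label Free-text label (accession or file stem).
#' @return An object of class `"genome_model"` with fields `sequence`,
#'   `length`, `genes` (tibble with promoter windows and `cds_length`) and
#'   `source_label`.
#' @export
genome_model <- function(sequence, genes, promoter_len = 100,
                         source_label = "genome") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- normalize_seq(sequence, what = source_label)
  genome_len <- nchar(sequence)
  genes <- as_tibble(genes)
  if (!all(c("gene_id", "start", "end", "strand") %in% names(genes))) {
    abort("`genes` needs columns gene_id, start, end, strand",
          class = "guidebac_input_error")
  }
  genes <- genes %>%
    mutate(cds_start = as.integer(.data$start),
           cds_end = as.integer(.data$end)) %>%
    select("gene_id", "cds_start", "cds_end", "strand")

  bad <- is.na(genes$cds_start) | is.na(genes$cds_end) |
    is.na(genes$strand) | !(genes$strand %in% c("+", "-")) |
    genes$cds_start < 1L | genes$cds_start > genes$cds_end
  if (any(bad)) {
    warn(sprintf("%d gene(s) with missing/invalid coordinates skipped: %s",
                 sum(bad),
                 paste(head(genes$gene_id[bad], 5), collapse = ", ")))
    genes <- genes[!bad, ]
  }
  if (nrow(genes) == 0L) {
    abort("no valid gene records", class = "guidebac_input_error")
  }
  if (any(genes$cds_end > genome_len)) {
    abort(sprintf(
      "annotation coordinates extend beyond the %d bp sequence (max end %d)",
      genome_len, max(genes$cds_end)),
      class = "guidebac_consistency_error")
  }
  if (anyDuplicated(genes$gene_id)) {
    abort("gene identifiers must be unique", class = "guidebac_input_error")
  }
  genes <- compute_promoters(genes, as.integer(promoter_len), genome_len)
  structure(
    list(sequence = sequence, length = genome_len, genes = genes,
         source_label = source_label, promoter_len = as.integer(promoter_len)),
    class = "genome_model"
  )
}

#' Load a complete genome from a FASTA file and an annotation
#'
#' The annotation may be a GenBank flat file (detected by its `LOCUS` header)
#' or a TSV gene table with columns `gene_id`, `start`, `end`, `strand`, such
#' as the one written by [write_gene_table()] or by the draft preprocessing
#' path. One gene record is created per CDS feature, extended upstream by
#' `promoter_len` bases.
#'
#' @param annotation_source Path to the annotation (GenBank or TSV).
#' @param fasta_source Path to the single-sequence genome FASTA.
#' @param promoter_len Upstream promoter window, bases. Default 100.
#' @return A `"genome_model"` object.
#' @export
load_complete_genome <- function(annotation_source, fasta_source,
                                 promoter_len = 100) {
  fa <- read_fasta_tbl(fasta_source)
  if (nrow(fa) > 1L) {
    abort(paste0("FASTA contains ", nrow(fa), " sequences; a complete genome ",
                 "must be a single sequence (use load_draft_genome() for ",
                 "contig sets)"),
          class = "guidebac_input_error")
  }
  first <- readLines(annotation_source, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (length(first) && stringi::stri_detect_regex(first[1], "^LOCUS")) {
    genes <- read_genbank_cds(annotation_source)
    declared <- attr(genes, "locus_length")
    if (!is.na(declared) && declared != nchar(fa$sequence[1])) {
      abort(sprintf(
        "FASTA length %d does not match GenBank LOCUS length %d",
        nchar(fa$sequence[1]), declared),
        class = "guidebac_consistency_error")
    }
  } else {
    genes <- readr::read_tsv(annotation_source, show_col_types = FALSE,
                             progress = FALSE)
  }
  genome_model(fa$sequence[1], genes, promoter_len = promoter_len,
               source_label = fa$id[1])
}

#' @export
print.genome_model <- function(x, ...) {
  st <- genome_stats(x)
  cat(sprintf("<genome_model> %s: %s bp, %.1f%% GC, %d genes (promoter %d bp)\n",
              x$source_label, format(st$size, big.mark = ","),
              st$gc_percent, nrow(x$genes), x$promoter_len))
  invisible(x)
}

#' Genome size and GC content
#'
#' @param model A `genome_model`.
#' @return One-row tibble with `size` (bases) and `gc_percent`
#'   (100 * (G+C)/(A+C+G+T), N excluded; `NA` for an all-N sequence).
#' @export
genome_stats <- function(model) {
  tibble(size = model$length, gc_percent = gc_fraction(model$sequence))
}

# Genomic bounds of a gene's target region (promoter + CDS) on the forward
# strand. Empty promoter windows (end < start) contribute nothing.
region_bounds <- function(gene) {
  prom_len <- max(0L, gene$promoter_end - gene$promoter_start + 1L)
  if (gene$strand == "+") {
    c(start = if (prom_len > 0L) gene$promoter_start else gene$cds_start,
      end = gene$cds_end, prom_len = prom_len)
  } else {
    c(start = gene$cds_start,
      end = if (prom_len > 0L) gene$promoter_end else gene$cds_end,
      prom_len = prom_len)
  }
}

#' Retrieve the promoter + CDS sequence of one gene, in gene orientation
#'
#' Minus-strand genes are reverse complemented, so the returned sequence
#' always reads promoter then CDS, 5' to 3'. `tss_offset` is the 0-based
#' offset at which the CDS begins, i.e. the realized promoter length after
#' boundary clipping.
#'
#' @param model A `genome_model`.
#' @param gene A gene identifier, or one row of `model$genes`.
#' @return A list of class `"target_region"` with `gene_id`, `sequence`,
#'   `tss_offset`, `cds_length`, `strand` and the forward-strand genomic
#'   bounds `genome_start`/`genome_end` of the region.
#' @export
extract_target_region <- function(model, gene) {
  if (is.character(gene)) {
    idx <- match(gene, model$genes$gene_id)
    if (is.na(idx)) {
      abort(sprintf("gene '%s' not in model", gene),
            class = "guidebac_input_error")
    }
    gene <- model$genes[idx, ]
  }
  b <- region_bounds(gene)
  seq <- substr(model$sequence, b[["start"]], b[["end"]])
  if (gene$strand == "-") seq <- revcomp(seq)
  structure(
    list(gene_id = gene$gene_id, sequence = seq,
         tss_offset = unname(b[["prom_len"]]),
         cds_length = gene$cds_length, strand = gene$strand,
         genome_start = unname(b[["start"]]), genome_end = unname(b[["end"]])),
    class = "target_region"
  )
}

#' Write the gene coordinate table of a model as TSV
#'
#' Columns `gene_id`, `start`, `end`, `strand`, `promoter_start`,
#' `promoter_end`, 1-based inclusive. Reloading the file with
#' [load_complete_genome()] (same FASTA, same `promoter_len`) reproduces the
#' model's coordinates exactly.
#'
#' @param model A `genome_model`.
#' @param path Output path.
#' @export
write_gene_table <- function(model, path) {
  model$genes %>%
    select("gene_id", start = "cds_start", end = "cds_end", "strand",
           "promoter_start", "promoter_end") %>%
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}
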