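# Synthetic genome fixtures: random bacterial-like genomes with controllable
# size, GC content and gene-duplication fraction (the axes along which real
# benchmark genomes vary), plus an optional contig-split draft version of
# the same genome. Used by the test suite and the acceptance script; fully
# deterministic under the spec's rng_seed.

#' Specification for a synthetic genome
#'
#' Defaults describe a small but realistic bacterial fixture: 20 genes of
#' 300-1500 bp (typical bacterial CDS lengths) separated by 100-400 bp
#' intergenic stretches, balanced GC, no duplications.
#'
#' @param n_genes Number of primary genes.
#' @param gene_length_range Length-2 integer range of CDS lengths, bases.
#' @param intergenic_length_range Length-2 integer range of intergenic
#'   stretches, bases.
#' @param gc_target Target GC content, percent.
#' @param duplicated_gene_fraction Fraction of genes receiving an identical
#'   second copy elsewhere in the genome (0-1).
#' @param contig_split Optional number of breakpoints for the draft version;
#'   breakpoints fall in intergenic stretches so no gene is interrupted.
#' @param rng_seed Integer seed; identical specs give byte-identical output.
#' @return A list of class `"synthetic_genome_spec"`.
#' @export
synthetic_genome_spec <- function(n_genes = 20,
                                  gene_length_range = c(300, 1500),
                                  intergenic_length_range = c(100, 400),
                                  gc_target = 50,
                                  duplicated_gene_fraction = 0,
                                  contig_split = NULL,
                                  rng_seed = 1L) {
  stopifnot(n_genes >= 1,
            length(gene_length_range) == 2, all(gene_length_range > 0),
            length(intergenic_length_range) == 2,
            all(intergenic_length_range > 0),
            gc_target > 0, gc_target < 100,
            duplicated_gene_fraction >= 0, duplicated_gene_fraction <= 1,
            is.null(contig_split) || contig_split >= 1)
  structure(
    list(n_genes = as.integer(n_genes),
         gene_length_range = as.integer(sort(gene_length_range)),
         intergenic_length_range = as.integer(sort(intergenic_length_range)),
         gc_target = gc_target,
         duplicated_gene_fraction = duplicated_gene_fraction,
         contig_split = if (is.null(contig_split)) NULL
                        else as.integer(contig_split),
         rng_seed = as.integer(rng_seed)),
    class = "synthetic_genome_spec"
  )
}

rand_seq <- function(n, gc_target) {
  g <- gc_target / 200
  a <- (100 - gc_target) / 200
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(a, g, g, a)), collapse = "")
}

# Naive per-region PAM count (truth table): test every trinucleotide window
# on both strands directly.
naive_pam_count <- function(region) {
  n <- nchar(region)
  if (n < 3L) return(0L)
  i <- seq_len(n - 2L)
  trip <- substring(region, i, i + 2L)
  sum(substring(trip, 2L, 3L) == "GG" & !stringi::stri_detect_fixed(trip, "N")) +
    sum(substring(trip, 1L, 2L) == "CC" & !stringi::stri_detect_fixed(trip, "N"))
}

#' Generate a synthetic genome with truth tables
#'
#' Assembles alternating intergenic and gene segments drawn from the spec's
#' base composition, plants identical duplicate copies for the requested
#' fraction of genes, and (when `contig_split` is set) derives a draft
#' version by cutting the sequence at intergenic midpoints. Truth tables
#' record the planted duplications and an independent naive per-gene PAM
#' count.
#'
#' @param spec A [synthetic_genome_spec()].
#' @param promoter_len Promoter window used when building the returned
#'   `genome_model`.
#' @param dir Optional directory; when given, writes `genome.fasta`,
#'   `genes.tsv` and, for split specs, `contigs.fasta` / `cds.fasta`.
#' @return A list with `model` (a `genome_model`), `genes` (truth
#'   coordinates), `duplications`, `pam_counts`, `draft` (NULL or a list
#'   with `contigs` and `cds` tibbles) and `spec`.
#' @export
generate_synthetic_genome <- function(spec, promoter_len = 100, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  withr::local_preserve_seed()
  set.seed(spec$rng_seed)

  glr <- spec$gene_length_range
  ilr <- spec$intergenic_length_range
  n_dup <- round(spec$n_genes * spec$duplicated_gene_fraction)

  gene_len <- sample(glr[1]:glr[2], spec$n_genes, replace = TRUE)
  cds_seq <- vapply(gene_len, rand_seq, character(1), gc_target = spec$gc_target)
  gene_id <- sprintf("g%03d", seq_len(spec$n_genes))
  dup_of <- if (n_dup > 0) sort(sample(spec$n_genes, n_dup)) else integer(0)

  dup_ids <- if (n_dup > 0) paste0(gene_id[dup_of], "_dup") else character(0)
  units <- tibble(
    gene_id = c(gene_id, dup_ids),
    cds = c(cds_seq, cds_seq[dup_of]),
    strand = sample(c("+", "-"), spec$n_genes + n_dup, replace = TRUE)
  )
  # shuffle duplicate copies among the tail positions so copies are not
  # adjacent to their originals
  units <- units[c(seq_len(spec$n_genes),
                   spec$n_genes + sample.int(max(n_dup, 1L))[seq_len(n_dup)]), ]

  n_units <- nrow(units)
  inter_len <- sample(ilr[1]:ilr[2], n_units + 1L, replace = TRUE)
  inter_seq <- vapply(inter_len, rand_seq, character(1),
                      gc_target = spec$gc_target)

  segments <- character(2L * n_units + 1L)
  segments[seq(1L, 2L * n_units + 1L, by = 2L)] <- inter_seq
  genomic <- ifelse(units$strand == "+", units$cds, revcomp(units$cds))
  segments[seq(2L, 2L * n_units, by = 2L)] <- genomic
  seg_len <- nchar(segments)
  seg_end <- cumsum(seg_len)
  seg_start <- seg_end - seg_len + 1L
  sequence <- paste(segments, collapse = "")

  gene_rows <- seq(2L, 2L * n_units, by = 2L)
  genes <- tibble(
    gene_id = units$gene_id,
    start = seg_start[gene_rows],
    end = seg_end[gene_rows],
    strand = units$strand
  )
  model <- genome_model(sequence, genes, promoter_len = promoter_len,
                        source_label = sprintf("synthetic_seed%d",
                                               spec$rng_seed))
  duplications <- tibble(original_id = gene_id[dup_of],
                         duplicate_id = dup_ids)
  pam_counts <- tibble(
    gene_id = model$genes$gene_id,
    n_pams = vapply(seq_len(nrow(model$genes)), function(i) {
      naive_pam_count(extract_target_region(model,
                                            model$genes$gene_id[i])$sequence)
    }, integer(1))
  )

  draft <- NULL
  if (!is.null(spec$contig_split)) {
    # cut at midpoints of internal intergenic segments, spread evenly
    internal <- seq(3L, 2L * n_units - 1L, by = 2L)
    n_cuts <- min(spec$contig_split, length(internal))
    pick <- internal[unique(round(seq(1L, length(internal),
                                      length.out = n_cuts)))]
    cuts <- (seg_start[pick] + seg_end[pick]) %/% 2L
    bounds <- c(1L, cuts + 1L)
    ends <- c(cuts, nchar(sequence))
    draft <- list(
      contigs = tibble(
        id = sprintf("contig_%02d", seq_along(bounds)),
        sequence = substring(sequence, bounds, ends)
      ),
      cds = tibble(id = units$gene_id, sequence = units$cds),
      breakpoints = cuts
    )
  }

  out <- list(model = model, genes = genes, duplications = duplications,
              pam_counts = pam_counts, draft = draft, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(model$source_label, sequence, file.path(dir, "genome.fasta"))
    readr::write_tsv(genes, file.path(dir, "genes.tsv"), progress = FALSE)
    if (!is.null(draft)) {
      write_fasta(draft$contigs$id, draft$contigs$sequence,
                  file.path(dir, "contigs.fasta"))
      write_fasta(draft$cds$id, draft$cds$sequence,
                  file.path(dir, "cds.fasta"))
    }
  }
  out
}
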