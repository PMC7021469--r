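# Shared fixture builders. Everything is constructed in code; no files.

# AT-only filler: no G/C (so no PAM can form inside it) and no A/T run
# longer than 2 (so the homopolymer filter never fires on it).
at_filler <- function(n) {
  substr(strrep("AATT", ceiling(n / 4) + 1L), 1L, n)
}

# Single-gene genome: the whole sequence is one plus-strand CDS, so the
# target region equals the genome (promoter window empty when
# promoter_len = 0 or the CDS starts at 1).
single_gene_model <- function(sequence, promoter_len = 0) {
  genome_model(
    sequence,
    tibble::tibble(gene_id = "g1", start = 1L, end = nchar(sequence),
                   strand = "+"),
    promoter_len = promoter_len, source_label = "fixture"
  )
}

# Identity key for guide-set comparisons in genome coordinates.
cand_key <- function(d) {
  paste(d$gene_id, d$strand, d$genome_start, d$genome_end, d$length,
        d$protospacer)
}

# Identity key robust to coordinate shifts (draft concatenation): region-
# relative quantities only.
cand_key_rel <- function(d) {
  paste(d$gene_id, d$strand, d$protospacer, d$pam, d$length,
        round(d$distance_fraction, 9))
}

# Random A/C/G/T string (uniform), independent of the package generator.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A protospacer of given length with an exact number of G/C bases and no
# A/T homopolymer run of 5, ending in a distinctive seed. G and C are kept
# isolated so the protospacer itself contains no GG/CC.
gc_controlled_proto <- function(length, n_gc) {
  stopifnot(n_gc <= floor(length / 2))
  gc <- rep(c("G", "C"), length.out = n_gc)
  out <- character(length)
  at <- strsplit(at_filler(length), "")[[1]]
  pos <- if (n_gc > 0) round(seq(2, length - 1, length.out = n_gc)) else integer(0)
  out[] <- at
  out[pos] <- gc
  paste(out, collapse = "")
}
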