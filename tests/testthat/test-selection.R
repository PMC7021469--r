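# Helpers to run selection on small hand-built genomes.
run_filtered <- function(genome, genes, params = design_params(),
                         promoter_len = 0) {
  m <- genome_model(genome, genes, promoter_len = promoter_len)
  idx <- build_seed_index(genome)
  apply_filters(enumerate_guides(m), params, idx)
}

test_that("per-PAM selection keeps the longest guide meeting the GC minimum", {
  # 8 G/C in the PAM-proximal 20-mer; the two extra 5' bases are A/T, so
  # GC drops from 40% (20-mer) to 38.1% (21) and 36.4% (22)
  proto <- gc_controlled_proto(20, 8)
  genome <- paste0(at_filler(40), proto, "TGG", at_filler(40))
  genes <- tibble::tibble(gene_id = "g1", start = 1L,
                          end = nchar(genome), strand = "+")

  filt <- run_filtered(genome, genes,
                       design_params(gc_min = 35, tss_max_fraction = 1))
  sel <- select_per_pam(filt, 35)
  expect_equal(nrow(sel), 1L)
  expect_equal(sel$length, 22L)    # all three pass GC >= 35

  sel40 <- select_per_pam(filt, 40)
  expect_equal(sel40$length, 20L)  # only the 20-mer reaches 40%

  sel50 <- select_per_pam(filt, 50)
  expect_equal(nrow(sel50), 0L)    # none qualify
})

test_that("top hits rank by TSS proximity with a deterministic tie-break", {
  sel <- tibble::tibble(
    gene_id = "g", strand = c("sense", "antisense", "sense", "sense"),
    pam_offset = c(10L, 60L, 200L, 250L),
    protospacer = c("CCC", "AAA", "BBB", "DDD"),
    distance_fraction = c(0.20, 0.05, 0.25, 0.05),
    length = 20L, pam = "TGG", gc_percent = 50,
    genome_start = 1L, genome_end = 20L,
    footprint_start = 1L, footprint_end = 23L
  )
  top <- rank_top_hits(sel, max_n = 3)
  expect_equal(top$rank, 1:3)
  # ties at 0.05 break by (strand, protospacer): antisense/AAA before sense/DDD
  expect_equal(top$protospacer, c("AAA", "DDD", "CCC"))
  top1 <- rank_top_hits(sel, max_n = 1)
  expect_equal(nrow(top1), 1L)
  expect_equal(top1$protospacer, "AAA")
})

test_that("pairs require the configured footprint gap", {
  g <- function(proto, fs, df) tibble::tibble(
    gene_id = "g", protospacer = proto, pam = "TGG", length = 20L,
    strand = "sense", genome_start = fs, genome_end = fs + 19L,
    footprint_start = fs, footprint_end = fs + 22L,
    distance_fraction = df, gc_percent = 50
  )
  # two guides, footprints 0..22 and 173..195 at offset: gap = 150
  two <- dplyr::bind_rows(g("AAA", 1L, 0.01), g("CCC", 174L, 0.20))
  pr <- build_pairs(two, min_sep = 100)
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$separation, 174L - 23L - 1L)
  expect_equal(pr$a_protospacer, "AAA") # TSS-proximal member first
  expect_equal(nrow(build_pairs(two, min_sep = 151)), 0L)

  # overlapping guides never pair
  ovl <- dplyr::bind_rows(g("AAA", 1L, 0.01), g("CCC", 10L, 0.05))
  expect_equal(nrow(build_pairs(ovl, min_sep = 100)), 0L)

  # three mutually distant guides give all three pairs, ordered by the
  # TSS distances of (guide_a, guide_b)
  three <- dplyr::bind_rows(g("AAA", 1L, 0.01), g("CCC", 500L, 0.20),
                            g("TTT", 1000L, 0.40))
  pr3 <- build_pairs(three, min_sep = 100)
  expect_equal(nrow(pr3), 3L)
  expect_equal(pr3$a_protospacer, c("AAA", "AAA", "CCC"))
  expect_equal(pr3$b_protospacer, c("CCC", "TTT", "TTT"))
  # fewer than 2 guides: no pairs
  expect_equal(nrow(build_pairs(g("AAA", 1L, 0.01), 100)), 0L)
})

test_that("iteration recovers a gene whose only guide sits in the relaxed GC band", {
  proto <- gc_controlled_proto(20, 6)  # 30% GC exactly; 21/22-mers below 30
  gene_seq <- paste0(proto, "TGG", at_filler(100))
  genome <- paste0(at_filler(40), gene_seq, at_filler(40))
  genes <- tibble::tibble(gene_id = "g1", start = 41L,
                          end = 40L + nchar(gene_seq), strand = "+")
  params <- design_params()
  filt <- run_filtered(genome, genes, params, promoter_len = 30)
  expect_equal(nrow(select_per_pam(filt, params$gc_min)), 0L)
  it <- iterate_relaxations(filt, params, "g1")
  expect_equal(unname(it$recovered_labels["g1"]), "GC")
  expect_equal(it$recovered$protospacer, proto)
  expect_equal(it$recovered$iteration_label, "GC")
  expect_length(it$genes_still_without_guides, 0)
  expect_equal(sum(it$report$genes_recovered), 1L)
})

test_that("a PAM-free gene survives no relaxation; homopolymer+offtarget combos work", {
  # gene A: no PAM at all. gene B: single guide with an A-run AND a seed
  # duplicated elsewhere (different full protospacer) -> needs
  # homopolymer+offtarget together.
  protoB <- paste0("AAAAA", "CGATCGTACGATCGT")  # 50% GC, A-run of 5
  seed12 <- substr(protoB, 9, 20)
  decoy <- paste0("ATCTATAC", seed12)           # same seed, other 20-mer
  geneA <- at_filler(120)
  geneB <- paste0(protoB, "TGG", at_filler(80))
  genome <- paste0(at_filler(30), geneA, at_filler(20), geneB,
                   at_filler(20), decoy, "AGG", at_filler(30))
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"),
    start = c(31L, 31L + 120L + 20L),
    end = c(150L, 30L + 120L + 20L + nchar(geneB)),
    strand = "+"
  )
  params <- design_params()
  filt <- run_filtered(genome, genes, params)
  expect_equal(nrow(select_per_pam(filt, params$gc_min)), 0L)
  it <- iterate_relaxations(filt, params, c("gA", "gB"))
  expect_equal(it$genes_still_without_guides, "gA")
  expect_equal(unname(it$recovered_labels["gB"]), "homopolymer+offtarget")
})
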