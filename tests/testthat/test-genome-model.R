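test_that("promoter windows extend upstream in gene orientation and clip at boundaries", {
  seq <- strrep("ACGT", 2500) # 10 kb
  genes <- tibble::tibble(
    gene_id = c("plus_mid", "minus_mid", "plus_edge"),
    start = c(2001L, 5001L, 1L),
    end = c(2900L, 5900L, 300L),
    strand = c("+", "-", "+")
  )
  m <- genome_model(seq, genes, promoter_len = 100)
  expect_equal(nrow(m$genes), 3L)

  g <- m$genes[m$genes$gene_id == "plus_mid", ]
  expect_equal(c(g$promoter_start, g$promoter_end), c(1901L, 2000L))

  g <- m$genes[m$genes$gene_id == "minus_mid", ]
  expect_equal(c(g$promoter_start, g$promoter_end), c(5901L, 6000L))

  # nothing upstream of coordinate 1: empty window (end < start)
  g <- m$genes[m$genes$gene_id == "plus_edge", ]
  expect_equal(c(g$promoter_start, g$promoter_end), c(1L, 0L))
  expect_lt(g$promoter_end, g$promoter_start)
})

test_that("target regions read promoter->CDS 5'->3' with the right tss_offset", {
  set.seed(11)
  seq <- random_dna(10000)
  genes <- tibble::tibble(
    gene_id = c("p", "m", "clipped"),
    start = c(1001L, 5001L, 41L),
    end = c(1300L, 5900L, 400L),
    strand = c("+", "-", "+")
  )
  m <- genome_model(seq, genes, promoter_len = 100)

  rp <- extract_target_region(m, "p")
  expect_equal(nchar(rp$sequence), 100 + 300)
  expect_equal(rp$tss_offset, 100)
  expect_equal(rp$sequence, substr(seq, 901, 1300))

  rm_ <- extract_target_region(m, "m")
  expect_equal(nchar(rm_$sequence), 100 + 900)
  expect_equal(rm_$sequence, revcomp(substr(seq, 5001, 6000)))

  rc <- extract_target_region(m, "clipped")
  expect_equal(rc$tss_offset, 40)
  expect_equal(nchar(rc$sequence), 40 + 360)

  # invariant: region length = realized promoter + cds_length, all genes
  for (i in seq_len(nrow(m$genes))) {
    g <- m$genes[i, ]
    r <- extract_target_region(m, g$gene_id)
    expect_equal(nchar(r$sequence),
                 max(0, g$promoter_end - g$promoter_start + 1) + g$cds_length)
  }
})

test_that("genome_stats computes GC over A/C/G/T only", {
  gm <- function(s) genome_stats(single_gene_model(s))
  expect_equal(gm("ATGC"), tibble::tibble(size = 4L, gc_percent = 50))
  expect_equal(gm("ATAT")$gc_percent, 0)
  expect_equal(gm("GCNN"), tibble::tibble(size = 4L, gc_percent = 100))
  expect_true(is.na(gc_fraction("NNNN")))
})

test_that("gc_fraction is invariant under reverse complementation", {
  set.seed(5)
  for (i in 1:20) {
    s <- random_dna(sample(50:500, 1))
    expect_equal(gc_fraction(revcomp(s)), gc_fraction(s))
  }
})

test_that("GenBank CDS parsing handles strands, joins, qualifiers and length checks", {
  gbk <- c(
    "LOCUS       TESTSEQ                 600 bp    DNA     circular BCT 01-JAN-2020",
    "DEFINITION  synthetic test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..600",
    "                     /organism=\"synthetic\"",
    "     CDS             11..100",
    "                     /locus_tag=\"tag_one\"",
    "                     /product=\"hypothetical protein\"",
    "     CDS             complement(201..350)",
    "                     /gene=\"genB\"",
    "     CDS             join(401..450,461..520)",
    "                     /locus_tag=\"tag_join\"",
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    "//"
  )
  gbk_path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(gbk, gbk_path)
  expect_warning(tbl <- read_genbank_cds(gbk_path), "outermost span")
  expect_equal(tbl$gene_id, c("tag_one", "genB", "tag_join"))
  expect_equal(tbl$start, c(11L, 201L, 401L))
  expect_equal(tbl$end, c(100L, 350L, 520L))
  expect_equal(tbl$strand, c("+", "-", "+"))
  expect_equal(attr(tbl, "locus_length"), 600L)

  fa_ok <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">TESTSEQ", strrep("ACGTACGTAC", 60)), fa_ok)
  m <- suppressWarnings(load_complete_genome(gbk_path, fa_ok, promoter_len = 10))
  expect_s3_class(m, "genome_model")
  expect_equal(nrow(m$genes), 3L)

  fa_bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">TESTSEQ", strrep("ACGT", 100)), fa_bad)
  expect_error(suppressWarnings(load_complete_genome(gbk_path, fa_bad)),
               class = "guidebac_consistency_error")
})

test_that("invalid gene records are skipped with a warning, fatal errors are fatal", {
  seq <- random_dna(1000)
  genes <- tibble::tibble(
    gene_id = c("ok", "reversed", "na"),
    start = c(101L, 500L, NA),
    end = c(400L, 400L, 300L),
    strand = c("+", "+", "-")
  )
  expect_warning(m <- genome_model(seq, genes), "skipped")
  expect_equal(m$genes$gene_id, "ok")
  expect_error(
    genome_model(seq, tibble::tibble(gene_id = "far", start = 900L,
                                     end = 1200L, strand = "+")),
    class = "guidebac_consistency_error")
  expect_error(load_complete_genome("missing.tsv", "missing.fasta"),
               class = "guidebac_input_error")
})

test_that("gene table round-trips through TSV with identical coordinates", {
  set.seed(21)
  syn <- generate_synthetic_genome(synthetic_genome_spec(n_genes = 8,
                                                         rng_seed = 3))
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "genes.tsv")
  fa <- file.path(dir, "genome.fasta")
  write_gene_table(syn$model, tsv)
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(syn$model$sequence), "syn"), fa)
  re <- load_complete_genome(tsv, fa, promoter_len = 100)
  expect_equal(re$genes[, c("gene_id", "cds_start", "cds_end", "strand",
                            "promoter_start", "promoter_end")],
               syn$model$genes[, c("gene_id", "cds_start", "cds_end", "strand",
                                   "promoter_start", "promoter_end")])
})
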