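test_that("PAM scanning finds NGG on both strands and skips N windows", {
  expect_equal(nrow(scan_pams("")), 0L)
  expect_equal(nrow(scan_pams("TTTTTT")), 0L)

  # exhaustively verified by hand: TAGGA has a single sense AGG at offset 1
  s <- scan_pams("TAGGA")
  expect_equal(nrow(s), 1L)
  expect_equal(s$strand, "sense")
  expect_equal(s$pam_offset, 1L)
  expect_equal(s$pam, "AGG")

  # CCA on the forward strand is an antisense TGG PAM
  a <- scan_pams("TCCAT")
  expect_equal(a$strand, "antisense")
  expect_equal(a$pam, "TGG")
  expect_equal(a$pam_offset, 3L) # 0-based offset of the PAM's 5'-most base

  # N inside the trinucleotide suppresses the site
  expect_equal(nrow(scan_pams("TNGGA")), 0L)
  expect_equal(nrow(scan_pams("GGG")), 1L) # GGG: one full NGG window
})

test_that("candidates per PAM depend on available upstream bases", {
  proto22 <- gc_controlled_proto(22, 9)
  # >= 22 clean upstream bases: all three lengths
  r1 <- paste0(proto22, "TGG")
  cand <- make_candidates(r1, scan_pams(r1))
  expect_equal(sort(cand$length), c(20L, 21L, 22L))
  expect_equal(cand$protospacer[cand$length == 22], proto22)
  expect_equal(cand$protospacer[cand$length == 20], substr(proto22, 3, 22))
  expect_true(all(cand$seed == substr(proto22, 11, 22)))

  # exactly 20 upstream bases: only the 20-mer
  r2 <- paste0(substr(proto22, 3, 22), "TGG")
  cand2 <- make_candidates(r2, scan_pams(r2))
  cand2 <- cand2[cand2$strand == "sense", ]
  expect_equal(cand2$length, 20L)

  # 10 upstream bases: nothing of adequate length
  r3 <- paste0(substr(proto22, 13, 22), "TGG")
  cand3 <- make_candidates(r3, scan_pams(r3))
  expect_equal(nrow(cand3[cand3$strand == "sense", ]), 0L)

  # N inside the window suppresses the candidate at that length only
  r4 <- paste0("N", substr(proto22, 2, 22), "TGG")
  cand4 <- make_candidates(r4, scan_pams(r4))
  expect_equal(sort(cand4$length[cand4$strand == "sense"]), c(20L, 21L))
})

test_that("scanner+maker equals brute-force enumeration on random regions", {
  set.seed(31)
  for (i in 1:12) {
    region <- random_dna(sample(200:1200, 1))
    got <- make_candidates(region)
    want <- naive_region_candidates(region)
    key <- function(d) paste(d$strand, d$length, d$region_off5, d$protospacer,
                             d$pam)
    expect_setequal(key(got), key(want))
  }
  # also with Ns sprinkled in
  region <- random_dna(800)
  substr(region, 100, 104) <- "NNNNN"
  substr(region, 500, 500) <- "N"
  key <- function(d) paste(d$strand, d$length, d$region_off5, d$protospacer)
  expect_setequal(key(make_candidates(region)),
                  key(naive_region_candidates(region)))
})

test_that("reverse-complementing a region swaps strands but keeps protospacers", {
  set.seed(32)
  region <- random_dna(600)
  fwd <- make_candidates(region)
  rev <- make_candidates(revcomp(region))
  expect_equal(sort(fwd$protospacer[fwd$strand == "sense"]),
               sort(rev$protospacer[rev$strand == "antisense"]))
  expect_equal(sort(fwd$protospacer[fwd$strand == "antisense"]),
               sort(rev$protospacer[rev$strand == "sense"]))
})

test_that("genomic coordinates of candidates point at their protospacers", {
  set.seed(33)
  syn <- generate_synthetic_genome(synthetic_genome_spec(n_genes = 6,
                                                         rng_seed = 9))
  cand <- enumerate_guides(syn$model)
  expect_gt(nrow(cand), 0)
  strand_tbl <- syn$model$genes[match(cand$gene_id, syn$model$genes$gene_id), ]
  slice <- substring(syn$model$sequence, cand$genome_start, cand$genome_end)
  # genome-forward orientation of each protospacer depends on gene strand
  # XOR candidate strand
  fwd_orient <- (strand_tbl$strand == "+") == (cand$strand == "sense")
  expect_equal(ifelse(fwd_orient, cand$protospacer, revcomp(cand$protospacer)),
               slice)
  expect_equal(cand$genome_end - cand$genome_start + 1L, cand$length)
  # footprint = protospacer + PAM
  expect_true(all(cand$footprint_end - cand$footprint_start + 1L ==
                    cand$length + 3L))
})
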