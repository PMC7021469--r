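test_that("GC and homopolymer predicates behave on the canonical cases", {
  expect_equal(gc_fraction(strrep("AT", 10)), 0)
  expect_equal(gc_fraction(strrep("GC", 10)), 100)
  expect_equal(gc_fraction(strrep("ATGC", 5)), 50)

  expect_true(has_at_homopolymer("AAAAA", 5))
  expect_true(has_at_homopolymer("GCGTTTTTGCA", 5))
  expect_false(has_at_homopolymer("GGGGGGG", 5)) # only A and T runs count
  expect_false(has_at_homopolymer("ATATATAT", 5))
  expect_false(has_at_homopolymer("AAAATTTT", 5)) # runs must be one letter
  expect_true(has_at_homopolymer("AAAA", 4))
})

test_that("bad seed matching is positional at the 5 PAM-proximal bases", {
  proto <- paste0(at_filler(15), "ACCCA")
  expect_true(matches_bad_seed(proto, "ACCCA"))
  expect_false(matches_bad_seed(proto, character()))
  # internal occurrence does not fire the positional filter
  proto2 <- paste0(at_filler(5), "ACCCA", at_filler(10))
  expect_false(matches_bad_seed(proto2, "ACCCA"))
  expect_true(matches_bad_seed(proto2, "ACCCA", substring = TRUE))
})

test_that("restriction sites are recognized on either strand", {
  g <- paste0(at_filler(8), "GGATCC", at_filler(9)) # BamHI, palindromic
  expect_true(contains_restriction_site(g, "GGATCC"))
  expect_false(contains_restriction_site(g, character()))
  # a non-palindromic site present only as its reverse complement
  g2 <- paste0(at_filler(8), revcomp("GACGTC"), at_filler(9))
  expect_true(contains_restriction_site(g2, "GACGTC"))
  expect_false(contains_restriction_site(at_filler(23), "GGATCC"))
})

test_that("TSS distance fractions are signed, inclusive at the threshold, and promoter guides pass", {
  # one + gene: 100 bp promoter then 500 bp CDS, PAMs planted at known spots
  proto <- gc_controlled_proto(20, 8)
  cds <- paste0(
    substr(at_filler(504), 1, 150), proto, "TGG",          # starts 150 into CDS
    substr(at_filler(1000), 1, 500 - 150 - 23))
  promoter <- paste0(substr(at_filler(100), 1, 77), proto, "AGG")
  genome <- paste0(promoter, cds)
  m <- genome_model(genome, tibble::tibble(gene_id = "g1", start = 101L,
                                           end = 600L, strand = "+"),
                    promoter_len = 100)
  cand <- enumerate_guides(m)
  cand20 <- cand[cand$length == 20 & cand$strand == "sense", ]
  expect_equal(nrow(cand20), 2L)
  df <- sort(cand20$distance_fraction)
  expect_lt(df[1], 0)                         # promoter guide
  expect_equal(df[2], 150 / 500)              # 150 bases into a 500-base CDS
  idx <- build_seed_index(genome)
  filt <- apply_filters(cand, design_params(tss_max_fraction = 0.30), idx)
  f20 <- filt[filt$length == 20 & filt$strand == "sense", ]
  expect_true(all(f20$pass_tss))              # inclusive boundary at 0.30
  filt2 <- apply_filters(cand, design_params(tss_max_fraction = 0.29), idx)
  f20b <- filt2[filt2$length == 20 & filt2$strand == "sense", ]
  expect_equal(sum(!f20b$pass_tss), 1L)
})

test_that("apply_filters produces complete verdicts and honors the homopolymer switch", {
  homo_proto <- paste0(gc_controlled_proto(13, 6), "TAAAAAT")
  region <- paste0(at_filler(20), homo_proto, "TGG", at_filler(40))
  m <- single_gene_model(region)
  idx <- build_seed_index(region)
  cand <- enumerate_guides(m)
  cand <- cand[cand$length == 20 & cand$strand == "sense", ]
  expect_equal(cand$protospacer, homo_proto)

  strict <- apply_filters(cand, design_params(), idx)
  expect_false(strict$accepted)
  expect_false(strict$pass_homopolymer)
  relaxed <- apply_filters(cand, design_params(homopolymer_filter_on = FALSE),
                           idx)
  expect_true(relaxed$accepted)
  expect_false(relaxed$pass_homopolymer) # verdict still recorded

  needed <- c("pass_length", "pass_homopolymer", "pass_gc", "pass_tss",
              "pass_bad_seed", "pass_restriction", "pass_offtarget",
              "strict_count", "relaxed_count", "accepted")
  expect_true(all(needed %in% names(strict)))
})

test_that("candidates with duplicated seeds are rejected; an all-pass candidate is accepted", {
  set.seed(52)
  syn <- generate_synthetic_genome(
    synthetic_genome_spec(n_genes = 8, duplicated_gene_fraction = 0.25,
                          rng_seed = 6))
  idx <- build_seed_index(syn$model)
  filt <- apply_filters(enumerate_guides(syn$model), design_params(), idx)
  dups <- filt[filt$strict_count >= 2, ]
  expect_gt(nrow(dups), 0)
  expect_false(any(dups$accepted))
  clean <- filt[filt$strict_count == 1 & filt$pass_homopolymer &
                  filt$pass_tss & filt$pass_bad_seed, ]
  expect_true(all(clean$accepted))
})

test_that("relaxing any single parameter never shrinks the accepted set", {
  syn <- generate_synthetic_genome(
    synthetic_genome_spec(n_genes = 12, gc_target = 38,
                          duplicated_gene_fraction = 0.2, rng_seed = 8))
  idx <- build_seed_index(syn$model)
  cand <- enumerate_guides(syn$model)
  base <- design_params()
  accept_set <- function(p) {
    filt <- apply_filters(cand, p, idx)
    sel <- select_per_pam(filt, p$gc_min)
    list(acc = cand_key(filt[filt$accepted, ]),
         genes = unique(sel$gene_id))
  }
  a0 <- accept_set(base)
  for (r in c("GC", "TSS", "homopolymer", "offtarget")) {
    a1 <- accept_set(guidebac:::relax_params(base, r))
    expect_true(all(a0$acc %in% a1$acc), label = paste("accepted under", r))
    # note the per-PAM *selected* guide may change (a longer guide becomes
    # admissible), but no gene ever loses guide coverage
    expect_true(all(a0$genes %in% a1$genes),
                label = paste("gene coverage under", r))
  }
})
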