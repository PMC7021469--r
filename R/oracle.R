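# Brute-force oracles: definition-level re-derivations of enumeration,
# off-target counting and end-to-end guide acceptance, used to validate the
# pipeline on fixtures. Every genomic/region window is tested directly with
# substring(); nothing here shares code with the stringi-search or indexed
# implementations.

#' Brute-force guide candidates for one region
#'
#' Tests every (offset, strand, length) triple directly: a window qualifies
#' iff the 3 bases 3'-adjacent to it (in the window's orientation) match NGG
#' and neither window nor PAM contains N. Antisense candidates are derived
#' by running the identical forward logic on the reverse complement and
#' mapping offsets back — strand handling is independent of the scanner's.
#'
#' @param region_sequence Region string.
#' @return Tibble with `strand`, `length`, `protospacer`, `pam`,
#'   `region_off5` (0-based offset of the protospacer's 5'-most region
#'   position).
#' @export
naive_region_candidates <- function(region_sequence) {
  n <- nchar(region_sequence)
  one_strand <- function(seq) {
    res <- list()
    for (L in 20:22) {
      s <- seq_len(max(0L, n - L - 2L))
      if (length(s) == 0L) next
      proto <- substring(seq, s, s + L - 1L)
      pam <- substring(seq, s + L, s + L + 2L)
      ok <- substring(pam, 2L, 3L) == "GG" &
        !stringi::stri_detect_fixed(proto, "N") &
        !stringi::stri_detect_fixed(pam, "N")
      if (any(ok)) {
        res[[length(res) + 1L]] <-
          tibble(length = L, start1 = s[ok], protospacer = proto[ok],
                 pam = pam[ok])
      }
    }
    bind_rows(res)
  }
  fwd <- one_strand(region_sequence)
  rev <- one_strand(revcomp(region_sequence))
  out <- bind_rows(
    if (nrow(fwd)) mutate(fwd, strand = "sense",
                          region_off5 = .data$start1 - 1L),
    if (nrow(rev)) mutate(rev, strand = "antisense",
                          region_off5 = n - .data$start1 - .data$length + 1L)
  )
  if (nrow(out) == 0L) {
    return(tibble(strand = character(), length = integer(),
                  protospacer = character(), pam = character(),
                  region_off5 = integer()))
  }
  out %>%
    mutate(length = as.integer(.data$length),
           region_off5 = as.integer(.data$region_off5)) %>%
    select("strand", "length", "protospacer", "pam", "region_off5")
}

#' Brute-force PAM-adjacent k-mer occurrence tables for a genome
#'
#' Single pass over every genomic window on both strands: position i carries
#' k-mer `genome[i..i+k-1]` iff `genome[i+k..i+k+2]` matches NGG with no N
#' anywhere in k-mer or PAM. Tabulated counts answer off-target queries by
#' direct lookup.
#'
#' @param genome_sequence Genome string.
#' @param ks Window sizes to tabulate.
#' @return Named list (by k) of count tables.
#' @export
naive_kmer_pam_tables <- function(genome_sequence, ks = c(12L, 20L, 21L, 22L)) {
  strands <- c(genome_sequence, revcomp(genome_sequence))
  purrr::map(set_names(as.integer(ks)), function(k) {
    kmers <- character(0)
    for (seq in strands) {
      n <- nchar(seq)
      i <- seq_len(max(0L, n - k - 2L))
      if (length(i) == 0L) next
      km <- substring(seq, i, i + k - 1L)
      pam <- substring(seq, i + k, i + k + 2L)
      ok <- substring(pam, 2L, 3L) == "GG" &
        !stringi::stri_detect_fixed(km, "N") &
        !stringi::stri_detect_fixed(pam, "N")
      kmers <- c(kmers, km[ok])
    }
    tab <- table(kmers)
    list(keys = names(tab), counts = as.integer(tab))
  })
}

#' Brute-force off-target counts
#'
#' @param tables Result of [naive_kmer_pam_tables()] (or a genome string,
#'   tabulated on the fly).
#' @param queries Character vector; each query is counted at its own length.
#' @return Integer vector of genomic occurrence counts (query + NGG, both
#'   strands).
#' @export
naive_offtarget_count <- function(tables, queries) {
  if (is.character(tables) && length(tables) == 1L &&
      !is.list(tables)) {
    tables <- naive_kmer_pam_tables(tables, ks = unique(nchar(queries)))
  }
  k <- nchar(queries)
  out <- integer(length(queries))
  for (kk in unique(k)) {
    tab <- tables[[as.character(kk)]]
    if (is.null(tab)) abort(sprintf("no naive table for k=%d", kk))
    sel <- k == kk
    idx <- match(queries[sel], tab$keys)
    cnt <- tab$counts[idx]
    cnt[is.na(cnt)] <- 0L
    out[sel] <- cnt
  }
  out
}

#' End-to-end brute-force guide derivation for a whole genome
#'
#' Re-derives, from first principles, the accepted guide set and the per-PAM
#' selected set: regions are sliced directly from the gene coordinates,
#' candidates come from [naive_region_candidates()], filters are re-applied
#' with the single-purpose predicates, and off-target counts come from
#' [naive_kmer_pam_tables()].
#'
#' @param model A `genome_model`.
#' @param params A [design_params()].
#' @return List with `accepted` (all accepted candidates), `selected` (per
#'   PAM), and `genes_with_guides` (character vector).
#' @export
naive_guides <- function(model, params) {
  tables <- naive_kmer_pam_tables(model$sequence)
  genes <- model$genes
  all_cands <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    prom_len <- max(0L, g$promoter_end - g$promoter_start + 1L)
    if (g$strand == "+") {
      lo <- if (prom_len > 0L) g$promoter_start else g$cds_start
      region <- substr(model$sequence, lo, g$cds_end)
    } else {
      hi <- if (prom_len > 0L) g$promoter_end else g$cds_end
      region <- revcomp(substr(model$sequence, g$cds_start, hi))
    }
    cand <- naive_region_candidates(region)
    if (nrow(cand) == 0L) return(NULL)
    cand$gene_id <- g$gene_id
    cand$distance_fraction <- (cand$region_off5 - prom_len) / g$cds_length
    # genomic protospacer coordinates, derived from region bounds
    o1 <- cand$region_off5
    o2 <- cand$region_off5 + cand$length - 1L
    if (g$strand == "+") {
      lo <- if (prom_len > 0L) g$promoter_start else g$cds_start
      cand$genome_start <- lo + o1
      cand$genome_end <- lo + o2
    } else {
      hi <- if (prom_len > 0L) g$promoter_end else g$cds_end
      cand$genome_start <- hi - o2
      cand$genome_end <- hi - o1
    }
    cand
  }) %>% bind_rows()

  if (nrow(all_cands) == 0L) {
    return(list(accepted = all_cands, selected = all_cands,
                genes_with_guides = character(0)))
  }
  all_cands$gc_percent <- gc_fraction(all_cands$protospacer)
  seed12 <- substring(all_cands$protospacer, all_cands$length - 11L,
                      all_cands$length)
  query <- if (params$offtarget_mode == "strict") seed12 else
    all_cands$protospacer
  ot <- naive_offtarget_count(tables, query)

  pass <- all_cands$length >= 20L &
    (!params$homopolymer_filter_on |
       !has_at_homopolymer(all_cands$protospacer, params$homopolymer_run)) &
    all_cands$distance_fraction <= params$tss_max_fraction &
    !matches_bad_seed(all_cands$protospacer, params$bad_seeds,
                      substring = params$bad_seed_substring) &
    !contains_restriction_site(paste0(all_cands$protospacer, all_cands$pam),
                               params$restriction_sites) &
    ot < 2L

  accepted <- all_cands[pass, ]
  # PAM site identity: 0-based region offset of the PAM's 5'-most base in
  # guide orientation (adjacent to the protospacer's 3' end)
  pam_off <- ifelse(accepted$strand == "sense",
                    accepted$region_off5 + accepted$length,
                    accepted$region_off5 - 1L)
  selected <- accepted %>%
    mutate(.pam_site = pam_off) %>%
    filter(.data$gc_percent >= params$gc_min) %>%
    group_by(.data$gene_id, .data$strand, .data$.pam_site) %>%
    slice_max(.data$length, n = 1L, with_ties = FALSE) %>%
    ungroup() %>%
    select(-".pam_site")
  list(accepted = accepted, selected = selected,
       genes_with_guides = sort(unique(selected$gene_id)))
}
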