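# Guide enumeration: scan a target region (promoter + CDS, gene orientation)
# for NGG PAM sites on both strands and emit candidates of lengths 20-22 per
# PAM. The PAM pattern is a single declared constant so alternative PAMs can
# be swapped in by editing one place.

PAM_CORE <- "GG"        # NGG on the reported strand
PAM_CORE_RC <- "CC"     # its appearance on the opposite strand
GUIDE_LENGTHS <- 20:22
SEED_LEN <- 12L

#' Scan a region for NGG PAM sites on both strands
#'
#' Sense sites are NGG read directly on the region string; antisense sites
#' are NGG on the reverse complement (CCN on the region string). `pam_offset`
#' is the 0-based offset, in region coordinates, of the PAM's 5'-most base in
#' the orientation of the reported protospacer. Trinucleotides extending past
#' the region or containing N never match.
#'
#' @param region_sequence Region string (A/C/G/T/N).
#' @return Tibble with columns `strand` (`"sense"`/`"antisense"`),
#'   `pam_offset` and `pam` (the trinucleotide in protospacer orientation).
#' @export
scan_pams <- function(region_sequence) {
  n <- nchar(region_sequence)
  empty <- tibble(strand = character(), pam_offset = integer(),
                  pam = character())
  if (n < 3L) return(empty)

  gg <- stringi::stri_locate_all_fixed(region_sequence, PAM_CORE,
                                       overlap = TRUE)[[1]][, 1]
  gg <- gg[!is.na(gg)]
  p <- gg[gg >= 2L] - 1L            # 1-based position of the PAM's N
  pam_s <- substr_vec(region_sequence, p, p + 2L)
  keep <- !stringi::stri_detect_fixed(pam_s, "N")
  sense <- tibble(strand = "sense", pam_offset = as.integer(p[keep] - 1L),
                  pam = pam_s[keep])

  cc <- stringi::stri_locate_all_fixed(region_sequence, PAM_CORE_RC,
                                       overlap = TRUE)[[1]][, 1]
  cc <- cc[!is.na(cc)]
  j <- cc[cc + 2L <= n]             # CCN triplet at j..j+2
  trip <- substr_vec(region_sequence, j, j + 2L)
  keep <- !stringi::stri_detect_fixed(trip, "N")
  anti <- tibble(strand = "antisense",
                 pam_offset = as.integer(j[keep] + 1L),  # 0-based of pos j+2
                 pam = revcomp(trip[keep]))

  bind_rows(sense, anti)
}

#' Create 0-3 guide candidates per PAM site
#'
#' For each site and each length L in 20, 21, 22: if L bases exist 5'-adjacent
#' to the PAM in the site's orientation and the window contains no N, one
#' candidate is emitted. Offsets in the result are 0-based region
#' coordinates: `region_off5`/`region_off3` bound the protospacer and
#' `fp_off5`/`fp_off3` bound the occupied footprint (protospacer + PAM).
#' The `seed` is the 12 PAM-proximal protospacer bases.
#'
#' @param region A `target_region` (or any list with a `sequence` field), or
#'   a plain region string.
#' @param sites Tibble of PAM sites from [scan_pams()]; scanned afresh when
#'   omitted. May be a single-row tibble to expand one site.
#' @return Tibble of candidates: `strand`, `pam_offset`, `pam`, `length`,
#'   `protospacer`, `seed`, `region_off5`, `region_off3`, `fp_off5`,
#'   `fp_off3`.
#' @export
make_candidates <- function(region, sites = NULL) {
  seq <- if (is.list(region)) region$sequence else region
  if (is.null(sites)) sites <- scan_pams(seq)
  n <- nchar(seq)
  empty <- tibble(strand = character(), pam_offset = integer(),
                  pam = character(), length = integer(),
                  protospacer = character(), seed = character(),
                  region_off5 = integer(), region_off3 = integer(),
                  fp_off5 = integer(), fp_off3 = integer())
  if (nrow(sites) == 0L) return(empty)

  cand <- tidyr::crossing(sites, length = as.integer(GUIDE_LENGTHS))
  p1 <- cand$pam_offset + 1L      # 1-based position of PAM 5'-most base
  L <- cand$length
  sense <- cand$strand == "sense"

  # 1-based protospacer window on the forward region string; for antisense
  # sites the CCN triplet ends at p1, so the protospacer starts at p1 + 1
  w_start <- ifelse(sense, p1 - L, p1 + 1L)
  w_end <- ifelse(sense, p1 - 1L, p1 + L)
  feasible <- w_start >= 1L & w_end <= n
  cand <- cand[feasible, ]
  if (nrow(cand) == 0L) return(empty)
  w_start <- w_start[feasible]
  w_end <- w_end[feasible]
  sense <- sense[feasible]

  fwd <- substring(seq, w_start, w_end)
  clean <- !stringi::stri_detect_fixed(fwd, "N")
  cand <- cand[clean, ]
  if (nrow(cand) == 0L) return(empty)

  proto <- ifelse(sense[clean], fwd[clean], revcomp(fwd[clean]))
  cand$protospacer <- proto
  cand$seed <- substring(proto, cand$length - SEED_LEN + 1L, cand$length)
  cand$region_off5 <- as.integer(w_start[clean] - 1L)
  cand$region_off3 <- as.integer(w_end[clean] - 1L)
  cand$fp_off5 <- as.integer(ifelse(sense[clean], cand$region_off5,
                                    cand$region_off5 - 3L))
  cand$fp_off3 <- as.integer(ifelse(sense[clean], cand$region_off3 + 3L,
                                    cand$region_off3))
  cand
}

empty_guides_tbl <- function() {
  tibble(gene_id = character(), protospacer = character(), pam = character(),
         length = integer(), strand = character(), pam_offset = integer(),
         region_off5 = integer(), genome_start = integer(),
         genome_end = integer(), footprint_start = integer(),
         footprint_end = integer(), distance_fraction = numeric(),
         gc_percent = numeric(), seed = character())
}

# Map region-coordinate candidates of one gene onto genome coordinates and
# attach per-candidate metrics (TSS distance fraction, GC).
candidates_for_gene <- function(model, gene) {
  region <- extract_target_region(model, gene)
  cand <- make_candidates(region)
  if (nrow(cand) == 0L) return(empty_guides_tbl())
  if (region$strand == "+") {
    rs <- region$genome_start
    cand$genome_start <- rs + cand$region_off5
    cand$genome_end <- rs + cand$region_off3
    cand$footprint_start <- rs + cand$fp_off5
    cand$footprint_end <- rs + cand$fp_off3
  } else {
    re <- region$genome_end
    cand$genome_start <- re - cand$region_off3
    cand$genome_end <- re - cand$region_off5
    cand$footprint_start <- re - cand$fp_off3
    cand$footprint_end <- re - cand$fp_off5
  }
  cand$gene_id <- region$gene_id
  cand$distance_fraction <-
    (cand$region_off5 - region$tss_offset) / region$cds_length
  cand$gc_percent <- gc_fraction(cand$protospacer)
  select(cand, "gene_id", "protospacer", "pam", "length", "strand",
         "pam_offset", "region_off5", "genome_start", "genome_end",
         "footprint_start", "footprint_end", "distance_fraction",
         "gc_percent", "seed")
}

#' Enumerate raw guide candidates for every gene of a model
#'
#' Runs [scan_pams()] and [make_candidates()] over each gene's promoter + CDS
#' region and maps candidates onto 1-based genomic coordinates
#' (protospacer-only; the occupied footprint including the PAM is carried in
#' `footprint_start`/`footprint_end` for pair spacing). Enumeration is
#' parameter-free: filtering happens downstream in [apply_filters()].
#'
#' @param model A `genome_model`.
#' @param genes Optional character vector restricting to some `gene_id`s.
#' @return Tibble of raw candidates, one row per (PAM site, length).
#' @export
enumerate_guides <- function(model, genes = NULL) {
  tbl <- model$genes
  if (!is.null(genes)) tbl <- filter(tbl, .data$gene_id %in% genes)
  out <- purrr::map(seq_len(nrow(tbl)),
                    function(i) candidates_for_gene(model, tbl[i, ])) %>%
    bind_rows()
  if (nrow(out) == 0L) empty_guides_tbl() else out
}
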