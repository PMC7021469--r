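# Off-target counting against the genome in use (never a reference): a
# both-strand occurrence index over the k-mers immediately 5'-adjacent to
# every NGG PAM site. Strict queries use the 12-base PAM-proximal seed;
# relaxed queries use the full 20-22 base protospacer. In both cases the NGG
# PAM is additionally required at the matching position (N of the PAM matches
# any base, but literal N characters in the genome never match).

# PAM-proximal contexts (up to 22 bases, N-truncated) for every PAM site on
# both strands. The last L characters of a context are the length-L
# protospacer that would target that site.
pam_contexts <- function(sequence) {
  n <- nchar(sequence)
  ctx <- character(0)
  if (n >= 3L) {
    gg <- stringi::stri_locate_all_fixed(sequence, PAM_CORE,
                                         overlap = TRUE)[[1]][, 1]
    gg <- gg[!is.na(gg)]
    p <- gg[gg >= 2L] - 1L                       # PAM N position, forward
    p <- p[substr_vec(sequence, p, p) != "N"]
    fwd <- substr_vec(sequence, pmax(1L, p - 22L), p - 1L)

    cc <- stringi::stri_locate_all_fixed(sequence, PAM_CORE_RC,
                                         overlap = TRUE)[[1]][, 1]
    cc <- cc[!is.na(cc)]
    j <- cc[cc + 2L <= n]
    j <- j[substr_vec(sequence, j + 2L, j + 2L) != "N"]
    rev <- revcomp(substr_vec(sequence, j + 3L, pmin(n, j + 24L)))

    ctx <- c(fwd, rev)
    # keep only the PAM-proximal run free of N
    ctx <- sub(".*N", "", ctx)
  }
  ctx
}

count_table <- function(x) {
  tab <- table(x)
  list(keys = names(tab), counts = as.integer(tab))
}

lookup_counts <- function(tab, q) {
  idx <- match(q, tab$keys)
  out <- tab$counts[idx]
  out[is.na(out)] <- 0L
  out
}

#' Build a both-strand off-target occurrence index over a genome
#'
#' Indexes, for every NGG PAM site on either strand, the 12-mer seed and the
#' 20/21/22-mer protospacer contexts adjacent to it. Counting includes every
#' genuine candidate's own site (so a real candidate always queries to at
#' least 1); occurrences on the reverse strand are counted in their own
#' orientation, never double-counted.
#'
#' @param genome_sequence Genome string, or a `genome_model`.
#' @param genome_label Label stored with the index.
#' @return An object of class `"seed_index"`.
#' @export
build_seed_index <- function(genome_sequence, genome_label = "genome") {
  if (inherits(genome_sequence, "genome_model")) {
    genome_label <- genome_sequence$source_label
    genome_sequence <- genome_sequence$sequence
  }
  stopifnot(nzchar(genome_sequence))
  ctx <- pam_contexts(genome_sequence)
  len <- nchar(ctx)
  tables <- purrr::map(set_names(c(SEED_LEN, GUIDE_LENGTHS)), function(k) {
    ok <- len >= k
    count_table(substr_vec(ctx[ok], len[ok] - k + 1L, len[ok]))
  })
  structure(
    list(genome_label = genome_label, n_sites = length(ctx), tables = tables),
    class = "seed_index"
  )
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("<seed_index> %s: %d PAM sites indexed\n",
              x$genome_label, x$n_sites))
  invisible(x)
}

#' Count genomic off-target occurrences for guide candidates
#'
#' Strict mode counts occurrences of the 12-base PAM-proximal seed followed
#' by NGG; relaxed mode counts occurrences of the full protospacer followed
#' by NGG. A candidate passes off-target filtering iff its count is below 2
#' (two or more genomic locations means discard).
#'
#' @param index A `seed_index` built over the same genome.
#' @param candidate A candidates tibble from [enumerate_guides()], or a
#'   character vector of query sequences (for strict mode, the last 12 bases
#'   of each query are used).
#' @param mode `"strict"` or `"relaxed"`.
#' @return Integer vector of occurrence counts, one per candidate.
#' @export
offtarget_count <- function(index, candidate,
                            mode = c("strict", "relaxed")) {
  mode <- arg_match(mode)
  if (is.data.frame(candidate)) {
    q <- if (mode == "strict") candidate$seed else candidate$protospacer
  } else {
    q <- toupper(candidate)
    if (mode == "strict") {
      q <- substr_vec(q, pmax(1L, nchar(q) - SEED_LEN + 1L), nchar(q))
    }
  }
  if (length(q) == 0L) return(integer(0))
  k <- nchar(q)
  if (mode == "strict" && any(k != SEED_LEN)) {
    abort("strict queries must be 12-mers", class = "guidebac_param_error")
  }
  if (mode == "relaxed" && !all(as.character(k) %in% names(index$tables))) {
    abort("relaxed queries must be 20-22-mers", class = "guidebac_param_error")
  }
  out <- integer(length(q))
  for (kk in unique(k)) {
    sel <- k == kk
    out[sel] <- lookup_counts(index$tables[[as.character(kk)]], q[sel])
  }
  out
}
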