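# Sequence/position filters. Each predicate is a small, single-purpose,
# vectorised function so that final outputs can be re-audited independently
# of the pipeline that produced them.

#' Does a sequence contain an A or T homopolymer run?
#'
#' True iff the sequence contains `run` or more consecutive A's, or `run` or
#' more consecutive T's. Runs of G or C are deliberately not counted: the
#' filter targets A/T runs (poly-T can terminate guide transcription from
#' bacterial promoters).
#'
#' @param seq Character vector of sequences.
#' @param run Minimum disqualifying run length (>= 2).
#' @return Logical vector.
#' @export
#' @examples
#' has_at_homopolymer(c("AAAAA", "GGGGGGG", "ATATATAT"), 5)
has_at_homopolymer <- function(seq, run = 5) {
  stopifnot(run >= 2)
  stringi::stri_detect_regex(seq, sprintf("A{%d,}|T{%d,}", run, run))
}

#' Does a guide carry a listed "bad seed"?
#'
#' Compares the 5 PAM-proximal protospacer bases (the bad-seed position of
#' the CRISPRi toxicity literature) against a user-supplied list of 5-mers.
#' With `substring = TRUE` the 5-mers are instead matched anywhere in the
#' protospacer (a stricter, non-positional reading).
#'
#' @param protospacer Character vector of protospacers.
#' @param bad_seeds Character vector of 5-mers (may be empty).
#' @param substring Match anywhere instead of PAM-proximally.
#' @return Logical vector.
#' @export
matches_bad_seed <- function(protospacer, bad_seeds, substring = FALSE) {
  if (length(bad_seeds) == 0L) return(rep(FALSE, length(protospacer)))
  stopifnot(all(nchar(bad_seeds) == 5L))
  bad_seeds <- toupper(bad_seeds)
  if (substring) {
    Reduce(`|`, lapply(bad_seeds,
                       function(b) stringi::stri_detect_fixed(protospacer, b)))
  } else {
    tail5 <- substring(protospacer, nchar(protospacer) - 4L,
                       nchar(protospacer))
    tail5 %in% bad_seeds
  }
}

#' Does a guide contain a restriction site (either strand)?
#'
#' True iff any listed recognition sequence, or its reverse complement,
#' occurs within the given sequence (protospacer + PAM for guide filtering).
#'
#' @param seq Character vector (protospacer + PAM strings).
#' @param sites Character vector of recognition sequences (may be empty).
#' @return Logical vector.
#' @export
contains_restriction_site <- function(seq, sites) {
  if (length(sites) == 0L) return(rep(FALSE, length(seq)))
  sites <- unique(c(toupper(sites), revcomp(toupper(sites))))
  Reduce(`|`, lapply(sites,
                     function(s) stringi::stri_detect_fixed(seq, s)))
}

#' Apply all filters to guide candidates, recording per-filter verdicts
#'
#' Adds one verdict column per filter plus the off-target counts in both
#' modes, and an `accepted` column. A candidate is accepted iff every
#' applicable filter passes: adequate length, no A/T homopolymer (when that
#' filter is on), TSS distance within threshold (promoter guides, with
#' negative distances, always pass), no bad seed, no restriction site, and
#' off-target count below 2 in the active mode. The GC verdict (`pass_gc`)
#' is recorded here but enforced only at the per-PAM selection step, matching
#' the pipeline's ordering.
#'
#' @param candidates Candidates tibble from [enumerate_guides()].
#' @param params A [design_params()] object.
#' @param seed_index A [build_seed_index()] index over the same genome.
#' @return The candidates tibble with verdict columns and `accepted`.
#' @export
apply_filters <- function(candidates, params, seed_index) {
  stopifnot(inherits(params, "design_params"),
            inherits(seed_index, "seed_index"))
  out <- candidates
  n <- nrow(out)
  if (n == 0L) {
    return(mutate(out, pass_length = logical(), pass_homopolymer = logical(),
                  pass_gc = logical(), pass_tss = logical(),
                  pass_bad_seed = logical(), pass_restriction = logical(),
                  strict_count = integer(), relaxed_count = integer(),
                  pass_offtarget = logical(), accepted = logical()))
  }
  out$pass_length <- out$length >= min(GUIDE_LENGTHS)
  out$pass_homopolymer <- !has_at_homopolymer(out$protospacer,
                                              params$homopolymer_run)
  out$pass_gc <- out$gc_percent >= params$gc_min
  out$pass_tss <- out$distance_fraction <= params$tss_max_fraction
  out$pass_bad_seed <- !matches_bad_seed(out$protospacer, params$bad_seeds,
                                         substring = params$bad_seed_substring)
  out$pass_restriction <- !contains_restriction_site(
    paste0(out$protospacer, out$pam), params$restriction_sites)
  out$strict_count <- offtarget_count(seed_index, out, "strict")
  out$relaxed_count <- offtarget_count(seed_index, out, "relaxed")
  if (any(out$strict_count == 0L)) {
    abort(paste0("internal consistency error: candidate from the genome has ",
                 "off-target count 0 (was the index built on the same ",
                 "genome?)"),
          class = "guidebac_internal_error")
  }
  active <- if (params$offtarget_mode == "strict") out$strict_count else
    out$relaxed_count
  out$pass_offtarget <- active < 2L
  out$accepted <- out$pass_length &
    (out$pass_homopolymer | !params$homopolymer_filter_on) &
    out$pass_tss & out$pass_bad_seed & out$pass_restriction &
    out$pass_offtarget
  out
}
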