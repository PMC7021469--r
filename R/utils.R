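#' Reverse complement of nucleotide strings
#'
#' Vectorised over `x`. Alphabet is restricted to A/C/G/T/N; N complements to N.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ATGCN")
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

#' GC content of a nucleotide string, as a percentage
#'
#' Vectorised. N bases are excluded from both numerator and denominator, so
#' `gc_fraction("GCNN")` is 100. An all-N (or empty) string gives `NA`.
#'
#' @param x Character vector of nucleotide strings over A/C/G/T/N.
#' @return Numeric vector of percentages in \[0, 100\] (or `NA`).
#' @export
#' @examples
#' gc_fraction(c("ATGC", "AT", "GCNN"))
gc_fraction <- function(x) {
  gc <- stringi::stri_count_charclass(x, "[GC]")
  at <- stringi::stri_count_charclass(x, "[AT]")
  ifelse(gc + at == 0L, NA_real_, 100 * gc / (gc + at))
}

# Normalize a raw sequence: uppercase, map non-ACGTN IUPAC codes to N.
normalize_seq <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- stringi::stri_count_charclass(x, "[^ACGTN]")
  if (any(bad > 0L)) {
    warn(sprintf(
      "%d non-ACGTN character(s) in %s replaced with N", sum(bad), what
    ))
    x <- stringi::stri_replace_all_regex(x, "[^ACGTN]", "N")
  }
  x
}

# Read a (multi-)FASTA into a tibble(id, sequence) of normalized strings.
read_fasta_tbl <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path), class = "guidebac_input_error")
  }
  ss <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) {
      abort(sprintf("could not read FASTA %s: %s", path, conditionMessage(e)),
            class = "guidebac_input_error")
    }
  )
  if (length(ss) == 0L) {
    abort(sprintf("FASTA %s contains no sequences", path),
          class = "guidebac_input_error")
  }
  tibble(
    id = sub("\\s.*$", "", names(ss)),
    sequence = normalize_seq(as.character(ss), what = basename(path))
  )
}

write_fasta <- function(ids, seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# substring() that tolerates empty position vectors (base R errors on them).
substr_vec <- function(x, start, stop) {
  if (length(start) == 0L) return(character(0))
  substring(x, start, stop)
}

# Deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 7919L) %% 2147483629L
}
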