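# Minimal GenBank flat-file reader: CDS features only. No installed R package
# parses GenBank flat files, so the small subset needed here (LOCUS length,
# FEATURES table, locus_tag/gene qualifiers) is implemented directly.

#' Read CDS features from a GenBank flat file
#'
#' Extracts one record per `CDS` feature: coordinates, strand and an
#' identifier taken from the `locus_tag` qualifier (falling back to `gene`,
#' then to a positional `CDS_<n>` label). Compound locations
#' (`join(...)`/`order(...)`) are collapsed to their outermost span with a
#' warning; partial-end markers (`<`, `>`) are stripped. The declared LOCUS
#' length is returned as an attribute for consistency checking against the
#' genome FASTA.
#'
#' @param path Path to a GenBank flat file.
#' @return A tibble with columns `gene_id`, `start`, `end`, `strand`, plus
#'   attribute `locus_length` (NA if the LOCUS line carries none).
#' @export
read_genbank_cds <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("GenBank file not found: %s", path),
          class = "guidebac_input_error")
  }
  lines <- readLines(path, warn = FALSE)
  locus_length <- NA_integer_
  locus_line <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus_line)) {
    m <- stringi::stri_match_first_regex(locus_line[1], "(\\d+)\\s+bp")
    if (!is.na(m[1, 2])) locus_length <- as.integer(m[1, 2])
  }
  feat_start <- grep("^FEATURES", lines)
  feat_end <- grep("^(ORIGIN|CONTIG|//)", lines)
  if (!length(feat_start)) {
    abort(sprintf("no FEATURES table in %s", path),
          class = "guidebac_input_error")
  }
  feat_end <- c(feat_end[feat_end > feat_start[1]], length(lines) + 1L)[1]
  flines <- lines[(feat_start[1] + 1L):(feat_end - 1L)]

  # Feature starts have the key in columns 6-20; continuations are indented
  # further. Group lines into features, then keep the CDS ones.
  is_new <- stringi::stri_detect_regex(flines, "^ {5}\\S")
  grp <- cumsum(is_new)
  keep <- grp > 0L
  feats <- split(flines[keep], grp[keep])

  recs <- purrr::imap(feats, function(fl, i) {
    key <- stringi::stri_match_first_regex(fl[1], "^ {5}(\\S+)")[, 2]
    if (!identical(key, "CDS")) return(NULL)
    qual_start <- stringi::stri_detect_regex(fl, "^\\s{10,}/")
    first_qual <- c(which(qual_start), length(fl) + 1L)[1]
    loc <- paste(trimws(sub("^ {5}CDS", "", fl[seq_len(first_qual - 1L)])),
                 collapse = "")
    quals <- paste(trimws(fl[qual_start]), collapse = "\n")
    tag <- stringi::stri_match_first_regex(
      quals, "/locus_tag=\"?([^\"\\n]+)\"?")[, 2]
    if (is.na(tag)) {
      tag <- stringi::stri_match_first_regex(
        quals, "/gene=\"?([^\"\\n]+)\"?")[, 2]
    }
    coords <- as.integer(
      stringi::stri_extract_all_regex(loc, "\\d+")[[1]]
    )
    if (length(coords) < 1L || anyNA(coords)) {
      warn(sprintf("CDS feature %s has unparseable location '%s'; skipped",
                   i, loc))
      return(NULL)
    }
    if (stringi::stri_detect_regex(loc, "join|order")) {
      warn(sprintf("compound location '%s' collapsed to outermost span", loc))
    }
    tibble(
      gene_id = if (is.na(tag)) NA_character_ else tag,
      start = min(coords),
      end = max(coords),
      strand = if (stringi::stri_detect_fixed(loc, "complement")) "-" else "+"
    )
  })
  out <- bind_rows(recs)
  if (nrow(out) == 0L) {
    abort(sprintf("no CDS features found in %s", path),
          class = "guidebac_input_error")
  }
  missing_id <- is.na(out$gene_id)
  out$gene_id[missing_id] <- sprintf("CDS_%04d", which(missing_id))
  if (anyDuplicated(out$gene_id)) {
    warn("duplicate gene identifiers made unique with numeric suffixes")
    out$gene_id <- make.unique(out$gene_id, sep = "_")
  }
  attr(out, "locus_length") <- locus_length
  out
}
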