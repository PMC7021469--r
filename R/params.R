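#' Guide design parameters
#'
#' Bundles every user-tunable threshold of the design pipeline. Defaults are
#' the primary stringent parameters used for genome-wide CRISPRi design:
#' GC minimum 35%, maximum distance from the TSS 30% of the gene length, and
#' a minimum 100 bp gap between paired guides (sized to the dCas9 footprint).
#' The relaxed values (GC 30%, TSS 50%, homopolymers retained, full-protospacer
#' off-target matching) are what the iteration engine switches to, individually
#' and in combination, for genes that produce no guide under the primary set.
#'
#' @param gc_min Minimum guide GC content, percent. Enforced at the per-PAM
#'   selection step: among the 20/21/22-mers of one PAM, the longest guide
#'   meeting `gc_min` is kept. Default 35.
#' @param tss_max_fraction Maximum distance of a guide's 5'-most position from
#'   the CDS start (the TSS proxy), as a fraction of the CDS length. Inclusive
#'   boundary; guides in the promoter get negative distances and always pass.
#'   Default 0.30.
#' @param pair_min_separation Minimum gap, in bases, between the occupied
#'   genomic footprints (protospacer + PAM) of the two guides of a pair.
#'   Default 100.
#' @param promoter_len Length of the putative promoter window prepended
#'   upstream of each annotated CDS start, bases. Default 100 (covers typical
#'   bacterial -35/-10 boxes).
#' @param homopolymer_run Minimum run of consecutive A's or consecutive T's
#'   that disqualifies a guide. Default 5 (poly-T of 5 can terminate guide
#'   transcription; 4 would be too aggressive in AT-rich genomes).
#' @param homopolymer_filter_on Whether the A/T homopolymer filter is active.
#'   Default `TRUE`; the relaxation engine switches it off.
#' @param bad_seeds Character vector of 5-mers compared against the 5
#'   PAM-proximal protospacer bases (the "bad seed" position). Default empty.
#' @param bad_seed_substring If `TRUE`, bad seeds are instead matched anywhere
#'   within the protospacer. Default `FALSE` (positional).
#' @param restriction_sites Character vector of recognition sequences; a guide
#'   is rejected if any site or its reverse complement occurs within
#'   protospacer + PAM. Default empty.
#' @param offtarget_mode `"strict"` (12 nt PAM-proximal seed + NGG must be
#'   unique in the genome) or `"relaxed"` (full protospacer + NGG unique).
#'   Default `"strict"`.
#' @param max_guides_per_gene Cap on the per-gene top-hits list. Default 10.
#' @param relaxed_gc_min GC minimum used when the GC constraint is relaxed.
#'   Default 30.
#' @param relaxed_tss_max_fraction TSS distance threshold used when the TSS
#'   constraint is relaxed. Default 0.50.
#' @param spacer_len Number of N's inserted between contigs when preprocessing
#'   a draft genome. Must exceed the 25-base protospacer+PAM window so no
#'   guide can bridge contigs. Default 50.
#' @param scramble_n,scramble_length,scramble_seed Scramble-control defaults
#'   used by [run_pipeline()] when scrambles are requested: how many, their
#'   length (20-22), and the RNG seed.
#'
#' @return A list of class `"design_params"`.
#' @export
#' @examples
#' design_params(gc_min = 30, bad_seeds = "ACCCA")
design_params <- function(gc_min = 35,
                          tss_max_fraction = 0.30,
                          pair_min_separation = 100,
                          promoter_len = 100,
                          homopolymer_run = 5,
                          homopolymer_filter_on = TRUE,
                          bad_seeds = character(),
                          bad_seed_substring = FALSE,
                          restriction_sites = character(),
                          offtarget_mode = c("strict", "relaxed"),
                          max_guides_per_gene = 10,
                          relaxed_gc_min = 30,
                          relaxed_tss_max_fraction = 0.50,
                          spacer_len = 50,
                          scramble_n = 0,
                          scramble_length = 20,
                          scramble_seed = 1L) {
  offtarget_mode <- arg_match(offtarget_mode)
  stopifnot(
    gc_min > 0, gc_min <= 100,
    tss_max_fraction > 0, tss_max_fraction <= 1,
    pair_min_separation >= 0,
    promoter_len >= 0,
    homopolymer_run >= 2,
    relaxed_gc_min > 0, relaxed_gc_min <= 100,
    relaxed_tss_max_fraction > 0, relaxed_tss_max_fraction <= 1,
    max_guides_per_gene >= 1,
    spacer_len >= 0
  )
  bad_seeds <- toupper(bad_seeds)
  if (length(bad_seeds) && any(nchar(bad_seeds) != 5L)) {
    abort("all `bad_seeds` must be 5-mers", class = "guidebac_param_error")
  }
  restriction_sites <- toupper(restriction_sites)
  structure(
    list(
      gc_min = gc_min,
      tss_max_fraction = tss_max_fraction,
      pair_min_separation = as.integer(pair_min_separation),
      promoter_len = as.integer(promoter_len),
      homopolymer_run = as.integer(homopolymer_run),
      homopolymer_filter_on = isTRUE(homopolymer_filter_on),
      bad_seeds = bad_seeds,
      bad_seed_substring = isTRUE(bad_seed_substring),
      restriction_sites = restriction_sites,
      offtarget_mode = offtarget_mode,
      max_guides_per_gene = as.integer(max_guides_per_gene),
      relaxed_gc_min = relaxed_gc_min,
      relaxed_tss_max_fraction = relaxed_tss_max_fraction,
      spacer_len = as.integer(spacer_len),
      scramble_n = as.integer(scramble_n),
      scramble_length = as.integer(scramble_length),
      scramble_seed = as.integer(scramble_seed)
    ),
    class = "design_params"
  )
}

#' @export
print.design_params <- function(x, ...) {
  cat("<design_params>\n")
  for (nm in names(x)) {
    val <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm,
                if (length(val) == 0) "(none)" else paste(val, collapse = ",")))
  }
  invisible(x)
}

#' Read design parameters from a flat key:value config file
#'
#' Lines look like `gc_min: 35`; blank lines and `#` comments are ignored.
#' List-valued keys (`bad_seeds`, `restriction_sites`) take comma-separated
#' values. Unknown keys are a fatal error. Keys not present keep the
#' [design_params()] defaults; `overrides` (a named list, e.g. parsed CLI
#' flags) wins over the file.
#'
#' @param path Path to the config file.
#' @param overrides Named list of parameter overrides applied after the file.
#' @return A `design_params` object.
#' @export
read_design_config <- function(path, overrides = list()) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- stringi::stri_match_first_regex(lines, "^([A-Za-z_]+)\\s*:\\s*(.*)$")
  if (anyNA(kv[, 1])) {
    abort(sprintf("unparseable config line: %s", lines[which(is.na(kv[, 1]))[1]]),
          class = "guidebac_input_error")
  }
  vals <- as.list(trimws(kv[, 3]))
  names(vals) <- kv[, 2]
  vals <- utils::modifyList(vals, overrides)
  fml <- names(formals(design_params))
  unknown <- setdiff(names(vals), fml)
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "guidebac_input_error")
  }
  chr_keys <- c("bad_seeds", "restriction_sites", "offtarget_mode")
  lgl_keys <- c("homopolymer_filter_on", "bad_seed_substring")
  vals <- purrr::imap(vals, function(v, k) {
    if (!is.character(v)) return(v)
    if (k %in% chr_keys) {
      v <- trimws(strsplit(v, ",")[[1]])
      v[nzchar(v)]
    } else if (k %in% lgl_keys) {
      toupper(v) %in% c("TRUE", "T", "YES", "ON", "1")
    } else {
      as.numeric(v)
    }
  })
  exec(design_params, !!!vals)
}

# Apply a set of relaxations (subset of "GC","TSS","homopolymer","offtarget")
# to a design_params object.
relax_params <- function(params, relaxations) {
  if ("GC" %in% relaxations) params$gc_min <- params$relaxed_gc_min
  if ("TSS" %in% relaxations) {
    params$tss_max_fraction <- params$relaxed_tss_max_fraction
  }
  if ("homopolymer" %in% relaxations) params$homopolymer_filter_on <- FALSE
  if ("offtarget" %in% relaxations) params$offtarget_mode <- "relaxed"
  params
}
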