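# Non-targeting (scramble) control guides: uniform random sequences accepted
# only if their 12-base PAM-proximal seed followed by NGG has zero
# occurrences in the genome (both strands) — absence at seed level
# guarantees no targeting under the same seed-match model the off-target
# filter uses, which is stronger than full-sequence absence.

#' Generate scramble (non-targeting) control guides
#'
#' Rejection sampling: candidate sequences of the requested length are drawn
#' uniformly over A/C/G/T; a draw is accepted iff its strict off-target count
#' against `index` is zero and its GC content lies within `gc_bounds`.
#' Output is deduplicated and deterministic for a given `rng_seed` (the
#' caller's RNG state is left untouched).
#'
#' @param index A [build_seed_index()] index over the genome the controls
#'   must not target.
#' @param n Number of controls wanted (>= 1).
#' @param length Guide length, 20-22.
#' @param gc_bounds Length-2 numeric, percent; default `c(35, 65)` so
#'   controls resemble targeting guides compositionally. Use `c(0, 100)` to
#'   disable.
#' @param rng_seed Integer seed; required for reproducibility.
#' @param max_attempts Draw budget; if exhausted a partial list is returned
#'   with a warning.
#' @return Tibble with `sequence`, `gc_percent`, `rng_seed_used`.
#' @export
generate_scrambles <- function(index, n, length = 20, gc_bounds = c(35, 65),
                               rng_seed, max_attempts = 1e6) {
  stopifnot(n >= 1, length >= 20, length <= 22, base::length(gc_bounds) == 2)
  n <- as.integer(n)
  length <- as.integer(length)
  rng_seed <- as.integer(rng_seed)
  withr::local_preserve_seed()
  set.seed(rng_seed)

  accepted <- character(0)
  attempts <- 0L
  batch <- max(1000L, 10L * n)
  while (base::length(accepted) < n && attempts < max_attempts) {
    m <- min(batch, as.integer(max_attempts - attempts))
    draws <- vapply(seq_len(m), function(i) {
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = "")
    }, character(1))
    attempts <- attempts + m
    gc <- gc_fraction(draws)
    ok <- gc >= gc_bounds[1] & gc <= gc_bounds[2]
    ok[ok] <- offtarget_count(index, draws[ok], mode = "strict") == 0L
    accepted <- unique(c(accepted, draws[ok]))
  }
  if (base::length(accepted) < n) {
    warn(sprintf(
      "only %d of %d scramble guides found within %g attempts",
      base::length(accepted), n, max_attempts))
  }
  accepted <- head(accepted, n)
  tibble(sequence = accepted, gc_percent = gc_fraction(accepted),
         rng_seed_used = rng_seed)
}
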