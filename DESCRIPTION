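Package: guidebac
Title: Genome-Wide CRISPR Guide RNA Design for Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs CRISPR/Cas9 guide RNAs (CRISPRi/CRISPRa oriented) genome-wide
    for any annotated bacterial genome, complete or draft. Scans promoter and
    coding regions for NGG PAM sites on both strands, creates 20-22 nt guide
    candidates, filters them on GC content, distance from the transcription
    start site, A/T homopolymer runs, user-supplied "bad seed" 5-mers,
    restriction sites and seed-sequence off-target matches counted against the
    genome in use, then ranks per-gene top hits, builds paired guides with a
    minimum spacing constraint, iteratively relaxes parameters for guide-poor
    genes, and generates non-targeting scramble controls. Includes a synthetic
    genome generator and brute-force oracles for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringi,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
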