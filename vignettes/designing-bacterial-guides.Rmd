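---
title: "Designing bacterial CRISPRi guides with guidebac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing bacterial CRISPRi guides with guidebac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidebac)
```

## The design model

`guidebac` designs guides for catalytically dead Cas9 (dCas9) applications —
transcriptional repression (CRISPRi) or activation (CRISPRa) — in bacteria.
The targeting model is the canonical *S. pyogenes* one: a 20–22 nt
protospacer immediately 5' of an NGG PAM, with specificity dominated by the
~12 PAM-proximal "seed" bases. Repression works by steric blockade of RNA
polymerase, so guides close to the transcription start site are preferred,
and guides in the promoter itself are best of all.

Three assumptions shape the implementation:

* **The annotated CDS start proxies the TSS.** Bacterial annotations rarely
  include mapped TSSs, and the inputs here carry only CDS coordinates. The
  promoter window is therefore an upstream extension of the CDS
  (`promoter_len`, default 100 bp — enough to cover the −35/−10 boxes of a
  typical σ70 promoter). Guides whose 5'-most base falls upstream of the
  CDS start get a *negative* TSS distance and always pass the distance
  filter.
* **Off-target risk is seed-level identity plus a PAM.** A 12-mer match
  without an adjacent NGG cannot be bound productively, so the off-target
  counter requires the PAM at the matching position, in the matching
  orientation, on either strand of the *input* genome (never a reference).
  A count ≥ 2 — the candidate's own site plus any other — discards the
  guide. The 12 nt are read as protospacer bases; the alternative reading
  (9 protospacer + 3 PAM bases) would be strictly weaker and is not used.
* **Each gene is independent.** Overlapping genes may both claim the same
  genomic position; a duplicated gene is simply a gene whose guides fail
  off-target filtering.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `gc_min` | 35 | % | guides below ~35% GC bind poorly; enforced at per-PAM selection |
| `tss_max_fraction` | 0.30 | fraction of CDS length | repression efficacy decays with distance from the TSS; inclusive boundary |
| `pair_min_separation` | 100 | bp | projected dCas9 footprint; measured between occupied protospacer+PAM intervals, not centers |
| `promoter_len` | 100 | bp | covers −35/−10 boxes; clipped at genome ends |
| `homopolymer_run` | 5 | nt | poly-T ≥ 5 can terminate guide transcription; 4 would be too aggressive in AT-rich genomes; only A and T runs count |
| `bad_seeds` | none | 5-mers | organism-specific toxicity; compared at the 5 PAM-proximal bases |
| `restriction_sites` | none | — | site or reverse complement anywhere in protospacer+PAM |
| `offtarget_mode` | strict | — | strict = 12-nt seed + PAM; relaxed = full protospacer + PAM |
| `max_guides_per_gene` | 10 | count | caps the ranked top-hits list |
| `relaxed_gc_min` / `relaxed_tss_max_fraction` | 30 / 0.50 | — | the relaxation targets used by the iteration engine |
| `spacer_len` | 50 | nt of N | longer than any protospacer+PAM window (25 nt), so no guide can bridge contigs |

The discard threshold for off-target counts (≥ 2 genomic locations) is fixed,
not a parameter: one occurrence is the guide's own locus, and any second
locus of equal seed identity is disqualifying under the seed model.

## Pipeline order and its consequences

Enumeration is parameter-free: every PAM on both strands of each
promoter+CDS region yields up to three candidates (20/21/22 nt), fewer when
insufficient clean sequence lies 5' of the PAM. Filtering then records a
verdict per filter per candidate. GC is deliberately *not* an elimination
filter: it is applied at the per-PAM selection step, where the longest
candidate meeting `gc_min` is kept. This ordering matters — a 22-mer whose
two extra 5' bases are A/T can dilute GC below threshold while its 20-mer
core passes, and the selection step recovers exactly that case.

Both strands are scanned and reported. CRISPRi practitioners often prefer
non-template-strand guides within the gene body; the `strand` column (and a
CLI flag) supports post-hoc restriction, but the default keeps both since
promoter-region guides are strand-agnostic.

## The iteration engine

Genes with zero selected guides at primary stringency are retried under
relaxed constraints. Four relaxations exist — GC, TSS distance, homopolymer
retention, and relaxed off-target — and they are tried in a fixed order:
each single relaxation (in the order just given), then all pairs, triples,
and finally all four together, each level in lexicographic order of the
single order. The first combination yielding ≥ 1 selected guide is recorded
as the gene's `iteration_label` and the search stops for that gene, keeping
the constraint load minimal per gene. This ordering and first-success rule
is a design choice: applying relaxations "individually and in combination"
admits many search policies, and a fixed enumeration makes results
reproducible and the per-combination recovery counts auditable. The trigger
is *zero top hits* (not "fewer than requested", and not "no pairs"): genes
that produce any guide keep their stringent guides untouched, and pairs are
then built from whatever selected set — primary or recovered — each gene
ends up with. A consequence worth knowing: recovery counts are attributed to
the *first* sufficient combination, so a gene recoverable by either GC or
TSS relaxation alone is always counted under GC.

## Determinism and tie-breaks

Everything outside scramble generation and the fixture generator is
deterministic. Top hits sort by ascending TSS distance with ties broken by
`(strand, protospacer)` lexicographically; per-PAM selection cannot tie
(the three lengths are distinct); pairs order by the TSS distances of their
members. Scramble and fixture generation take explicit integer seeds and
restore the caller's RNG state, so a fixed configuration reproduces
byte-identical output files — the test suite asserts this at file level.

Degenerate inputs are handled explicitly: empty promoter windows are
represented with `end < start` and contribute zero length; regions shorter
than a protospacer+PAM yield no candidates; windows containing N never match
(this is what makes contig spacers safe); an all-N sequence reports missing
GC; a CDS that maps nowhere on a draft concatenation lands in an `unmapped`
table rather than failing the run, and a CDS with several exact matches is
assigned to its first occurrence with a warning (every gene stays
addressable, ambiguity is flagged — duplicated genes lose their guides to
off-target filtering anyway).

## What the synthetic generator does and does not emulate

`generate_synthetic_genome()` builds genomes along the axes that distinguish
real bacterial genomes for this task: size (gene count × realistic CDS and
intergenic length ranges), GC content (binomial base sampling at a target
percentage), gene duplication (planted identical copies), and draft
fragmentation (cuts at intergenic midpoints, so no planted gene is split).
Base composition is i.i.d., which a real genome's is not: there are no
operons, no codon structure, no repeat families beyond the planted
duplications, no strand-biased GC skew, and duplicated copies are *exact*,
where real paralogs diverge. A green oracle-equivalence test therefore
establishes that the implementation computes the specified function on
realistic input *scales and compositions* — it does not establish
biological efficacy of the designed guides, which the filters only proxy.

AT-rich fixtures (GC ≈ 32–38%) reproduce the qualitative behaviour expected
from real low-GC genomes: lower primary recovery (fewer PAMs, more
candidates failing the GC minimum) and a larger share of genes rescued by
the relaxation engine.

## Validation strategy

The acceptance suite re-derives everything by brute force: candidates by
testing every (offset, strand, length) window with `substring()`, off-target
counts by tabulating every genomic window followed by a PAM, filters from
their single-predicate definitions. On 20 synthetic genomes (10–100 kb,
GC 30–70%, duplication 0–0.5) the pipeline's accepted and selected sets must
equal the brute-force sets exactly. Draft/complete concordance is asserted
for genes whose promoter+CDS region does not cross a contig breakpoint;
genes that do are legitimately different (their promoter sequence is partly
N in the draft), which is also why breakpoint-adjacent genes deserve manual
review in real draft-genome designs.

## Known limitations

* No mismatch-tolerant (Hamming ≤ k) off-target search: identity-level seed
  matching is the model; near-matches are not counted.
* No operon awareness: polar effects of CRISPRi on downstream genes of an
  operon are outside the model, as is any TSS inference.
* No efficiency scoring: the filters encode exclusion rules, not a ranking
  of predicted knockdown strength; distance to the TSS is the only
  preference signal.
* Draft preprocessing requires the CDS FASTA to derive from the same
  assembly as the contigs (exact-match location); CDS sets from a different
  strain will land in the unmapped list.
* Runtime scales with genome size through enumeration and index
  construction; genomes in the tens of megabases are feasible but slow in
  plain R.
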