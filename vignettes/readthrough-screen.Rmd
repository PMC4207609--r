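---
title: "Screening genomes for readthrough-derived peroxisomal isoforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening genomes for readthrough-derived peroxisomal isoforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtscreen)
library(dplyr)
```

## The screening model

Termination of translation is leaky at certain stop codon contexts. The
screen implemented here rests on three observations established by
mutational reporter analysis in fungal and human cells:

* stop codon identity matters — TGA is read through far more efficiently
  than TAG or TAA;
* the first two downstream nucleotides are the main determinant — a TGA
  stop followed by the dinucleotide CT suffices for efficient readthrough
  (the *core element*);
* an A at position +3 stimulates readthrough further, and a G at +4 marks
  an extended weak-termination context.

We deliberately model this as ordered boolean flags (`core_pass`,
`plus3_A`, `plus4_G`) rather than a quantitative efficiency score: the
underlying evidence is relative band intensity on Western blots, which
ranks contexts but does not calibrate numeric weights. Inventing weights
would suggest precision the data do not support. The screen's inclusion
filter is `core_pass` alone; the +3/+4 flags are annotations that let users
stratify candidates.

A readthrough event appends the translation of the region between the
annotated stop and the next in-frame stop — the *extension*. A candidate
peroxisomal isoform requires this extension to terminate in a PTS1
tripeptide, because PTS1 signals are only functional at the extreme
C-terminus. This is why the motif pattern

```
(^\*[^*]*?([ASTPCE]RL|[SATPCVNG]KL|S[SNH]L|ARI|S[KR]M|[AG]NL|SN[IM]|[SA][KRQ]Y|HHL|[QS][KRQ]F)\*)
```

is applied to the extension rendered as `"*" + extension + "*"`: the
leading `^\*` anchors at the read-through (annotated) stop, `[^*]*?`
forbids internal stops, and the trailing `\*` forces the tripeptide to sit
immediately before the terminal stop. An *open* extension (no in-frame stop
found within the search bound) has no terminal `*` to anchor to and is
therefore ineligible for PTS1 calling, though it is still reported. The ten
alternatives expand to 37 distinct tripeptides
(`pts1_tripeptide_set()`); the equivalence of the expansion and the regex
is property-tested over all 8,000 tripeptides with random motif-free
prefixes.

Orthologs can achieve the same peroxisomal targeting without readthrough:
some species encode the PTS1 within the regular open reading frame
("in-ORF PTS1"), and others use an N-terminal PTS2. Each gene is therefore
assigned one mechanism class with the fixed priority

```
readthrough_PTS1 > in_ORF_PTS1 > readthrough_PTS1_noncore_context > PTS2 > none
```

The priority order is a design decision of this package — the mechanisms
are biologically alternatives and no tie rule is established in the
literature; core-context readthrough outranks the in-ORF motif because it
is the signal the screen exists to find, and the non-core class is
speculative by construction (reported only under `context_mode = "any"`).

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `flank_len` | 600 nt | genomic 3′ flank retrieved per gene |
| `max_ext_nt` | 600 nt (200 codons) | extension search bound |
| `context_mode` | `"tga-ct"` | inclusion filter; `"any"` also reports non-core PTS1 extensions |
| `include_pts2` | `FALSE` | approximate PTS2 consensus scan |
| `pts2_window` | 40 aa | N-terminal window for PTS2 |

Documented readthrough extensions are short (tens of residues), so 200
codons is a generous bound whose only role is to keep degenerate,
stop-free flanks cheap; both lengths are configurable. A `flank_len`
shorter than `max_ext_nt` triggers a warning because it can leave
extensions open at the flank edge.

The PTS2 scan matches the canonical consensus
`R-[LVIQ]-x-x-[LVIH]-[LSGA]-x-[HQ]-[LAF]` in the N-terminal window. This is
a coarse stand-in for trained PTS2 predictors, included so that
conservation matrices can express the PTS2 mechanism; it is off by default
and labelled approximate wherever it appears.

## Input handling

GFF3 coordinates (1-based inclusive) are converted once, at parse time, to
0-based half-open intervals; all internal arithmetic uses that convention
to avoid off-by-one drift. When a gene has several mRNAs the transcript
with the longest total CDS is used, ties broken by the lexicographically
smallest transcript id — a deterministic rule, since the choice is
otherwise arbitrary. CDS models whose length is not a codon multiple or
that do not end in TAA/TAG/TGA are skipped with a warning and counted in
the run summary; annotation errors must not silently poison a genome-wide
screen.

If `three_prime_UTR` features are present the flank is their spliced
concatenation (`flank_source = "spliced_utr"`): an intron inside a genomic
flank would corrupt the reading frame of the extension. Otherwise the
unspliced genomic flank is used and flagged, truncated at contig edges
(`flank_truncated`). Minus-strand genes are reverse-complemented so that
`cds_nt` and `flank_nt` both read 5′→3′ in the coding sense; a
strand-invariance property (reverse-complementing every contig and
flipping all strands changes no report field except coordinates) is tested
on simulated genomes.

Degenerate cases are resolved as follows: a codon containing `N`
translates to `X`, is never treated as a stop, and can never participate
in a PTS1 hit (no alternative contains `X`). A flank whose first in-frame
codon is a stop yields an `empty` extension; a flank with no full codon
yields a zero-length `open` extension, and mechanisms for such entries are
decided from the ORF terminus alone.

## The synthetic-data generator

`simulate_genome()` emulates the statistical structure the screen assumes:
protein-coding genes (uniform random sense codons between a start codon
and a terminal stop) separated by random intergenic spacers on both
strands, where each gene's 3′ region contains an in-frame extension ending
at a second stop. Four planted classes carry exactly one signal each:

* `readthrough_PTS1` — TGA stop, +1..+3 = CTA, extension ending in a PTS1
  tripeptide drawn uniformly from the 37;
* `context_only` — TGA CT context, extension free of terminal PTS1;
* `pts1_wrong_stop` — TAA/TAG stop with a PTS1-terminated extension;
* `in_orf_pts1` — PTS1 tripeptide at the regular ORF terminus.

Background genes are *rejection-sampled*: a background body or 3′ region
that happens to carry a core context, a PTS1-terminated extension, or an
in-ORF PTS1 is redrawn. Without this, the ~0.46% tripeptide rate
(37/8,000) and the 1/192 natural rate of the core stop context would
stochastically contaminate the negatives, and exact planted-truth recovery
(sensitivity = specificity = 1) would not be a testable property.
Rejection happens at generation time, not by post-hoc filtering, so class
counts always match the configuration exactly.

Defaults (200 genes, 10 planted positives, 10 decoys per class, CDS
100–300 codons, extensions 5–30 codons, intergenic spacers 200–400 nt, half
the genes on the minus strand) are sized like a compact microbial genome
region: large enough that every class and both strands are exercised,
small enough that a full simulate–write–read–screen cycle takes seconds.
Codon usage is uniform over sense codons; the screen is codon-usage
agnostic, so a realistic usage bias would change nothing it measures.

What the generator does *not* emulate — and what passing tests therefore do
not show about real data: realistic codon usage and UTR length
distributions, introns in 3′ UTRs (exercised separately with hand-built
fixtures), overlapping genes, sequencing or annotation noise beyond the
malformed-CDS classes, and any quantitative level of readthrough. The
generator validates the *logic* of the screen, not its yield on a real
genome.

## Reproducibility and numerical choices

Simulation is driven by a single integer seed; the generator saves and
restores the caller's RNG state and produces byte-identical FASTA/GFF3/
truth files for identical configurations. Screen output is deterministic:
reports are sorted by contig and transcript start, and re-running on the
same input produces byte-identical TSVs. The extension cap admits a stop
codon found immediately after a maximum-length extension (the stop is not
part of the extension), so a 200-codon extension followed by a stop is
`closed`, not `open`.

One representational note: extension `status` distinguishes `empty` (the
first flank codon is a stop; a genuine zero-length readthrough product)
from `open` (no stop found; includes the degenerate empty-flank case).
`empty` always implies length zero, but a zero-length extension with no
flank at all is `open`, since no terminating stop was observed.

## Conservation analysis

Ortholog groups arrive as a precomputed TSV (`group_id`, `species`,
`gene_id`, `protein_aa`, `stop_codon`, `flank_nt`); orthology inference
itself is out of scope. Every entry is classified by the same internal
routine the genome screen uses — this is asserted by a cross-module test —
and per group the package tabulates species counts per mechanism, whether
all readthrough-positive species share the core TGA CT context, and a
per-species matrix (`autoplot()` renders it as a tile map). "Conservation"
here means presence/absence tabulation across the provided species, not
phylogenetic reconstruction. A species listed more than once keeps its
best-priority mechanism.

## Scope and limitations

The package identifies *candidates* by sequence context and motif; it does
not predict readthrough efficiency, model downstream mRNA secondary
structures that can stimulate readthrough at non-core contexts, handle
selenocysteine recoding, score PTS1 context quality beyond the tripeptide
(receptor-binding models, upstream charge), or detect isoforms generated
by alternative splicing. Candidates behind non-TGA-CT contexts are only
reported under an explicit `context_mode = "any"` and carry their own
class, since the screen's evidence base does not support calling them
positives.

## A compact end-to-end run

```{r demo}
sim <- simulate_genome(simulate_config(
  n_genes = 50, n_planted_readthrough_pts1 = 3,
  n_decoy_context_only = 3, n_decoy_pts1_wrong_stop = 3,
  n_decoy_in_orf_pts1 = 3, seed = 42
))
res <- screen_genome(sim$genome, sim$models)
glance(res)

res |>
  tidy() |>
  filter(mechanism_class != "none") |>
  select(gene_id, stop_codon, context_plus1_4, ext_status,
         pts1_tripeptide, orf_terminal_pts1, mechanism_class)

autoplot(res)
```

The recovered `readthrough_PTS1` set equals the generator's planted truth
(`sim$truth`) exactly — the property the acceptance checks verify at the
200-gene scale.
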