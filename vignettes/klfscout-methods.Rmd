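---
title: "Methods: finding SP/KLF-family genes and pseudogenes with klfscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: finding SP/KLF-family genes and pseudogenes with klfscout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(klfscout)
```

## The problem

Specificity proteins and Krüppel-like factors (the SP/KLF family) are
transcription factors with three C2H2 zinc fingers whose residue spacings are
remarkably rigid: the zinc-binding pattern is

```
C X4 C X12 H X3 H  --7--  C X4 C X12 H X3 H  --7--  C X2 C X12 H X3 H
```

i.e. cysteine-pair separations of 4, 4 and 2 residues, 12-residue inner
spacers, 3 residues between the histidines, and 7-residue linkers. This
spacing tuple is essentially unique to SP/KLF members among C2H2 proteins:
EGR-type fingers show separations (4,2,2), and the Wilms' tumor protein adds
a fourth finger with separation 4 to an otherwise SP/KLF-like triplet. That
rigidity makes family membership decidable by a small spacing grammar rather
than by alignment scores, and it is the backbone of this package: a candidate
locus anywhere in a genome is an SP/KLF candidate precisely when its
translation contains three fingers with this signature.

`klfscout` implements the complete discovery pipeline around that idea:
grammar-based finger detection and classification, conservation checks of the
DNA-contact residues, analytics for a tandem repeat motif found in the
N-terminal region of KLF18-like proteins, synteny-anchored locus finding,
six-frame translated scanning with splice-aware gene-model assembly and
pseudogene calling, and duplication-history inference (local gene duplication
versus retrotransposition). Because the interesting loci are *predicted*
genes with no curated annotation, every stage is validated against synthetic
genomes with planted truth generated by the package itself.

## Finger detection and classification

`find_c2h2_domains()` scans left to right and matches
`C X(g) C X(12) H X(3) [H|C]` with `g` in a configurable range (default 2-4).
Matching is greedy — a matched finger consumes its residues — and within one
start position the smallest admissible `g` is preferred, which makes the
parse deterministic. Two deliberate tolerances:

* the final zinc-binding position accepts cysteine as well as histidine
  (`allow_terminal_cys_for_his`, default on): a general C2H2 consensus allows
  either, and at least one murine KLF18 candidate carries the C variant;
* `X` (unknown residue, including codons containing `N`) matches any
  non-anchor position but can never serve as a C/H anchor, so assembly gaps
  degrade a locus to *partial* rather than inventing fingers.

`signature_of()` turns a finger set into a family label. `SPKLF_STRICT` is
the exact (4,4,2) signature with 7-residue linkers; `SPKLF_RELAXED` admits
separations from {2,4} other than (4,4,2) with canonical linkers — the rat
KLF18 proteins, whose first two cysteine pairs contracted from four to two
residues, land here; `EGR_LIKE` (4,2,2) and `WT1_LIKE` (4,4,2 + a fourth
finger at 4) label the two decoy patterns a genome-wide scan must reject.
Tests verify 100% separation of these labels on generated panels of 100
decoys each.

### DNA-contact residues

SP/KLF fingers read GC/GT boxes through three invariant arginines (two in
finger 2, one in finger 3) buttressed by three acidic residues (two
aspartates, one glutamate). The alignment positions of these residues are
published as figure shading, not as offsets, so `contact_spec()` ships them
as configuration rather than hard-coded truth. The defaults follow canonical
C2H2 recognition-helix geometry — helix positions −1, +2, +3 and +6
correspond to offsets 5, 7, 8 and 11 within the 12-residue inner spacer
(the Zif268-style `R S D E ... R` arrangement) — with arginines expected at
(finger 2, 5), (finger 2, 11), (finger 3, 5) and acidic partners at
(finger 2, 7), (finger 2, 8), (finger 3, 7). Calibration against curated
human KLF1-KLF17 sequences is the recommended refinement when those
sequences are at hand; the synthetic generator plants its contacts at
whatever offsets the active `contact_spec()` declares, so the
generator-detector closure holds for any chosen offsets.

```{r}
p <- make_zf_protein("example", n_repeats = 14, seed = 1)
fingers <- find_c2h2_domains(p)
signature_of(fingers, nchar(p$sequence))
contact_report(p, fingers)
```

## The N-terminal repeat motif

KLF18-like proteins carry long N-terminal regions built from a repeated
four-residue motif, `[YC] x [GASTDNPE] [QH]` — tyrosine (occasionally
cysteine), any residue, a small residue or glutamate, then glutamine or
histidine. `scan_motif()` reports all matches; for this pattern two matches
can never overlap (positions 2-4 of a match cannot contain Y or C... position
1 requires one), so the all-position count is the motif count. *Motif
density* is the number of matches divided by the full protein length — the
printed definition, not a per-region density. `extend_segments()` widens
each hit by five residues on both sides into 14-mers (boundary-truncated
hits are dropped, not padded, keeping the position-frequency matrix columns
homogeneous), `build_pfm()` tabulates counts, frequencies and per-position
information content in bits, and `find_tandem_runs()` reports chains of hits
spaced 14 ± 4 residues apart. `rank_proteome()` orders proteins by density
and reports the fraction of Y-initial hits, which separates KLF18-like
proteins (mostly Y) from cysteine-rich keratin-like decoys (all C).

## Synteny-anchored locus finding

The KLF17/KLF18 locus sits between conserved neighbors: B4GALT2, CCDC24 and
SLC6A9 upstream, DMAP1, ERI3 and RNF220 downstream. `find_anchored_interval()`
looks for at least one anchor from each side in consistent order on one
chromosome and returns the interval between the innermost found anchors;
one anchor per side suffices (low-coverage assemblies often lack some), and
the anchors found are reported so downstream consumers can weigh confidence.
Orientation is normalized, so a chromosome stored in mirrored orientation
yields the reflected interval, and candidate intervals wider than 1 Mb
(configurable) are rejected as spurious. `orientation_relation()` classifies
neighbor-gene geometry (tail-to-tail, head-to-head, co-oriented) — the
KLF17/KLF18 pair is tail-to-tail.

## Translated locus scanning and pseudogene calling

`six_frame_scan()` translates both strands in all three frames (standard
code; stops as `*`, fuzzy codons as `X`) and runs the finger grammar on each
translation, *tolerating stops inside spacers* so that pseudogenized fingers
are still located and their stop codons mapped back to exact genomic
positions. Neighboring fingers of one frame are grouped into fragments.

`scan_interval_copies()` resolves fragments into gene copies in three
stages: (1) a one-finger and a two-finger fragment joined by a
splice-consistent gap form a two-exon copy; (2) fragments with a full
three-finger complement form single-exon (intronless) copies; (3) remaining
fragments are clustered by proximity, and clusters with at least two fingers
are reported with unknown intron structure. Isolated single-finger matches
are discarded as scan background: out-of-frame translations of long coding
regions produce occasional chance C2H2 matches, and a bona fide SP/KLF locus
always leaves at least a two-finger footprint.

Splice consistency is deliberately narrow: the gap between the finger-1 and
finger-2/3 coding fragments must contain a `GT..AG` sub-interval whose
removal leaves an in-frame linker of plausible length (at most 12 codons;
candidates closest to the canonical 7 preferred). Fragments end at codon
boundaries, so linker codons flank the intron — the check accounts for that.
Only the canonical `GT..AG` boundary class is recognized; the family's one
relevant intron, between the coding regions of the first finger and the last
two, is canonical, and non-canonical splice detection is out of scope.

`call_status()` then labels each copy: *pseudogene* when an in-frame
premature stop lies in a finger-coding segment or when the finger complement
is deteriorated (fewer than three fingers recovered, i.e. a zinc-binding
anchor lost — "deteriorated" is operationalized as anchor loss, the
conservative reading); *coding* when three clean fingers are present;
*absent* when nothing was found. A locus whose finger-coding DNA is missing
but whose interval still shows a tandem run of the repeat motif in some
frame (`detect_repeat_region()`, run length ≥ 3 at period 14 ± 4 — isolated
chance motif hits in random sequence are common, periodic runs are not) is
reported as *partial* in the cross-genome presence matrix, mirroring what
low-coverage genomes show in practice.

## Evolution: trees and event histories

`anchor_align()` aligns three-finger regions by their twelve C/H anchors;
unequal inter-anchor spans are padded with gaps right-aligned against the
downstream anchor, a fixed convention that places the rat-type deletions
immediately after the upstream cysteine and makes the alignment
deterministic and round-trippable. `p_distance()` computes pairwise
mismatch fractions over shared ungapped columns (optionally
Poisson-corrected), and `nj_tree()` builds a neighbor-joining tree (via
`ape::nj`, negative branches clamped to zero).

NJ replaces maximum-likelihood and Bayesian machinery on purpose: branch
support values from those methods are not reproducible in a lightweight
pipeline, and the quantity that matters downstream is topological — whether
the fast-evolving KLF17/KLF18-like rows form a clade under WT1-style
outgroup rooting (`is_monophyletic()`). The packaged simulation
(`simulate_klf_family()`) gives the pair an extra shared fast branch (rate
0.15) over a background rate of 0.08 and an outgroup at 0.3, emulating the
elevated evolutionary rate reported for these proteins, and the clade is
recovered in well over 90% of replicates.

`classify_events()` reconstructs a duplication history: parents are assigned
by nearest sequence identity (global pairwise alignment, BLOSUM62), growing
outward from a designated root so the parent graph is acyclic by
construction. Mechanisms per edge:

* **RT** (retrotransposition) — the child is intronless and either its
  parent is intron-containing (a retrocopy of a spliced mRNA), or the copy is
  distal. The second clause extends to serial retrotransposition: the
  hallmark of a retrocopy is its intronless coding region, and a distal
  intronless copy of an already-intronless parent (the Zfp353-from-Zfp352
  configuration) is an RT product even though its parent lost its coding
  introns one event earlier.
* **LGD** (local gene duplication) — the child lies on the parent's
  chromosome within 250 kb (configurable; adjacency is only qualitative in
  the literature).
* **distal_unknown** — a distal intron-containing copy.

On the five-member murine scenario (KLF17 → KLF18 by LGD, KLF18 → Zfp352 by
RT, Zfp352 → Zfp352l by LGD, Zfp352 → Zfp353 by RT) the full four-event
history is recovered exactly across seeds at 5% per-branch divergence. At
exactly zero divergence all identities tie and ties fall back to id order,
so event recovery is evaluated at small nonzero rates; this is a property of
the problem (identical sequences carry no genealogical signal), not of the
implementation.

## The synthetic-data generator

`make_zf_protein()` builds proteins from the family grammars: `n_repeats`
14-residue repeat units (each holding one motif match, with the Q-T-L
context observed before the conserved tyrosine and Y:C odds of 9:1), then a
finger region with requested cysteine separations and planted contact
residues. Filler residues exclude C, H and Y so that the planted fingers
and motifs are exactly what any detector can find — the closure property
that makes 100%-accuracy assertions meaningful. Repeat counts default to
the 10-50 range seen across species, with 50 and 14 used for the
human-like and mouse-like constructs.

`make_locus()` back-translates with uniform seeded codon choice (no
codon-usage table — the simplest reproducible scheme) and plants gene
structure: a 101-bp `GT..AG` intron mid-linker between fingers 1 and 2
(101 is deliberately not a multiple of 3, so the downstream exon shifts
frame); optionally a TAA stop inside a chosen finger or a destroyed anchor;
optionally hard-masking of the finger region with `N`. The non-canonical
`CT..AC` negative-control intron is resampled until the gap contains no
coincidental splice-consistent `GT..AG` pair, so the control is unambiguous
by construction. `make_genome()` lays out anchors, tandem/distal copies and
intergenic filler with exact truth coordinates; `simulate_panel()` produces
multi-genome surveys whose status mix (majority coding, a few pseudogenes, a
few missing or partial) is proportioned like a placental-mammal survey.

What the generator does **not** emulate: real intergenic sequence
composition (filler is i.i.d. uniform ACGT), repeat-array length evolution,
indels other than the fixed finger contractions, non-canonical splicing,
codon-usage bias, and assembly artifacts beyond whole-region N-masking.
Passing tests therefore demonstrate correctness of the detectors under the
family's sequence grammar, not robustness to every artifact of real
assemblies.

## Numerical and procedural choices

* All randomness flows from explicit seeds; per-stage substreams are derived
  from a master seed, so pipelines are reproducible and stages independently
  re-runnable. Identical inputs and configuration reproduce identical output
  digests (asserted in tests).
* Protein coordinates are 0-based indices and genomic intervals 0-based
  half-open internally; GFF3 is written 1-based inclusive and BED 0-based
  half-open, and the proteome report prints 1-based finger coordinates for
  readability.
* Problem sizes in the packaged checks — 20-genome panels, 50-locus
  pseudogene panels, 20-seed event-history sweeps, 50 tree replicates,
  oracle sweeps over 1000 random 500-mers — were chosen as the smallest
  sizes at which the properties are statistically meaningful while keeping a
  full run in the minutes range on one core.
* Tree-topology correctness is cross-checked against an exhaustive
  least-squares oracle over all topologies for up to six taxa; motif and
  finger scanners are cross-checked against brute-force all-position
  oracles.

## Known limitations

* The grammar is spacing-only; divergent SP/KLF members with non-canonical
  linkers classify as `OTHER_C2H2` by design.
* Anchored locus finding matches anchor gene ids; it does not do
  sequence-level anchor discovery in unannotated genomes.
* Gene models cover the finger-coding region (plus the reconstructed spliced
  linker); N-terminal exon structure is observed only through the
  repeat-region similarity flag.
* Event classification relies on nearest-identity parents and is therefore
  only as good as the divergence signal; near-zero divergence degenerates to
  tie-breaking, and very high divergence erodes accuracy monotonically (a
  property asserted in tests for the detectors).
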