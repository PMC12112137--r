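---
title: "Methods: scanning and classifying the rpmH-dnaA antisense-promoter architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning and classifying the rpmH-dnaA antisense-promoter architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrascan)
```

## The biological object and the model

The *rpmH*–*dnaA* intergenic region of *Bacillus* chromosomes lies
inside oriC territory and, in several species, carries a promoter on
the strand antisense to *dnaA* that drives an antisense RNA (ArrA)
overlapping the *dnaA* 5' untranslated leader. The promoter is a
SigA-type −35/−10 pair and is embedded between two DnaA binding sites.
`arrascan` formalises the comparative scan for this architecture as a
deterministic, parameterised procedure:

1. **Extraction.** The intergenic interval strictly between the *rpmH*
   and *dnaA* gene bodies is sliced out and re-oriented 5'→3' on the
   strand antisense to *dnaA*, reading from the *dnaA*-proximal end.
   All downstream coordinates are offsets into this region string, and
   the region records its provenance (genome interval, source strand)
   so that every element can be mapped back exactly.
2. **Motif scanning.** Promoter candidates are exhaustive −35/−10
   hexamer pairs on the region's own strand under Hamming mismatch
   budgets and a spacer constraint. DnaA boxes are fixed-width windows
   scored by the fraction of positions matching the box consensus, on
   both orientations (DnaA boxes occur in either orientation around
   oriC; the promoter, by definition of the question, is sought only on
   the antisense strand).
3. **Classification.** The first acceptable promoter with a 16-bp
   spacer whose measured gaps to its two flanking boxes equal a defined
   pattern — (downstream, upstream) gaps of (16, 2), (14, 4) or
   (11, 7) nt — fixes the Group I/II/III call. A locus with candidates
   but no matching geometry is `unclassified`; a locus with no
   candidate under the budgets is Group IV, the promoterless
   architecture. Every Group I–III call obeys the conservation law
   `g_up + 6 + g_down = 24`: the 24-bp inter-box distance is the
   invariant, the promoter's position between the boxes is what varies.

The model is deliberately consensus-based. No position-weight matrix is
trained: the published evidence for the architecture is stated in
mismatch counts and exact spacings, and a proportional
(matching-fraction) box score reproduces that reasoning transparently.

## Parameters

All scanning parameters live in one `scan_params()` object:

| parameter | default | units | rationale |
|---|---|---|---|
| `consensus_m10` | `TATAAT` | — | SigA housekeeping −10 |
| `consensus_m35` | `TTGACA` | — | SigA housekeeping −35 |
| `max_mm10` | 1 | mismatches | loosest value among accepted antisense −10s (e.g. `TATAGT`) |
| `max_mm35` | 2 | mismatches | loosest value among accepted antisense −35s (`TACACA`, `ATGAAA`) |
| `spacer_range` | 15–18 | nt | brackets canonical SigA spacing; classification additionally demands exactly 16 |
| `box_consensus` | `TTATCCACA` | — | the *B. subtilis* DnaA-box consensus; a documented, configurable stand-in (see limitations) |
| `min_box_matches` | 7 of 9 | positions | admits the box variants observed around the locus while excluding background |
| `tss_offset` | 7 | nt | conventional distance from the −10 3' end to the start site; affects only the reported TSS, never classification |

Gap matching in the classifier is exact by default
(`gap_tolerance = 0`): a 2-bp shift of the promoter against the boxes
is precisely what separates Group I from Group II, so any tolerance
merges defined groups. The flag exists for exploratory scans only.

The flanking-box search windows (nearest edge within 12 nt on the −35
side, 20 nt on the downstream side) are conventions chosen to contain
every defined group with margin while keeping distant boxes from being
mistaken for flanks. On each flank the highest-similarity box wins;
similarity ties break toward the box nearest the −10, then toward the
`+` orientation. Box orientation is ignored for gap measurement — the
conserved quantity across species is spacing, not orientation.

## Coordinate conventions

Coordinates are 0-based half-open everywhere internally and in BED
output; GenBank- and GFF3-style 1-based inclusive coordinates appear
only at parse/serialize boundaries. "Intergenic" means strictly between
annotated gene bodies, with `gene` features preferred and CDS features
as fallback; anchor genes are matched case-insensitively by symbol,
with RefSeq product text ("chromosomal replication initiator", "L34")
as a fallback because symbols vary across annotations. Ambiguity is an
error listing coordinates, never a silent choice. Origin-wrapping
intervals are supported only on records declaring circular topology and
are represented with `source_end` exceeding the genome length; the
round-trip invariant (re-slicing the genome by the recorded provenance
reproduces the region byte-for-byte) holds for wrapped and unwrapped
intervals alike and is asserted in the test suite. `N` bases are
preserved and count as mismatches wherever they fall, so masked
sequence can never help a candidate.

Candidate ordering is contractual: promoters sort by total mismatches,
then |spacer − 16|, then leftmost −10, then leftmost −35. The last key
exists because a spacer of 15 and of 17 tie on |spacer − 16| and can
co-occur at one −10; without it the order of such ties would be an
accident of enumeration.

## The synthetic-locus generator

`generate_locus()` builds an annotated genome outward from the
*arrA*-sense region string: a planted consensus −10, a −35 with exactly
two seed-chosen mismatches at a 16-nt spacer (both published −35
examples carry exactly two), and two exact consensus boxes at the
requested group's gaps; Group IV loci get the two boxes at their
conserved 24-bp separation and no promoter. The background is i.i.d.
nucleotides at a configurable GC fraction (default 0.44,
approximately *B. subtilis*); a higher-order background model would add
realism the consensus-based scanner cannot see. The region is embedded
between minimal same-direction *rpmH*/*dnaA* gene stubs — only their
boundaries matter to extraction — optionally on the minus strand and
optionally rotated so the locus straddles the origin of a circular
molecule, which exercises every extraction path.

Backgrounds are rejection-sampled: a draw is accepted only when the
scan of the assembled region reports exactly the planted elements and
nothing else under the default budgets. Rejection keeps the accepted
background distribution clean (post-hoc editing of offending windows
would bias it); failure after the redraw budget (default 1000) is a
loud error naming the seed. Masking probability falls with region
length — the expected number of spurious 7-of-9 box windows grows
linearly — so the generator is practical at the default 300-nt region
and up to roughly 1 kb, not at multi-kilobase lengths. This bounds what
the generator emulates: real intergenic regions are not guaranteed free
of promoter-like noise, real DnaA boxes deviate from consensus, and
real cohorts were curated by eye over a multiple alignment. Passing
recovery tests on synthetic panels therefore demonstrates that the
pipeline's book-keeping and classification logic are exact, not that
the default budgets match any particular curator's judgement on real
genomes.

Determinism is pinned: the generator seeds a private RNG stream
(Mersenne-Twister, rejection sampling for discrete draws) and restores
the caller's stream, so identical arguments give byte-identical records
across platforms and panel generation never perturbs user code.

## Transcript arithmetic

`runoff_length()` and `isoform_lengths()` implement the product-size
arithmetic for linear templates: a run-off product spans TSS to
template edge inclusive; a terminated product spans TSS through the
terminator's last transcribed base inclusive. Terminator 3'-end
chemistry is out of scope, so "the terminator's coordinate" is defined
as the last included base. Enumeration stops at the first
non-readthrough terminator, and a run-off species is appended only when
every terminator is readthrough-permissive. Whether an observed short
isoform is a termination or a processing product is not modelled — the
readthrough flag is the only representation of that uncertainty.
Absolute genomic TSS positions are never inferred; layouts are stated
in template coordinates.

## Anchor alignment

The cross-species display is a gapless anchor alignment: each extracted
region is left-padded so the downstream (conserved) DnaA box of its
call starts in the same column, then right-padded to a rectangle. A
general multiple sequence alignment is deliberately not performed:
classification never depends on the alignment, the published display is
itself anchored on the conserved box, and a defined shift is exactly
testable where an MSA heuristic is not. Rows without a downstream box
(Group IV and unclassified-without-flanks) are excluded and logged.

## Design choices that were genuinely open

- **Which side is "upstream" of the −10.** Prose descriptions of the
  *B. subtilis* locus place the two boxes either "in the −35 region"
  or "between the −10 and −35", depending on the account. The package
  fixes upstream = the −35 side of the −10 in the *arrA*-sense reading
  frame, because only that reading makes the printed 24-bp inter-box
  distance arithmetically consistent across all three groups
  (2+6+16 = 4+6+14 = 7+6+11 = 24).
- **The box consensus.** The published analysis shades boxes by
  similarity but never prints the consensus it used; `TTATCCACA` (the
  classical *B. subtilis* DnaA box) with a 7/9 floor is an explicit,
  configurable stand-in, kept as data (a parameter), never hard-coded
  in logic.
- **Feature type for "intergenic".** Annotations differ on whether
  gene or CDS extents are authoritative; the package prefers `gene`
  and falls back to CDS, and treats the choice identically across
  formats so cross-format parses are comparable.

## Problem sizes in the test suite

The suite verifies the scanners against independent brute-force
enumeration oracles on random instances up to 2 kb, checks
strand-symmetry, round-trip and conservation-law invariants on
generated loci over both strands and topologies, and measures
planted-group recovery on a 200-locus positive panel plus 200 masked
negatives (zero promoter calls expected and observed). Scan outputs are
byte-compared across repeated runs to pin end-to-end determinism.
These sizes keep the whole suite within tens of seconds on one CPU
while exceeding the scales at which every failure mode so far has been
expressible.

## Known limitations

- The GenBank reader covers the GBFF subset the pipeline needs (LOCUS
  topology, gene/CDS features with gene/locus_tag/product qualifiers,
  ORIGIN blocks, multi-record files); it is guarded by a cross-format
  equality test against the independent FASTA+GFF3 route rather than by
  a full-grammar parser.
- Consensus/Hamming scoring cannot rank degenerate boxes the way a
  trained PWM would; this is a faithful rendering of the published
  reasoning, not a general promoter predictor.
- Applying the default budgets to real genome cohorts reproduces a
  deterministic version of a scan that, as published, included visual
  inspection of an alignment; counts on real data may differ at the
  margins for that reason alone.
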