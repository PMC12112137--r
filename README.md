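# arrascan

Detection and classification of the antisense-promoter architecture in
the *rpmH*–*dnaA* intergenic region of *Bacillus* genomes.

## The problem

In *B. subtilis*, an antisense RNA (ArrA) is transcribed from the strand
opposite the *dnaA* 5' leader, from a SigA-type promoter located in the
intergenic region between *rpmH* and *dnaA* — inside oriC territory.
The promoter is embedded between two DnaA binding sites, and across
*Bacillus* species the spacing of those two boxes is conserved even
where the promoter slides between them. This geometry sorts the
*rpmH*–*dnaA* regions of different species into four groups:

| Group | nt between −10 and downstream box | nt between −10 and upstream box |
|-------|-----------------------------------|---------------------------------|
| I     | 16                                | 2                               |
| II    | 14                                | 4                               |
| III   | 11                                | 7                               |
| IV    | no promoter                       | —                               |

In every promoter-bearing group the −10/−35 spacer is 16 bp and the
distance between the facing edges of the two DnaA boxes is the same
24 bp (2 + 6 + 16 = 4 + 6 + 14 = 7 + 6 + 11).

`arrascan` makes that comparative scan reproducible: it reads annotated
genomes (GenBank flat files or FASTA+GFF3), extracts the intergenic
region re-oriented 5'→3' on the strand antisense to *dnaA* with exact
coordinate provenance, enumerates −35/−10 hexamer pairs under Hamming
mismatch budgets (−10 ≤ 1 vs `TATAAT`, −35 ≤ 2 vs `TTGACA`, spacer
15–18 nt), detects DnaA boxes on both orientations by consensus
similarity (≥ 7/9 matches to `TTATCCACA` by default), and classifies
each locus by the exact gap rules above. A seeded synthetic-locus
generator with planted architectures and spurious-hit masking makes the
whole pipeline testable without downloading a single genome, and a
transcript-length module handles the run-off / terminator arithmetic
for predicted product sizes.

## Worked example

Generate a Group I locus, run the pipeline on it, then scan a 20-locus
cohort:

```r
library(arrascan)

gl  <- generate_locus("I", seed = 42)
reg <- extract_target_region(gl$genome)
call <- classify_locus(scan_promoters(reg), find_dnaa_boxes(reg),
                       genome_id = gl$genome$id)
call
#> <arch_call> synI_s42: Group I
#>   promoter: -35 CTGAAA (2 mm) ..16 nt.. -10 TATAAT (0 mm)
#>   gaps: 2 nt to upstream box, 16 nt to downstream box, 24 nt between boxes

panel <- generate_panel(c(I = 14, II = 1, III = 2, IV = 3), base_seed = 7)
res   <- scan_genomes(panel)
summary(res)
#> Antisense-promoter architecture scan
#>         group  n
#>             I 14
#>            II  1
#>           III  2
#>            IV  3
#>  unclassified  0

evaluate_panel(panel$truth, res$calls)
#> <panel_evaluation> 20 loci, recovery 100.0%
```

The call says: the first promoter candidate (a perfect −10, a −35 with
two mismatches, 16-bp spacer) has a DnaA box ending 2 nt upstream of
the −10 and another starting 16 nt downstream — the Group I geometry —
and the two boxes sit 24 bp apart, the distance conserved across all
three promoter-bearing groups. `scan_genomes(..., out_dir = ...)`
additionally writes `calls.tsv`, `summary.tsv`, `elements.bed`
(genome-frame coordinates) and `regions.fasta`. `anchor_align()`
left-pads extracted regions so every locus's downstream DnaA box sits
in the same column, the display convention for cross-species
comparison. A command-line front end with `scan`, `simulate`,
`evaluate` and `align` verbs is installed at
`system.file("scripts", "arrascan", package = "arrascan")`.

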