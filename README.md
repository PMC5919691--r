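# phasegrn

Infer a phasic transcription-factor co-regulation network from zonally
fractionated expression profiles and TF binding evidence.

## The problem

Tissues organised in differentiation gradients — the motivating system is
the cartilage growth plate, fractionated into proliferating (PZ),
pre-hypertrophic (PHZ), upper (UHZ) and lower (LHZ) hypertrophic zones —
express genes in *phases*: waves of transcription that peak in one zone
and fade in the next. Master regulators such as SOX9 and the
Hedgehog-pathway GLI factors drive these phases, often by binding the same
loci cooperatively. `phasegrn` implements, as a tested and reusable R
pipeline, the analysis chain that ties *where a gene is expressed* to
*who binds it*:

1. **Expression phasing.** Genes are called On/Off per zone against a
   global threshold `T = max(` On-reference level in its Off zone,
   Off-reference level in its Off zone `)` derived from two designated
   reference genes (a Sox9-like and a Col10a1-like profile). Variable
   genes are selected by the coefficient of standard deviation of their
   four zone means, `CSD = S / X̄ > 0.15`, and k-means (k = 4, unit-mean
   normalised profiles) assigns each to a phase cluster I–IV labelled by
   its peak zone.
2. **Motif analysis.** Conservation-filtered PWM scanning (min–max
   similarity `> 0.85`, minimum per-base phastCons-like score `> 300`,
   within 10 kb of a TSS), enumeration of cooperative SOX dimer half-site
   pairs `5'-AACAA(L_n)TTGTT-3'` with spacer `L_n ∈ [4, 16]`,
   discriminative k-mer enrichment by length-normalised foreground /
   shuffled-background ratio, and PWM library matching by mean
   column-wise Pearson correlation.
3. **Peak integration.** ChIP coverage peaks are called as strict
   windowed local maxima (25 bp windows for SOX9 ChIP-seq-style tracks,
   50 bp for GLI ChIP-chip-style tracks; height `> 15`, Poisson
   background p `< 0.05`), assigned to nearest-TSS genes with a region
   class (promoter `[TSS−1000, TSS+200]` > intron > 3'UTR > intergenic),
   and joined into SOX9–GLI linked binding regions (SGBRs): same-gene
   peak pairs with summit distance `< 250` bp (or `< 50` bp, stringent).
4. **Enrichment and network assembly.** Co-binding is tied to phasic
   expression with a two-tailed Fisher exact test on the 2×2 table of
   (phasic clusters I–III vs LHZ cluster IV) × (SGBR present/absent), and
   the relative-representation odds ratio as printed in the motivating
   analyses:

   `OR = (a / c) / ((a + b) / (c + d))`

   where `a`, `c` count SGBR-bearing genes in the phasic and reference
   groups and `a+b`, `c+d` are the group sizes (the canonical `ad/bc` is
   reported alongside). The resulting network places jointly-bound genes
   on an inner circle and singly-bound genes on an outer circle.

A seeded synthetic-data generator emulates every input — genome FASTA,
GFF3/BED gene models, bedGraph conservation and ChIP coverage, the
zone×replicate expression TSV — with known ground truth, so the whole
pipeline runs and is verified at desk scale without external data.

## Worked example

```r
library(phasegrn)

ds  <- simulate_dataset(sim_config(seed = 42))
ds
#> Synthetic dataset: 200 genes on chrS (1000000 bp), 137 planted sites,
#>   153 planted summits (SOX9, GLI1)

res <- run_pipeline(ds)
table(res$phasing$degs$cluster)
#>   I  II III  IV
#>  69  32   3  96

res$enrichment
#> 2x2 enrichment (PZ+PHZ+UHZ vs LHZ)
#>   counts: a=46 b=58 c=5 d=91
#>   relative-representation odds ratio: 8.492308
#>   canonical odds ratio: 14.43448
#>   two-tailed Fisher p: 4.554e-11

res$grn
#> GRN: 104 nodes (51 inner, 51 outer), 153 edges
```

Reading the output: of the 104 phasic genes in clusters I–III, 46 carry
an SGBR (a SOX9 and a GLI1 summit within 250 bp on the same gene)
against 5 of the 96 LHZ-cluster genes — an 8.5-fold relative
over-representation of co-bound loci among phasic genes
(p = 4.6e-11), matching the co-binding the generator planted
preferentially into clusters I–III. The 51 co-bound genes form the
inner circle of the exported network; SOX9- or GLI-only targets sit on
the outer circle. `write_dataset(ds, dir)` and `write_grn(res$grn, dir)`
emit all artifacts (FASTA/GFF3/BED/bedGraph/TSV/JSON/GraphML).

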