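---
title: "Methods: phasic co-regulation inference in phasegrn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phasic co-regulation inference in phasegrn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasegrn)
```

`phasegrn` connects zonal expression phases to transcription-factor
co-binding. This vignette describes the statistical procedure, its
assumptions, the tunable parameters and their defaults, the design
decisions taken where the underlying analysis conventions are ambiguous,
and what the synthetic-data generator does and does not emulate.

## Expression phasing

The input is a genes × (zone, replicate) matrix of linear-scale,
nonnegative expression intensities over the fixed zone order PZ, PHZ,
UHZ, LHZ (proliferating, pre-hypertrophic, upper and lower hypertrophic).
Three operations are applied to per-gene zone means (replicates are
averaged first):

**On/Off calling.** Two designated reference genes anchor the detection
threshold: an On-reference expressed early and silent in hypertrophy
(Sox9-like) and an Off-reference silent early and expressed late
(Col10a1-like). The global threshold is
`T = max(on-ref level in HZ, off-ref level in PZ)`, where HZ is the mean
of UHZ and LHZ. A gene is On in a zone iff its zone mean exceeds `T`,
and its category (common, PZ-/PHZ-/HZ-specific, other-combination,
all-off) is a pure function of the three booleans (PZ, PHZ, HZ).
*Design decision:* one global threshold rather than one per zone. The
source convention gives two reference levels (356 and 511 on the RMA
intensity scale) without stating a combination rule; the maximum of the
two Off-zone levels is the conservative choice (no zone can call a gene
On below the level a silent reference reaches), and is what
`call_on_off()` derives from the matrix itself rather than hard-coding
either number.

**Variability filter.** `CSD = S / X̄` over the four zone means, with
`S` the *sample* (n−1) standard deviation. *Design decision:* whether
the historical filter used sample or population SD is not stated; with
n = 4 the two differ by the factor `sqrt(4/3)` (≈ 1.155). The sample
version is the default and `sample_sd = FALSE` exposes the other. The
cut-off (default 0.15) is a strict inequality; a gene at exactly 0.15 is
excluded. CSD is computed on linear-scale means — the scale the
reference thresholds are printed on — not log values. Genes with zero
mean in every zone have undefined CSD, are excluded from selection, and
are reported in the `undefined` attribute.

**Phase clustering.** k-means (k = 4) on zone-mean vectors normalised
per gene to unit mean, so that profile *shape* rather than magnitude
drives the clusters. Seeding uses `stats::kmeans` with `n_init = 25`
restarts under a caller-supplied seed, making results deterministic.
Clusters are relabelled I–IV by their centroid's argmax zone (I: PZ
peak/decreasing, II: PHZ, III: UHZ, IV: LHZ). Degenerate case: if two
centroids peak in the same zone, relabelling falls back to ordering
centroids by their expression-weighted zone index and a warning plus a
`relabel_fallback` attribute are emitted.

## Motif analysis

**PWM similarity** is min–max normalised:
`(raw − min) / (max − min)` with `raw` the sum of per-position observed
base frequencies and min/max the sums of column minima/maxima. The score
is exactly 1 on consensus windows and 0 on anti-consensus windows,
making the "similarity over 85%" convention scale-free. `N` bases score
the uniform background 0.25. PWM columns are normalised with
pseudocount 0.01.

**Conserved-site scanning** emits a site iff similarity `> sim_min`
(default 0.85, strict), minimum per-base conservation over the site
`> cons_min` (default 300 on a 0–1000 phastCons-like scale, strict) and
the site midpoint lies within `tss_window` (default 10 kb) of some TSS.
*Design decision:* the minimum per-base score is the strictest reading
of a "conservation score over 300" requirement; using the site mean is
a one-line change but the minimum guarantees every base of an accepted
site is conserved. Both strands are scanned; a minus-strand hit is
reported at the same interval with strand `-`. Coordinates are 0-based
half-open internally, converted to the 1-based conventions of
GFF3/GRanges only at the I/O boundary.

**Dimer enumeration** reports every occurrence of
`AACAA + spacer(L_n) + TTGTT` with `L_n` in `[spacer_min, spacer_max]`.
Overlapping occurrences are all reported. Because the arrangement
half-site + spacer + reverse-complement(half-site) is its own reverse
complement, the forward scan finds every genomic occurrence; each locus
is reported once. *Design decision:* the published spacer ranges are
internally inconsistent (4–11 vs 4–13 vs 4–16 depending on zone and
counting origin); the default range is the widest, `[4, 16]`, and both
bounds are arguments — no attempt is made to resolve the original
intent.

**Word enrichment** is a deliberate functional substitute for a full
discriminative motif-enumeration program: exact k-mers are counted with
overlaps on both strands in foreground promoters and shuffled
backgrounds, and ranked by the pseudocount-adjusted, length-normalised
ratio `((fg + 1) / (bg + 1)) · (bg_windows / fg_windows)`, reporting the
top 50 words at ratio ≥ 2 (both defaults). Shuffling preserves each
sequence's mononucleotide composition exactly. Likewise
`dimer_spacer_enrichment()` substitutes a per-spacer-length one-sided
binomial test (foreground count against the background rate, background
pseudocount 1) for a motif-EM run over half-site flanking sequences.
Both substitutes take the same inputs and produce the same kind of
output (ranked words; per-spacer p-values) as the programs they stand
in for, with transparent, testable statistics.

**PWM library matching** scores all ungapped alignments on both strands
with at least 4 overlapping columns by mean column-wise Pearson
correlation. Degenerate columns (zero variance) compare as 1 when
identical and 0 otherwise, so a self-match is always exactly 1.

## Peak integration

**Peak calling** declares position `i` a summit iff its coverage
strictly exceeds everything in the `window_bp` positions to its left and
is at least everything in the window to its right — i.e. the strict
windowed maximum with ties broken to the leftmost position. This rule
implies summits of one track are always more than `window_bp` apart. A
summit is emitted iff height `> min_height` (default 15, strict) and its
Poisson upper-tail p-value against the track-wide mean coverage is below
`p_max` (default 0.05). *Design decision:* the upstream ChIP pipelines'
p-values are not reproducible from published cut-offs alone; a Poisson
background with the genome-wide mean rate is the standard simple model
and respects the published height/p cut-offs. Window conventions: 25 bp
for SOX9 (ChIP-seq-like) and 50 bp for GLI (ChIP-chip-like) tracks.

**Gene assignment** is nearest-TSS, with exact ties going to the
lexicographically smaller gene id (documented, deterministic). Region
class uses the precedence promoter (strand-oriented
`[TSS−1000, TSS+200]`) > intron > 3'UTR > intergenic, evaluated at the
summit (or site midpoint). Peaks outside their assigned gene's
intergenic bounds (the span from the upstream neighbour's body to the
downstream neighbour's) are dropped and counted.

**SGBRs.** A linked binding region is a (SOX9 peak, GLI peak) pair on
the *same* gene with summit-to-summit distance strictly below
`max_interpeak` (250 bp relaxed, 50 bp stringent). *Design decisions:*
distance is summit-to-summit (edge-to-edge is not well defined for
point summits), and the same-gene requirement reflects that linked
regions are meaningful downstream only as per-gene evidence. Site–peak
linkage (`link_sites_to_peaks()`) uses the site midpoint and the same
strict-inequality convention; the published distance appears as both
200 and 250 bp in different places, and 250 is the configurable default.

## Enrichment and the network

The 2×2 table contrasts phasic genes (clusters I–III, i.e. peak zones
PZ/PHZ/UHZ) against the LHZ cluster IV, split by SGBR presence.
*Design decision:* the source text describes the grouping both as
{PZ, PHZ, HZ} and as {PZ, PHZ, UHZ} vs LHZ; the latter is the default
and `phasic_zones` accepts either.

Two association measures are reported. The *relative-representation
ratio* `(a/c) / ((a+b)/(c+d))` is the formula printed in the motivating
analyses; it is not the canonical odds ratio `ad/bc`, so both are
computed and clearly named (`relative_risk`, `odds_ratio`),
with the relative-representation form driving reported numbers for
fidelity and the canonical form available for statistical comparability.
Degenerate cells: `a = 0` gives ratio 0; `c = 0` flags the ratio
undefined (infinite when `a > 0`) while the p-value is still computed.

The two-tailed Fisher p-value is computed in-package by hypergeometric
enumeration under the probability-mass rule (sum of the probabilities of
all tables at most as probable as the observed, relative tolerance
1e-7), which matches `stats::fisher.test`; the doubling rule is exposed
as an option. The tests use `stats::fisher.test` as an independent
oracle rather than as the implementation, keeping the dual-route check
meaningful. No multiple-testing correction is applied in distance
sweeps (matching the original analysis); a Benjamini–Hochberg column is
emitted for information only.

`assemble_grn()` builds one edge per (regulator, target) from the
binding-region tables, upgrades evidence to SGBR for co-bound genes,
and assigns the ring attribute: inner iff the gene has an SGBR, outer
otherwise. Node attributes carry the phase cluster and zone-mean trend
used for colouring.

## The synthetic-data generator

`simulate_dataset()` emulates all five inputs under one seed:

- **Gene models:** non-overlapping bodies (default 1.5–3 kb) placed with
  randomly distributed gaps on one 1 Mb chromosome, random strand, 1–3
  introns each, promoters and per-gene intergenic bounds derived.
  Placement distributes the leftover length proportionally to uniform
  weights on top of a 2 kb minimum gap, so non-overlap holds by
  construction and infeasible configurations fail with a capacity error.
- **Sequence:** i.i.d. background at configurable GC (default 0.42) with
  planted monomer consensus sites and `AACAA(L_n)TTGTT` dimers
  (reverse-complemented on minus-strand placements).
- **Conservation:** background mean 100, planted-site mean 500, Gaussian
  jitter clamped symmetrically at 3 SD — clamping preserves the
  configured means exactly and keeps planted-site minima above
  500 − 3·25 = 425, safely over the 300 cut-off.
- **ChIP coverage:** Poisson background (mean 2) plus Gaussian bumps of
  height 40 at planted summits; co-bound loci receive a SOX9 and a GLI1
  bump within ±40 bp of each other. The default bump width is
  `chip_peak_sd = 20` bp (a sharp TF peak, ~100 bp across): the summit
  must be identifiable to within half a 25 bp calling window, which
  requires the apex curvature to dominate Poisson background
  fluctuation; much wider bumps have statistically flat apexes whose
  argmax wanders under noise.
- **Expression:** cluster mean profiles on the RMA-like intensity scale
  (hundreds, matching reference thresholds of a few hundred) with
  Gaussian replicate noise (default SD 60, triplicates), truncated at
  zero, plus the two reference genes whose Off-zone levels are 356 (HZ)
  and 511 (PZ) by construction.

Default cluster proportions follow the motivating four-cluster split
(654 : 299 : 31 : 907), and co-binding is planted in 50% of phasic
(cluster I–III) versus 5% of LHZ-cluster genes — the contrast the
enrichment stage is expected to detect.

**What the generator does not emulate:** dinucleotide or repeat
structure of real genomes, probe-level microarray noise, mappability or
input-chromatin biases in ChIP coverage, multi-chromosome genomes, and
correlated replicate noise. Passing the planted-signal tests therefore
demonstrates algorithmic correctness — every operation equals its
brute-force oracle and recovers what was planted — not robustness to
every artefact of real data.

## Problem sizes and determinism

The verification suite runs the full pipeline on 200 genes over 1 Mb
(the default configuration), checks each core operation against
exhaustive oracles on 100 randomized small fixtures, and calibrates the
null co-binding test over 500 replicates at the contingency level
(re-drawing co-binding flags with equal fractions over the fixed
cluster structure — exactly the stage the calibration concerns, without
re-simulating genomes). All randomness flows from explicit seeds; every
generator derives an independent stream from the configuration seed, so
outputs are byte-identical across runs and machines.

## Known limitations

- One chromosome; multi-chromosome support would be a thin extension of
  the coordinate plumbing but is not implemented.
- The On/Off threshold rule and the CSD standard-deviation convention
  are choices among ambiguous alternatives (documented above); both are
  configurable, and conclusions that hinge on them should be checked
  under the alternative.
- Word and dimer enrichment are discriminative substitutes, not motif
  discovery: they will not find motifs that are not exact words or
  half-site pairs.
- Genome-scale peak sets from real ChIP experiments depend on upstream
  processing this package does not reproduce; `call_peaks()` expects
  per-base coverage that is already background-comparable, and pre-called
  peaks can be supplied directly to `assign_peaks_to_genes()`.
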