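---
title: "Detecting alien introgressions from alignment coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting alien introgressions from alignment coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introscan)
```

## The problem

Modern wheat cultivars carry large blocks of chromatin introgressed from
wild relatives: a ~33 Mb *Aegilops ventricosa* segment (2NvS) on the short
arm of chromosome 2A, whole-arm 1AL:1RS / 1BL:1RS translocations that
replace a wheat short arm with the short arm of rye chromosome 1R, and
smaller haplotypes such as the greenbug-resistance region carried on an
assembled contig from the distal end of 7D. None of these are visible as
ordinary variant calls when reads are aligned to a single reference that
lacks the alien sequence: the reads simply fail to map, and the
introgression appears only as a hole (or, with the right reference, a
surplus) in alignment coverage.

`introscan` turns those coverage footprints into explicit
presence/absence calls per line, starting from the per-sequence summaries
that `samtools coverage` emits (breadth, mean depth, mean mapping
quality) and per-megabase binned read counts. Around the detectors it
implements the supporting statistics such a panel analysis needs: site
filtering by minor allele frequency (MAF), missingness and
heterozygosity; variant-type and sequence-ontology (SO) impact
summaries; per-base nucleotide diversity; and neighbor-joining trees
from identity-by-state (IBS) distances.

## Decision procedures

Three detectors, one per introgression class. All thresholds live in
`pav_thresholds()` and every call records its evidence, so a decision is
always auditable.

**Segment (cross-reference gain).** For a segment present in one
reference (e.g. a locally adapted cultivar assembly) but not another
(the standard reference), a carrier line gains coverage on the
homologous chromosome when switching references, because its
segment-derived reads finally map. With coverage already expressed in
percent, the statistic is the difference in percentage points,

$$\Delta = \mathrm{cov}_\text{match}(\mathrm{2A}) -
           \mathrm{cov}_\text{other}(\mathrm{2A}),$$

and the call is *present* when $\Delta \ge$ `delta_pp_min` (default 2),
*absent* when $\Delta < 0$ (non-carriers lose the native segment
instead), *ambiguous* between. A gain "by ~2%" could also be read as
relative percent; we use percentage points because coverage is itself a
percentage, and the threshold is configurable either way.

**Arm translocation (loss + composite validation).** A replaced short
arm removes roughly a fifth to a quarter of a chromosome's alignable
sequence, so the screen compares the target chromosome's breadth with
the line's baseline — the unweighted mean breadth over the remaining
chromosomes (`line_baseline()`; unweighted because chromosome lengths
are similar and the quantity is already a fraction; a length-weighted
variant is a one-line change via `exclude`). A relative drop
$\ge$ `drop_rel_min` (default 0.15, sitting between the ~23% drop a
whole short arm produces and chromosome-to-chromosome noise) flags a
candidate. Breadth, not mean depth, is screened: depth fluctuates with
library size while breadth saturates, making the arm-sized hole the
cleaner signal. Validation then aligns the panel to a *composite*
reference that includes the alien chromosome: carriers cover the
homologous arm — about 30% of the alien chromosome — at confident
mapping quality (mean MQ $\ge$ 30), while non-carriers show only trace
alignment to conserved sequence: breadth under 2% and mean depth under
1x, at MQ below the usual 20 filter. The present-call breadth floor
defaults to 20%, not 30%: the observed carrier level is ~30%, and 20
separates it from the <2% non-carrier class with margin on both sides.
Anything between the two regimes stays *ambiguous* — a first-class
outcome, not an error.

**Contig haplotype (relative coverage change + differential regions).**
For a haplotype carried on an assembled contig appended to the
reference, the statistic is the absolute change between the contig's
coverage and that of the reference region it maps to. Carriers cover
most of the contig (small change, ~10%), non-carriers miss its unique
regions (~30% drop); the boundary defaults to 20%, midway between the
two observed regimes, with strict `<` for presence. Independently,
`find_differential_regions()` scans the binned depth tracks for bins
where the carrier-group mean exceeds the non-carrier mean by a factor of
`region_ratio_min` (default 5, with a pseudocount of 0.1x stabilising
the denominator) while the carrier mean clears
`region_carrier_depth_min` (default 2x); qualifying bins merge across
gaps of at most `region_merge_gap` bins. The ratio rule and its
parameters are our algorithmic choice — the target observation is the
*outcome* (a few sharply carrier-specific regions), not a procedure —
so everything is exposed in `pav_thresholds()`.

## The synthetic panel generator

The generator produces exactly the inputs the detectors consume, under
a stated statistical model, with a ground-truth table — so detector
behaviour can be validated end-to-end without touching an aligner.

Per line and sequence, each bin of width $B$ has an *alignable length*
$a = m + \varepsilon c$, where $m$ is the length matching the line's
genome, $c$ the length where only conserved background remains, and
$\varepsilon$ (`epsilon_conserved`, default 0.01) the conserved
fraction of alien sequence. Mapped reads are
$R \sim \mathrm{Poisson}(dB_a/L)$ with $d$ the line's depth, $L$ the
read length and $B_a = a$; covered bases follow the Lander–Waterman
expectation on the alignable part,
$a\,(1 - e^{-d_\text{loc}})$ with $d_\text{loc} = RL/a$. The crucial
modelling point is that conserved homology is *localised*: a
non-carrier's reads pile onto the conserved ~1% of the alien
chromosome rather than spreading thinly everywhere, which is what keeps
non-carrier breadth near $\varepsilon$ (~1%) and mean depth near
$\varepsilon d$ (<1x) — the trace-alignment regime — instead of an
unrealistic 10% breadth of scattered single reads. Mean MQ is the
read-weighted mix of a high value (35) for matching alignments and a
low value (12) for conserved-background alignments.

Defaults are the study conditions the package is built around: 30
inbred lines at 5–20x depth (drawn uniformly per line — individual
depths are a modelling choice, exposed in the config), a wheat-like
genome of 21 chromosomes, 1 Mb bins, one 2NvS-like segment (2.5% of
2A), one 1RS-like translocation (23% of 1B, matching the observed ~23%
coverage drop) with a 40 Mb alien chromosome whose first 30% is the
translocated arm, and one 2.8 Mb haplotype contig binned at 100 kb with
three carrier-unique regions (1, 3 and 2 bins) plus ~10% junk bins that
no line covers, so that carriers show a ~10% contig-vs-reference change
and non-carriers ~30%. Chromosomes are scaled to 40 Mb (wheat's are
~400–800 Mb): every decision statistic is a ratio or percentage, so
scale cancels, and the whole panel simulates in seconds.

Genotypes: each site has a true alternate frequency drawn uniformly on
(0, 0.5]; inbred lines are homozygous carriers with that probability,
heterozygous calls occur at a residual error rate (0.5%), and a
genotype is missing with probability $e^{-d/2}$, tying missingness to
depth (~8% at 5x, negligible at 20x). Both the MAF spectrum and the
missingness law are package choices — the field reports no canonical
form — and are config-exposed.

What the generator does *not* emulate: sequence-level realism (repeats,
GC bias, paired-end structure, mappability), population structure and
linkage between sites, partial or nested introgressions, and
reference-assembly errors beyond the junk bins. Passing tests therefore
demonstrate that the decision procedures are correct *given* coverage
summaries of the assumed shape, not that the thresholds are optimal on
any particular real panel.

## Variant statistics

Sites are typed by allele length (SNP / INS / DEL; equal-length
multi-base substitutions are rejected as unsupported, and the VCF
reader accepts biallelic records only, keeping every downstream count
cleanly type-partitioned). Filtering keeps a site when MAF $\ge$
`maf_min`, missingness $\le$ `max_missing` and heterozygosity $\le$
`max_het`, all inclusive (the natural reading of "maximum 10%").
Denominators differ deliberately: missingness is over all samples,
heterozygosity over called samples — the quantities answer different
questions (how much data is absent vs how trustworthy the calls are) —
and both choices are documented here because other conventions exist.
A useful analytic consequence: in a panel of 30 homozygous diploids one
carrier contributes at most $2/60 = 3.3\%$ allele frequency, so a 5%
MAF floor structurally requires at least two carrier individuals, while
3% admits singleton-carrier alleles; relaxing 5% to 3% can therefore
only grow the surviving set.

SO terms map to snpEff-style impact tiers (HIGH: stop gained/lost,
start lost, frameshifts, splice donor/acceptor; MODERATE: missense,
in-frame indels and other non-disruptive protein changes; LOW:
synonymous, splice region, incomplete terminal codon, start/stop
retained; MODIFIER: intronic, up/downstream, non-coding, intergenic),
with multi-term variants classified by their most severe term and
unknown terms demoted to MODIFIER with a warning. Functional classes
follow the conventional missense/nonsense/silent triple. Arm binning
assigns positions at or before the centromere to the short arm
(`<chrom>.1`) — the boundary site is arbitrary and documented.

## Diversity

Per-site diversity uses the unbiased estimator
$\hat\pi = \frac{n}{n-1}\bigl(1 - \sum_i p_i^2\bigr)$ over the $n$
called alleles, which equals the average pairwise allele difference
(the test suite checks this identity against brute-force enumeration).
Windowed tracks divide the summed site values by the *window width* in
bp, not by callable bases: monomorphic sequence contributes zero
difference but real length, which is what makes per-base values
comparable across windows; a callable-base denominator would need a
callability mask the coverage summaries cannot provide.

The IBS distance between two samples is one minus the mean shared-allele
fraction over co-called sites. Neighbor joining is implemented in the
package (Saitou–Nei $Q$-minimisation with branch lengths from the
standard formulas) rather than delegated, for one reason: exact ties in
$Q$ are broken by the lexicographic order of the joined pair's labels,
making the tree a deterministic function of the input — a property the
usual implementations do not promise and reproducible pipelines need.
Negative branch lengths are not clamped; on additive inputs they cannot
occur, and on real data clamping would silently distort path distances.
By default the tree and the diversity track are computed from the
MAF5-filtered site set (the raw set is dominated by singleton and
near-monomorphic sites); any other set can be passed explicitly.

## Pipeline and numerical conventions

`run_pipeline()` executes simulate → pav → contig → vcfstats →
diversity under one configuration, writing every output with an MD5
manifest; reruns with the same seed are byte-identical, and each
generator consumes an independent sub-seed so stages can be rerun
selectively. Coordinate conventions are fixed once at format
boundaries: coverage tables are 1-based inclusive (samtools dialect),
bedgraph is 0-based half-open, bin indices and region spans are 0-based
half-open so that `span = end - start` holds everywhere internally —
the convention that the distal-7D haplotype region table satisfies row
by row. Region gaps are computed from aligned block lengths, never as
`ref_span - contig_span`, because a region's gap depends on how its
blocks land on the reference, not just on its endpoints. Composite
contigs order members by target start with lexicographic contig-id
tie-breaks.

Test and acceptance problem sizes (a 30-line panel on 40 Mb
chromosomes, 3,000-site genotype matrices, 50x30 filter oracles,
1,000-column diversity oracles, 4–8 taxon tree recovery) were chosen so
the full suite exercises every closed-form expectation at comfortable
statistical margins while running in well under a minute.

## Known limitations

Breakpoint-resolution mapping of introgression boundaries, haplotype
phasing, read alignment itself, de novo assembly and effect-prediction
engines are out of scope: the package consumes coverage summaries,
alignment records and pre-assigned SO terms. Thresholds are calibrated
against the coverage signatures of large (arm- to segment-scale)
introgressions in inbred panels at 5–20x depth; small introgressions,
heterozygous material, or very low depth would need the thresholds —
all exposed — revisited.
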