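---
title: "Methods: structural variant detection from nick-label optical maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural variant detection from nick-label optical maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nicksv` detects large (>2 kb) structural variants from optical genome
maps: ordered positions of fluorescent labels deposited at the
recognition sites of a nicking endonuclease (Nt.BspQI, motif GCTCTTC,
by default) along single DNA molecules of 150 kb and up. This vignette
is the package's own account of its models, parameter choices, and
limitations. Everything empirical stated here is computed by the test
suite (`tests/testthat/`) or by `scripts/acceptance.R`; no numbers are
quoted from elsewhere.

## The data and its error model

A *label map* is a sorted vector of label positions (bp) plus a total
length. Reference maps come from in silico digestion: all motif
occurrences on both strands, with occurrences closer than the optical
resolution (450 bp) merged to the midpoint of the run. Single-molecule
maps differ from the underlying genome by four instrument effects,
which both the simulator (`noise_model()`) and the callers share:

* a true label is missed with probability `fn_rate` (default 0.06);
* false labels arise as a Poisson process (`fp_per_100kb`, default 0.6);
* an inter-label distance `d` is measured as `d + e`,
  `e ~ N(0, s(d))` with `s(d)^2 = (1000*sizing_sf)^2 + (sizing_sr*d)^2`
  (defaults 0.20 kb and 0.01 — `sizing_sf` is in kb, following the
  convention of the vendor's `-sf` flag);
* labels within 450 bp merge.

Molecules are drawn to a target depth of 79x with a length floor of
150 kb and length N50 of 262 kb. Only the floor and the N50 constrain
the length law, so the simulator uses a log-normal (sdlog 0.55) whose
meanlog is solved in closed form so that the truncated law attains the
N50; this is a stand-in for the unknown true distribution, and nothing
downstream depends on its shape beyond the floor and N50.

Consensus contigs are emulated, not assembled: each haplotype
chromosome yields contigs (optionally fragmented at a Poisson break
density) whose noise is the molecule noise attenuated by
`1/sqrt(coverage)` — the error reduction expected from averaging
independent molecules. Real consensus assembly errors (chimeric joins,
collapsed repeats) are *not* emulated, so passing tests say nothing
about assembler artefacts.

## Alignment

Maps are aligned by a local dynamic program over label chains
(`align_map()`, compiled in C++). A chain pairs query and reference
labels monotonically; each pair earns `match_bonus` (3), skipped
labels cost `cq`/`cr` (1.5) each, and a step spanning distances
`dq`/`dr` pays `min((dq-dr)^2 / (sf_pen^2 + (sr_pen*dr)^2),
outlier_cap)`. Three numerical choices matter:

* **Skip cap `K = 9`.** A bridged indel hides all its labels in one
  chain step; at ~10 kb label spacing a 50 kb indel carries a
  Poisson(5) label load, so `K = 5` would leave half of the largest
  indels unbridgeable. `K = 9` keeps that failure mode under ~3%.
* **Outlier cap (12).** Without a cap, one large-indel interval severs
  an otherwise perfect alignment; with it, the indel is bridged and
  handed to the interval-distance test.
* **Chimeric cut (25).** A chain crossing a rearrangement tends to
  limp through it by loosely pairing interior labels. The worst
  (minimum-sum) stretch of chain steps is excised when its net score
  is −25 or worse *and* it contains at least two steps at −5 or worse;
  a bridged indel is a single bad step flanked by good ones and is
  deliberately never cut. Freed labels re-enter the split-alignment
  recursion, which re-aligns every unaligned run of ≥ 5 labels in both
  orientations — this is how inversion interiors surface as
  opposite-orientation segments.

Against long references a cheap `K = 2` scan first locates the
placement and the full program runs on a ±30-label window; small
instances always use the exact full program, and the test suite checks
exact score equality against an independently written exhaustive
oracle on 500 random instances.

**Confidence.** The pipeline keeps alignments with confidence > 9,
defined as `-log10` of the probability that a label-shuffled query
reaches the observed score anywhere on the reference. An empirical
permutation estimate cannot reach 9 (10^4 permutations bound it near
4), so the null best-score distribution — estimated from shuffled
queries against a reference window — is fitted with a Gumbel law, the
standard extreme-value model for local alignment scores, and the tail
is extrapolated with a Bonferroni factor for the full search space.
The scale of this score is internal to the package; the threshold 9 is
comparable only within it.

## Indel calling (MR / CR / MCR)

For every pair of labelled sites that is consecutive in some alignment
chain — adjacent on the reference, or adjacent on a molecule when
intervening reference sites are absent from it — the reference
distance `d0` is compared with the distances `d1..dn` on every aligned
map spanning both sites. Collecting pairs adjacent *on the molecule*
is essential: a deletion removes its interior reference labels, so the
only informative pair brackets several reference intervals.

Each distance is modelled as Normal around the true spanned length
with the sizing law above, and five hypotheses are fitted by maximum
likelihood: no indel; homozygous indel (`t = d0 + delta`); heterozygous
insertion / deletion (equal-weight mixture of `d0` and `d0 + delta`,
`|delta|` at least the 2 kb floor); and a two-allele hypothesis (two
indel alleles, fitted by EM from five deterministic quantile starts).
Three guards keep the test honest:

* every hypothesis shares a small uniform outlier component (weight
  0.03), so a single misaligned molecule cannot flip a homozygous call
  to heterozygous;
* the two-allele hypothesis needs its alleles separated by at least
  the 2 kb floor (closer alleles are indistinguishable at this
  resolution) and must beat the best one-allele hypothesis by a full
  log10 unit, since it spends an extra free parameter;
* mixture weights are fixed at 1/2 (the diploid expectation) rather
  than estimated, which stabilises small-n fits.

A call is emitted when the winning alternative beats the null by
`lr_cutoff_log10` (default 3, calibrated in the test suite to at most
one false call per SV-free 5 Mb replicate), the size estimate exceeds
2 kb, and at least `min_support` molecules favour the variant
component (posterior > 0.5). The default support threshold is 10; the loose threshold 6 is the
configuration the benchmarks run, trading a little specificity
(re-verified on SV-free replicates) for sensitivity at loci where only
a minority of spanning molecules bridge the event.
Overlapping site-pair keys that bracket the same event are reduced to
the narrowest bracketing interval.

The CR route compares consensus contigs with the reference directly
(calls without zygosity); the MCR route composes molecule-to-contig
with contig-to-reference alignments (each molecule assigned to its
best-scoring contig, ties broken by contig id) and reuses the MR test.
`bagging_normalize()` resamples a locus's molecules with replacement
to what one million aligned molecules would give, for coverage
normalisation across samples.

**A real detection limit.** When an inserted segment's label pattern
happens to contain a label near the reference register (probability
grows with insertion size), the aligner prefers pairing that label
over honestly bridging the insertion, and such molecules report a
reference-like distance. Heterozygous insertions therefore rest on the
minority of molecules that do bridge; this is why insertion recall
targets sit below deletion targets here, as in optical-map studies
generally.

## Complex SVs

Contigs are split-aligned; junctions between consecutive segments are
typed by signature: different chromosomes — inter-chromosomal
translocation; same chromosome over 5 Mb apart — intra-chromosomal
translocation; within 5 Mb with opposite orientations — inversion;
overlapping reference intervals — duplication. Each candidate is then
adjudicated against the molecules: split-aligned molecules whose
junctions match the candidate within a 200 kb window support it;
molecules contiguously aligned across a breakpoint reject it. Each
molecule contributes the minimum over its adjacent split maps of
`n/(n+l) * log(n)` (`n` matched sites, `l` extra or missing sites;
natural log — the comparison is base-invariant), rejecting molecules
being notionally split at the breakpoint; after per-molecule
de-duplication the candidate is accepted only when the summed
supporting score strictly exceeds the rejecting score. Small
inversions (≥ 4 labels) that survive inside an apparently contiguous
alignment are found by re-aligning, in reversed orientation, the
labels under every substantially negative stretch of the chain;
inverted spans over 5 Mb are re-typed as intra-chromosomal
translocations. Tandem CNVs are counted exactly between unique flank
patterns (`count_tandem_units()`, distance-pattern matching at 15% per
interval).

Tandem-duplication detection needs every copy of the unit to anchor
its own split segment, i.e. ≥ 5-6 labels per unit; the duplication
benchmark therefore places units on label-dense windows, and units
with 2-4 labels are a documented blind spot (they surface instead as
large insertions in the indel module).

## Genome classification and population structure

The genome is partitioned from two run-length tracks: loci covered by
two or more consensus scaffolds, or by none despite individual
assembly coverage at or above 60% of the cohort (92 of 154; half on
chrY), are complex candidates; loci under the threshold are low
coverage; the rest low complexity. A region's SV inventory makes it
complex when ≥ 3 distinct recurrent SVs remain after discarding
≤ 10 kb indels, with at least one > 100 kb when only indels remain.
Feature enrichment uses a permutation test (default 10,000 placements,
lengths preserved, uniform over the genome minus the inaccessible
space, add-one correction); overlap *events* are counted. Reference
N-gap sizes are estimated from spanning alignments as query distance
minus the reference distance outside the gap — negative values mean a
deletion swallowed the gap's flanks.

Cohort analyses merge per-sample calls into loci by single linkage:
same-type calls (multi-allele records match either indel type) whose
sizes agree within max(2 kb, 20%) and whose intervals either overlap
reciprocally by half or have midpoints within 10 kb — the midpoint
clause matters because bracketing intervals vary with which flanking
labels each sample's molecules anchored, and insertions are point
events. The occurrence matrix codes hom 2 / het 1 / unknown 1, feeds
balanced-subsample sharing fractions, a neighbour-joining tree on
Euclidean distances between population allele-frequency vectors, an
unscaled column-centred PCA, and per-locus one-way ANOVA of SV sizes
across super-populations (≥ 10 carriers, Bonferroni at 0.05). Trio
concordance asks, for each child call, whether a matching call exists
in at least one parent.

The cohort simulator draws per-population allele frequencies from the
Balding-Nichols Beta model around a global frequency (`divergence` is
the F-like dispersion; a two-component vector nests populations into
clades) and genotypes under Hardy-Weinberg. It emulates frequency
structure only — no linkage, no admixture, no sex chromosomes — so
population-level tests validate the statistics, not demographic
realism.

## Problem sizes and what the tests show

All validation runs at desk scale, chosen so the full suite completes
in well under half an hour: digestion oracles on 1 Mb of sequence;
aligner oracle equality on 500 small instances; 200 implanted indels
of 3-50 kb across four 12 Mb genomes at 79x; twenty SV-free 5 Mb
replicates; four single-type complex-SV scenarios; twenty trios on
1.5 Mb genomes; cohort analyses on truth-derived calls (the
molecule-level pipeline's accuracy being certified separately). These
sizes establish correctness of the algorithms and calibration of the
statistics under the stated error model; they do not establish
genome-wide runtimes, behaviour in segmental duplications or other
repeat-dense sequence contexts (the simulator's reference is a
homogeneous Poisson label process), or robustness to assembly
artefacts in real consensus maps.
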