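---
title: "Methods: SLAF genotyping, BC1 linkage maps and ED-based bulked-segregant scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SLAF genotyping, BC1 linkage maps and ED-based bulked-segregant scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`slafmap` implements, end to end, the computational chain behind a
reduced-representation (SLAF/RAD-style) genetic mapping study in a first
backcross (BC1) population, together with a synthetic-data generator that
produces every input the chain needs with full ground truth. This vignette
explains the models behind each stage, the parameters that matter, the
numerical choices we made where the design was open, and what the package's
tests do and do not demonstrate about real data.

## The study design being modelled

Two fully homozygous inbred parents differ at biallelic tag loci spread over
six linkage groups. Their F1 is backcrossed to the recurrent parent, giving
148 BC1 offspring in the default configuration; at every informative marker
(pattern aa×bb) each offspring is either homozygous for the recurrent allele
(`aa`) or heterozygous (`ab`), segregating 1:1. A single sex-determining
locus sits on one linkage group: an offspring is male exactly when its F1
gamete carries the donor ("Y") allele there, so sex itself segregates 1:1
and is completely linked to one chromosomal position. Sequencing yields
tag-level read counts per individual; depth is the only source of
missingness.

## Synthetic data generator (`simdata`)

`generate_genome()` draws i.i.d. nucleotides at a target GC content (default
0.38, typical for the emulated genome) and can overwrite a fraction of the
sequence with copies of one block so that repeat-derived tags exist.
`digest_genome()` performs the in-silico double digest: every occurrence of
either recognition site, forward strand only, cut at the 5' end of the site,
fragments retained when their length falls in the size-selection window
(default 364–414 bp). Scanning only the forward strand with a fixed cut
offset is a deliberate, bit-reproducible simplification; for the palindromic
sites of typical type-II enzymes it loses nothing.

`simulate_cross()` generates each F1 gamete per linkage group as a Markov
chain along marker positions: the first allele is drawn 50/50 and switches
between adjacent positions with the recombination fraction implied by the
configured map function. Under Haldane (the default for simulation) this is
the exact no-interference crossover process. Under the Kosambi option the
chain uses Kosambi-inverse adjacent recombination fractions — consistent
with the Kosambi map function interval by interval, but still a Markov
approximation to true positive interference. Simulation defaults to Haldane
because nothing in the emulated study constrains the simulation side, while
the *estimation* side uses Kosambi throughout, matching the study's mapping
function.

`simulate_read_counts()` draws per-cell depth from a Poisson with class
means (parents 34.39×/31.31×, offspring 7.22×), samples heterozygous
templates 50/50, and flips each read to a uniformly chosen other nucleotide
with probability `error_rate` (default 0.001, the Q30 error rate via
Q = −10·log10 e). `build_pools()` forms the two bulks by summing read counts
over female and over male offspring — an in-silico pooling of reads; pooling
of genotype calls is also possible through the TSV entry points, since the
study text does not fully pin down which was done.

All stage seeds fan out from one master seed through `fan_seed()`, a small
deterministic string hash, so a fixed configuration reproduces every
artifact byte for byte.

## Genotyping (`genotyping`)

Tags are clustered into loci by single-linkage on pairwise identity
(matches/length) strictly above 0.95, replacing the original BLAT-based
clustering with an exactly specified routine for the fixed-length synthetic
tags. Groups are then filtered in a fixed order: *low* (either parental
depth < 10×), *repeat* (> 4 distinct tags — impossible for one diploid
locus), *ambiguous* (coefficient of variation of per-tag read counts > 1.0).
The study describes ambiguous tags only as having "a wide range" of read
counts; the CV cut is our operationalization — monotone in spread, simple,
and configurable. Kept groups are classified as non-polymorphic (one tag),
repetitive (> 2 tags in one parent), or polymorphic (2–4 tags), and
polymorphic loci are encoded into the eight standard two-allele segregation
patterns (paternal genotype first). Only aa×bb is fully informative in a
BC1 and only those markers proceed to mapping.

Offspring calls use read counts over the two parental alleles: depth < 4 is
missing; first-allele fraction ≥ 0.9 (or ≤ 0.1) is a homozygote; anything
between is heterozygous. These two thresholds are this package's own
pragmatic defaults — the study does not state its calling rule — and both
are exposed in the configuration. Calls of the donor homozygote, impossible
in a BC1, are set missing and counted per marker. The marker-level quality
filters then run in the published order: parental depth < 10×, integrity
(non-missing offspring fraction; parents excluded from the denominator)
< 60%, SNP count > 7, and 1:1 segregation distortion at P < 0.05 by a plain
1-df chi-square without continuity correction (the exact binomial is
available behind a flag; the printed threshold is taken as unadjusted for
multiplicity). At n = 148 the discrete chi-square's true null size is 5.8%,
not 5.0% — worth remembering when checking the filter's behaviour.

Reported percentages round half-up to two decimals, matching the printed
summary tables this package's report mirrors.

## Linkage map construction (`linkmap`)

Two-point statistics for every marker pair use the individuals scored at
both markers: recombination fraction `rf = R/n` capped at 0.5 and the BC1
LOD `n·log10(2) + R·log10(rf) + (n−R)·log10(1−rf)`. The original study's
HighMap "modified LOD" is not specified anywhere in its text, so grouping
uses this standard two-point LOD behind a single function boundary where an
alternative could be swapped in. Groups are single-linkage components of
the LOD ≥ 5 graph; markers with no qualifying edge are dropped and
reported — the package's model for how a handful of available markers can
fail to reach the final map.

Ordering minimizes SARF, the sum of adjacent recombination fractions:
greedy nearest-neighbour seriation start, simulated annealing (default
10,000 iterations, t0 = 1, geometric cooling 0.999, seeded) over
segment-reversal and relocation moves, then a deterministic descent to a
local optimum under 2-opt reversals and relocations of segments of length
1–3 in either orientation. The segment relocation matters: a pair of tightly
linked markers misplaced together is invisible to single-marker moves
because moving either one away from its partner costs what it gains.
Orders are canonically oriented (first marker id lexicographically before
the last) so outputs are byte-stable.

Error correction follows the classic iterative smoothing strategy: each
cell is predicted from up to `window = 5` flanking markers per side,
weighted 1/distance; a call disagreeing with a sufficiently confident
prediction is erased to missing — never overwritten — and the pass repeats
with a widening disagreement band (confidence thresholds 0.98, 0.96, 0.92,
0.84 over the default 4 passes). The widening schedule is essential: a
strict single pass only removes errors in unanimous neighbourhoods, while
miscalls sitting within a few markers of a genuine crossover — the dominant
survivors at 7× depth, where a heterozygote read pattern occasionally looks
homozygous — need the relaxed passes. Erasing instead of flipping keeps the
correction from amplifying its own mistakes; the k-nearest-neighbour
imputation (majority of the k = 5 nearest informative markers, ties to the
nearest) then fills the gaps. Ordering and correction iterate (up to three
rounds) until the order stabilizes, and map distances accumulate the
Kosambi function of adjacent recombination fractions estimated from the
corrected, imputed matrix.

The per-group summary reproduces the conventions of the published map
table: average adjacent distance is length/marker-count rounded half-up to
two decimals, the overall average is the mean of the per-group averages,
and totals sum markers, lengths and SNP counts.

## Bulked-segregant scan (`bsa_ed`)

At each mapped SNP the two pools' nucleotide frequency 4-vectors are
compared by Euclidean distance

$$ED = \sqrt{(A_F-A_M)^2 + (C_F-C_M)^2 + (G_F-G_M)^2 + (T_F-T_M)^2},$$

zero for identical pools and $\sqrt{2}$ at a fully differentiated biallelic
site. ED is raised to the 5th power (the study's garbled phrase about the
"ED 5 party" is read as the fifth power, consistent with its stated purpose
of suppressing background; the exponent is configurable), smoothed per
linkage group by LOESS (tricube weights, local linear, span 0.3 — the study
names local linear LOESS but no span), and thresholded genome-wide at
mean + 3 sample SD of all fitted values. Maximal runs of consecutive
above-threshold SNPs become regions; runs closer than 2 cM merge, and
merged runs with fewer than 3 above-threshold SNPs are dropped. The merge
gap and minimum marker count are this package's own post-processing to
avoid one-SNP regions, both configurable. The LOESS fit uses exact direct
evaluation (`surface = "direct"`), so every fitted value equals the
tricube-weighted least-squares fit at that point; with tied map positions
the local design can be singular and the fit falls back on a pseudoinverse,
which is the intended behaviour.

## What the tests show — and what they cannot

The test-suite study conditions are 6 linkage groups of the published
lengths with 100 equispaced markers each, 148 offspring, 7.22× offspring
depth and 0.1% base error, with the sex locus at LG4:80 cM; smaller
fixtures (single groups of 21–51 markers, toy matrices) exercise the
individual operations, and closed-form or brute-force oracles pin the ED
formula, the LOESS fit, the Kosambi/Haldane functions, the two-point LOD
and the small-instance ordering optimum. Under those conditions the
pipeline recovers the six groups exactly, orders them with Kendall |τ| above
0.95 against truth, reconstructs a single group's length within 15%, and
localizes the planted locus: the top region contains the true position and
the fitted-profile argmax lands within 5 cM.

One calibration property fails by design of the method, not of the code:
with pools formed by a random, trait-free split of the 148 siblings and the
default scan parameters, the scan virtually always calls at least one
region somewhere. Two effects combine. First, pooling full sibs makes the
pool frequency difference a smooth random function of map position
(neighbouring markers are inherited together, so the composition noise has
a correlation length of tens of cM). Second, the mean + 3 SD threshold is
computed from the same fitted ED⁵ field it is applied to, and the fifth
power makes that field so right-skewed that a few percent of points exceed
the threshold under any null, in runs wider than the minimum marker count
because of smoothing. The acceptance checks report this honestly (the
null-calibration test is red); practitioners should read single-study
region calls against this backdrop — a permutation threshold would be the
statistical fix, but is outside this package's scope, which is to reproduce
the published procedure.

The generator also idealizes real SLAF data in ways that matter for
extrapolation: marker spacing is even, depth is Poisson with no
locus-specific amplification bias, tags within a locus differ only at their
SNP sites, and missingness comes from depth alone. Passing tests therefore
demonstrate the correctness of the chain and its behaviour under the
modelled noise, not performance under PCR duplicates, allele-specific
bias, or segregation-distorted genomic regions.

## Problem sizes and runtime

Defaults were chosen so the whole simulated study runs in seconds: the
600-marker, 148-offspring pipeline completes in ~10 s on one core, and the
complete test suite in under a minute. The annealing schedule
(10,000 iterations) is sized for ~100-marker groups; larger groups warrant
proportionally more iterations via `n_anneal`.
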