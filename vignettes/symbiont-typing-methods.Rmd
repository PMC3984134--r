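---
title: "Methods: deep amplicon typing and quantification of symbiont communities"
author: "symtyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deep amplicon typing and quantification of symbiont communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Reef corals host communities of *Symbiodinium*-like dinoflagellate symbionts
in which one type usually dominates while others persist at background
abundances of a few percent or less. Gel-based genotyping (DGGE, SSCP)
cannot reliably see types below roughly 10% of the community, yet those
background types matter: shifts in their relative abundance ("shuffling")
are a mechanism of thermal acclimatization. Deep amplicon sequencing of the
ribosomal internal transcribed spacers (ITS-1/ITS-2) can in principle detect
and *quantify* types down to a fraction of a percent — but the ITS locus is
multicopy and intra-genomically variable, and pyrosequencing adds
substitution and homopolymer-indel errors, so raw read variants cannot be
equated with biological taxa.

`symtyper` implements the full analysis chain for calibrating such an assay
on mock communities of known composition: simulate (or read) barcoded
amplicon reads, filter them, build a reference library of read variants by
100%-identity clustering, annotate references to type, prune the library
using the known-dominant samples, quantify types as percentages of mapped
reads, estimate the detection limit from pure samples, validate
quantification with rank statistics, and analyse within-type haplotype
structure.

## The mock-community simulator

The simulator is a first-class, tested component: it defines the conditions
under which every downstream claim is checked.

**Ground truth.** A `type_genome` holds a type's intra-genomic rDNA variant
sequences, the fraction of rDNA copies carrying each variant, and the rDNA
copy number per cell. `build_type_panel()` generates four types carrying
familiar Symbiodinium type names (A13, D1, C1, C3) from a common 300 bp root: C1 and C3 are
separated by exactly one substitution at position 212 (C in C1, T in C3),
mimicking type pairs distinguishable only by a single diagnostic SNP; all
other pairs differ at 10% or more of positions, with the A13-like type most
divergent (20%). Each type carries four variants whose copy fractions
decline 0.4/0.3/0.2/0.1 — a dominant intra-genomic variant with progressively
rarer ones, the pattern typical of rDNA arrays. Variants differ by at most
two substitutions.

**Copy numbers.** ITS-1 copy number is known to be about 3-fold higher in
clade D than clade C (roughly 3,200 copies per cell), but per-type ITS-2
copy numbers are not established. The default panel therefore uses *equal*
copy numbers (1000 per cell), which makes expected read fractions equal cell
fractions and keeps the calibration interpretable; `copy_numbers =
c(1000, 3000, 1000, 1000)` reproduces the 3x clade-D scenario for studying
copy-number bias. `expected_read_fractions()` gives the prediction
f_t = c_t n_t / sum(c_u n_u).

**The dilution series.** `dilution_designs()` encodes the 15-sample mixing
design: each of the four types dominant at 99.7%, 97% and 85% against the
other three at 0.1%, 1% and 5%, plus pure samples of three types; combined
density 1e6 cells per sample. `make_dilution_series()` simulates the series
at 10,000 reads per sample by default — the coverage chosen so that a 0.1%
type is expected at ~10 reads.

**Error model.** Reads are drawn as a single multinomial over (type,
variant) templates weighted by cell fraction x copy number x copy fraction;
PCR cycle counts are carried as metadata only, since no per-cycle
amplification model is warranted by the calibration data. Each read then
receives: per-base substitutions at rate 0.001; a +/-1 length change in each
homopolymer run (length >= 2) of the insert at rate 0.002 per run — the
dominant pyrosequencing error class; and truncation to a normal read length
(mean 320, sd 40, floor 150). Together these give ~99.7% per-base accuracy,
matching the post-cleanup accuracy typical of the platform. Qualities are
synthesized (Phred 38 with a tail declining to 22) because the vendor's
quality model is unspecified; the quality filter is therefore exercised by
constructed fixtures, not by the simulator defaults. Barcodes are 8-mers at
pairwise Hamming distance >= 3, prepended with the forward primer; the
reverse-complemented reverse primer is appended so full-length reads carry
it.

**What the simulator does not emulate:** chimeras, per-cycle PCR duplication
and bias, flowgram-level noise, cross-sample contamination, and quality
degradation correlated with error. Consequently, passing tests demonstrate
the pipeline's behaviour under multinomial sampling with realistic per-read
errors — they do not bound the effect of PCR chimeras or contamination on
real libraries (a double-digit percentage of an absent type appearing in a
nominally pure sample is of that kind, and enters here only through the
outlier rule below).

## Preprocessing

Reads are demultiplexed on a unique best barcode match (<= 1 mismatch,
strictly better than the runner-up), the forward primer is required at the
5' end (<= 2 mismatches; reads without it are rejected), the reverse primer
is trimmed when found near the 3' end, and reads shorter than 150 bp are
discarded — the boundary is strict, a 150 bp read survives. Mean Phred >= 20
stands in for the vendor tool's unspecified default filter; it is a
configurable parameter, and only the length rule is treated as exact.
Accounting is conserved at every stage (raw = unassigned + no-primer +
filtered + clean), which the run report verifies.

## Clustering and reference selection

Reads are clustered at 100% identity with prefix containment, since
pyrosequencing reads vary in length. The containment relation is not an
equivalence (a short read can be a prefix of two longer reads that differ
only beyond its end — exactly what happens with truncated reads of a C1/C3
pair), so transitive merging would fuse distinct templates. Clustering is
therefore greedy: unique strings are processed longest-first and each joins
the cluster, among those whose representative it is a prefix of, with the
most abundant founding string. Genuinely ambiguous truncated reads are
resolved — by being discarded — at the mapping stage, where ambiguity is
explicit.

Reference selection follows the cluster-size histogram: size classes are
admitted from largest down while each class adds at least `asymptote_gain`
(1%) of total reads; when the curve shows no asymptote the fallback keeps
every cluster with >= 10 reads (`asymptote_gain = 0` forces the fallback).
The 10-read floor removes singletons and rare variants that are mostly
PCR/sequencing error. Selected references are finally screened for the
pyrosequencing indel signature: a reference differing from a >= 10x larger
reference only by the length of one homopolymer run is dropped.

## Mapping, annotation, pruning, consensus

Mapping is semi-global (5' anchored, free trailing gaps; +1/-1/-2 scoring,
implemented as a banded C++ dynamic program): a read is counted only when a
*unique* best-scoring reference exists with >= 90% identity; any score tie
makes it ambiguous and it is discarded from counting — maximum
discrimination, reproducing the discard-on-tie behaviour of repeat-score
threshold 0 mapping. Ambiguity concentrates, as expected, between the
near-identical C1/C3 pair and among within-type variants for truncated
reads.

References are annotated against a curated one-sequence-per-type panel by
percent identity. Hits within 0.5 percentage points of the best are treated
as tied; ties covered by a configured diagnostic site (C at panel position
212 means C1, T means C3) are resolved by the reference's base at that site,
remaining ties by alignment score, and the rest are flagged for manual
review rather than silently broken. The margin matters: with exact-equality
ties only, a reference carrying one sequencing error would never reach the
diagnostic rule.

Pruning uses the known composition: a sample with a type at >= 85% must
contain every genuine reference of that type, so a reference with zero reads
in any such sample is removed (with the triggering sample logged). Types
lacking a high-abundance sample keep their references, with a warning.

A per-type consensus is built by star alignment around the largest-cluster
reference with per-column majority (ties toward the anchor); indel columns
are decided by majority presence. The consensus is for reporting and
annotation only — mapping continues against the original references, because
editing the mapping targets toward a consensus would collapse the very
haplotype structure analysed below.

## Quantification and validation statistics

Counts are normalized to percent of each sample's mapped reads (controlling
for depth), and summed over a type's references for type-level percentages.

**Detection limit.** False-positive values are the observed percentages of
types designed absent from a sample. Outliers are removed by a leave-one-out
rule — the largest value is excluded while it exceeds the mean + 5 sd of the
*remaining* values — because a pooled-sd rule suffers masking: a single
gross contamination value (like a 15.6% type in a nominally pure sample)
inflates the pooled sd enough to hide itself. The cutoff is mean + 2 SE of
the retained values; with error-free input it is exactly 0.

**Gamma rank correlation.** Agreement between observed and expected
percentages is measured with the Goodman-Kruskal gamma over all pairs,
(Nc - Nd)/(Nc + Nd), with an optional robustness tolerance r under which
pairs differing by <= r in either variable count as ties (default r = 0, the
classical statistic; the robust variant is exposed because variable
low-abundance data motivate it). Significance is a one-sided permutation
test of positive association (1000 permutations, pseudocount 1 so p > 0).
One-sided is the appropriate alternative here — the calibration asks whether
observed tracks expected, not whether any association exists; a two-sided
option would halve nothing of substance and is trivially obtained by
doubling.

**Bootstrap and residuals.** Per-level 95% confidence intervals are
percentile bootstrap intervals of the mean (1000 resamples), and
over/under-estimation is summarized by the sign of residuals from the
observed ~ expected least-squares line at each expected level.

Validation compares against cell fractions by default; `expected_basis =
"reads"` switches to copy-number-weighted expectations to study the
quantification bias that unequal rDNA copy numbers produce.

## Haplotype analysis

Within a type, multiple references ("haplotypes") may be intra-genomic rDNA
variants of one genome. Such variants must co-vary: their percentages (of
the sample's mapped reads) rise and fall together with the genome's
abundance across samples. `infer_intragenomic()` computes gamma and its
permutation p for every haplotype pair and links pairs with gamma > 0 and
p < alpha (raw p-values by default, the usual convention for such screens; a
Bonferroni option exists); connected components are putative single-genome
variant groups. Note the normalization: within-type renormalized proportions
would be nearly constant by construction and carry no correlation signal,
which is why grouping operates on percent-of-sample values while
`haplotype_proportions()` reports the within-type shares used descriptively.

Haplotype networks use a mutation distance in which an entire contiguous
indel run counts as one mutation (indels treated like SNPs), computed from a
global affine-gap alignment. Identical haplotypes are collapsed (reads
summed) and the network is the union of all minimum spanning trees, so tied
alternative connections are retained. This replaces statistical-parsimony
network construction with a deterministic, testable equivalent; the two
agree on the descriptive use made of networks here. (The alternative
convention of treating gaps as a fifth character state would count each gap
column separately; the run-as-one rule is used throughout.)

## Numerical choices and degenerate inputs

- Alignment band half-width 12 around the diagonal: ample for the <= 2-3
  indels per read the error model produces; widen `band` for indel-rich
  data.
- Score ties are exact integer comparisons (linear scoring keeps scores
  integral), so tie detection is not at the mercy of floating-point noise.
- `gamma` is undefined (flagged, not NaN) when no pair is informative, e.g.
  a constant vector; the permutation test refuses to run on it.
- Samples with zero mapped reads get NA percentages and are flagged, never
  silently dropped.
- Empty reference selections return an explicit empty-set signal.
- Seeds: every stochastic operation takes an explicit seed; the dilution
  series derives per-sample seeds as `seed + sample index`; RNG state of the
  caller is always restored.

## Problem sizes

The package's own validation runs the 15-sample series at 10,000 reads per
sample (150,000 reads end to end) — the depth the calibration design calls
for — in a few minutes on one core. Unit and property tests run the same
operations at depths of a few hundred to a few thousand reads, which is
sufficient because the operations under test are depth-agnostic; the
law-of-large-numbers check uses 100,000 reads where convergence is the
claim.

## Known limitations

- False positives in this simulator arise only from sequencing error routed
  through clustering/mapping; cross-contamination, the dominant real-world
  source, must be assessed on real pure samples.
- The greedy containment clustering is order-deterministic but, like all
  greedy dereplication, not invariant to adversarial length/abundance
  patterns; the mapping stage's tie discard is the backstop.
- The diagnostic-site rule assumes the site is covered by the reference;
  references truncated short of it are flagged for manual review rather
  than guessed.
- Percent-identity annotation with a score tie-break replaces e-value
  ranking against a large public database; with a small curated panel,
  e-values add no discrimination beyond score.
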