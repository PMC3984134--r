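# symtyper

Detection and quantification of dominant and *background* symbiont types —
and the haplotypes within them — from deep amplicon sequencing of the
ribosomal ITS locus, as used to profile *Symbiodinium* communities in
reef-building corals.

Corals typically host one dominant symbiont type plus others at background
abundances (5% of cells down to 0.1% and below) that gel-based genotyping
cannot see. Quantifying them from amplicon reads is complicated by the ITS
locus being multicopy and intra-genomically variable, and by
pyrosequencing-style errors (substitutions and homopolymer indels).
`symtyper` implements the calibration workflow for such an assay on mock
communities of known composition, plus a simulator that generates those
mock communities with full ground truth.

## What it computes

Given barcoded amplicon reads, a barcode manifest, a curated type panel and
a mixture design, the pipeline:

1. demultiplexes, trims primers, and filters reads (length >= 150 bp, mean
   Phred >= 20);
2. clusters reads at 100% identity (with prefix containment for
   variable-length reads) and selects reference sequences from the
   cluster-size histogram — size classes are admitted while each adds >= 1%
   of total reads, falling back to all clusters with >= 10 reads when no
   asymptote appears;
3. maps reads semi-globally against the references with unique-best-hit
   semantics (+1/−1/−2 scoring, >= 90% identity); any score tie discards the
   read as ambiguous;
4. annotates references to type by percent identity against the panel, with
   near-ties resolved by a diagnostic SNP (C at position 212 ⇒ C1, T ⇒ C3);
5. prunes the reference library using known-dominant samples: a reference
   with zero reads in a sample where its type is >= 85% of cells is a false
   positive and is removed;
6. normalizes mapped counts to percent of each sample's mapped reads and
   aggregates to type level;
7. estimates the detection limit from designed-absent types as
   `cutoff = mean(FP) + 2·SE(FP)` (outliers removed by a leave-one-out
   rule);
8. validates quantification with the Goodman–Kruskal gamma rank correlation
   `γ = (Nc − Nd)/(Nc + Nd)` with a one-sided permutation test (1000
   iterations), percentile bootstrap CIs (1000 resamples), and residual
   over/under-estimation summaries;
9. groups within-type haplotypes into putative intra-genomic variant sets
   (pairs with γ > 0, p < 0.05 across samples) and builds minimum-spanning
   haplotype networks in which a contiguous indel run counts as a single
   mutation.

The simulator (`build_type_panel()`, `make_dilution_series()`) reproduces a
15-sample dilution series — four types each dominant at 99.7/97/85% against
the others at 0.1/1/5%, plus pure samples, 1e6 cells per sample — with
intra-genomic variants, per-type rDNA copy numbers, and a 454-style error
model, labelling every read with its template.

## Worked example

Simulate the dilution series at 2,000 reads per sample and run every stage:

```r
library(symtyper)
cfg <- pipeline_config(out_dir = "demo", seed = 7, simulate = list(depth = 2000))
report <- run_pipeline(cfg)
print(report)
#> <run_report> 15 samples, 30000 raw reads, 16 final references
#>    sample_id reads cleaned mapped ambiguous unmapped mapping_efficiency
#> 1  sample_01  2000    1998   1301       697        0               0.65
#> 2  sample_02  2000    2000   1807       193        0               0.90
#> 3  sample_03  2000    2000   1791       209        0               0.90
#> 4  sample_04  2000    1999   1973        26        0               0.99
#> ...
round(report$abundance$type_percent[1:4, ], 2)
#>             A13    C1    C3    D1
#> sample_01 99.77  0.08  0.08  0.08
#> sample_02  0.00  0.06  0.06 99.89
#> sample_03  0.06 99.72  0.06  0.17
#> sample_04  0.05  0.10 99.70  0.15
report$gamma_background$gamma   # observed vs expected, 0-5% background cells
#> [1] 1
report$detection_limit$cutoff   # percent; 0 when no false positives appear
#> [1] 0
```

Reading the output: the 16 final references are exactly the simulator's 16
intra-genomic variants; each sample's background types are recovered within
a few hundredths of a percent of their designed abundances (e.g. 0.08%
observed for types mixed at 0.1%); the sizeable ambiguous fractions are
reads that tie between near-identical references — mostly the C1/C3 pair,
which differ by a single SNP, and within-type variants on truncated reads —
and are discarded rather than guessed. Gamma = 1 over the background cells
says observed and expected percentages are perfectly rank-concordant.

Statistics are usable standalone:

```r
g <- gamma_permutation_p(c(0.1, 1, 5, 0.1, 1, 5),
                         c(0.09, 1.2, 4.6, 0.16, 0.9, 5.8),
                         n_iter = 1000, seed = 1)
print(g)
#> <gamma_result> gamma = 1.0000 (Nc = 12, Nd = 0), p = 0.00999
```

A command-line wrapper lives at `inst/scripts/symtyper.R`
(`Rscript symtyper.R simulate|run-all --seed <int> --out <dir> ...`).

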