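# nascentr

Two-condition analysis of nascent protein-coding and lncRNA
transcription, for epigenomics and regulatory-genomics work that asks
what happens to PROMPTs, eRNAs and lincRNAs — and to the chromatin and
replication landscape around them — when a transcription factor is
depleted.

## What it computes

Given paired-end libraries for two conditions (nascent transcription /
mNET-seq, chromatin and nucleoplasmic RNA-seq, IP + input chromatin
marks) plus a gene annotation and interval sets, the package
implements:

- **Nascent 3′-end signal**: one unit of signal at the 3′-terminal
  aligned base of read 2 of every properly paired, mapped pair, strand
  from read 1 — single-nucleotide Pol II positioning, with
  library-size-normalized bedGraph export.
- **Transcription-unit sets**: genes collapsed TSS→TES across
  transcripts; isolated expressed coding genes (2.5-kb exclusion zone,
  >2 kb, top 3 of 4 k-means expression groups); intronless non-histone
  coding genes; PROMPT–mRNA nearest-opposite-strand pairs; divergent
  mRNA–lincRNA pairs (TSS < 3 kb apart, ≥10 nascent reads in a
  condition).
- **Region quantification**: `value = count × (10⁸ / library) /
  length` over class-specific windows (PROMPT: TSS→+3 kb; eRNA: center
  ±2 kb; gene classes: TSS→TES); IP-minus-input for chromatin marks
  with the min/2 imputation contract; Spearman correlation of tracks
  over 10-kb bins; Wilcoxon rank-sum / signed-rank comparisons.
- **Chromatin Retention Index**: `CRI = log2(chromatin / nucleoplasm)`
  over the 5-kb PROMPT window — positive when a transcript stays on
  chromatin.
- **Metagene profiles** at 10-bp resolution, reference-point and
  mass-conserving scaled-region modes.
- **R-loop (RDIP-seq) peak annotation**: majority-vote strand
  assignment, summit-based exon/intron/upstream/downstream/distal
  partition, size-normalized category densities, and summit
  co-location with γH2AX peaks against a random-placement null.
- **Replication-origin collision analysis**: intergenic classification
  of 1-kb origin windows, two-condition Pol II quantification,
  ≥2-fold induction flags, 100-kb proximity to PROMPTs/eRNAs, and
  overlap with depletion-induced lncRNA readthrough extensions.
- **A synthetic-data generator** that plants all of the above — class
  rates, induction folds, elongation decay, retention ratios, IP
  enrichment, peak categories/strands, origin flags — with exact
  ground truth, so the whole chain is testable without any external
  data.

## Worked example

```r
library(nascentr)
run <- run_pipeline(sim_config(seed = 1),
                    depths = list(netseq = 3e5, rnaseq = 2e5, chip = 2e5))
print(run)
#> nascentr pipeline run (seed 1 )
#>   genes: 60 | PROMPT pairs: 20 | lincRNA pairs kept: 5
#>   median class log2 fold changes (depleted/control):
#>     coding       eRNA intronless    lincRNA     PROMPT      snRNA
#>     -0.177      1.718     -0.179      0.795      1.883     -0.229
#>   median CRI: 1.087
#>   RDIP category fractions:
#>       exon     intron   upstream downstream     distal
#>      0.472      0.320      0.000      0.000      0.208
#>   summit overlap: 0.88 (null mean 0.054 )
#>   origins: 100 | intergenic: 80 | Pol II positive: 80 | 2-fold induced: 40
```

Reading the output: the depleted condition induces the lncRNA classes
(PROMPT median log2 fold-change 1.883 against a planted 4×;
eRNA 1.718 against 4×; lincRNA 0.795 against 2×) while coding classes
sit near zero — slightly negative because library-size normalization
redistributes a global lncRNA gain. The median CRI of 1.087 reflects
the planted 2:1 chromatin retention of PROMPTs. Peak categories and
the 0.88 summit co-location (null 0.054) recover the planted layout,
and 40 origins pass the 2-fold Pol II induction threshold — the 40
planted ones. `run_pipeline(..., outdir = )` writes the quantification
tables, origin report, categorized peak BED and a JSON run log.

Individual stages are plain functions over `GRanges`/`SignalTrack`
objects — `extract_net_3prime()`, `select_nonoverlapping_coding()`,
`chromatin_retention_index()`, `categorize_peaks()`,
`flag_induced()`, … — see the help pages and the methods vignette
(`vignettes/nascentr-methods.Rmd`) for the models and conventions.

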