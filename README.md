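# ripTargets

Genome-wide microRNA target identification from paired RISC
immunoprecipitation (RIP) and gene-expression profiles.

Transfecting a miRNA and immunoprecipitating Argonaute-2 captures the
transcripts the miRNA loads into RISC; profiling expression in the
same cells captures which of them are degraded. `ripTargets`
implements the ratio-based analysis that combines the two read-outs
into a per-gene target call, together with the sequence-level
validation analyses a target set should pass: seed-match location
(5'UTR/CDS/3'UTR), seed frequency across ranked gene bins, and a
guide-tiling specificity scan. A synthetic study generator with
planted targets makes every stage verifiable by parameter recovery.

It is written for computational biologists analysing RIP-seq/RIP-ChIP
plus expression experiments (FPKM-like gene-by-sample abundance
tables), in Bioconductor style: `Biostrings` for sequences,
`SummarizedExperiment` for the profiling container.

## The scores

All abundances are floored at 1 FPKM before any ratio is formed.
With replicate-mean abundances per library class, each gene gets

- repression `R = expr_ctl / expr_trt` — above 1 when the miRNA
  transfection lowers the gene's expression;
- RIP enrichment `E = (rip_trt / expr_trt) / (rip_ctl / expr_ctl)` —
  the RISC-association ratio, normalized to expression, treatment
  over control; above 1 when RISC binding is miRNA-dependent;
- target score `S = (E + R) / 2`; genes with `S >= 1.5` form the
  target set.

A seed match is the DNA reverse complement of guide positions 2–8
(7mer-m8 by default; window start and length are configurable). For
the miR-191 guide `5'-CAACGGAAUCCCAAAAGCAGCUG-3'` the match k-mer is
`TTCCGTT`.

## Worked example

Simulate a study with 100 true targets (3-fold RIP enrichment, 2-fold
repression, 3'UTR-planted seed sites) among 2,000 genes, then run the
full analysis:

```r
library(ripTargets)

mir <- mir191()
seedDefinition(mir)
#> SeedDefinition: guide positions 2-8 (k = 7)
#>   guide window 5'-AACGGAA-3'
#>   match k-mer  5'-TTCCGTT-3' (DNA)

sim <- simulateStudy(simulationConfig(nGenes = 2000, nTargets = 100,
                                      rngSeed = 8))
scores <- scoreTargets(sim$experiment)
head(scores, 3)
#>     gene_id repression enrichment    score is_target
#> 1 gene00254   2.949107   5.488524 4.218815      TRUE
#> 2 gene01626   2.673620   5.246707 3.960163      TRUE
#> 3 gene01144   2.616493   5.192102 3.904298      TRUE

res <- runTargetProfile(sim$experiment, sim$models, mir)
res$bins$score[1:3, ]
#>   bin_index bin_size n_match relative_frequency partial
#> 1         1      250      99               7.92   FALSE
#> 2         2      250       1               0.08   FALSE
#> 3         3      250       0               0.00   FALSE
```

The top 250 genes by score carry the 7-mer seed match in their 3'UTR
7.9 times more often than the transcriptome background — the declining
bin profile expected when the ranking captures seed-driven targeting.
The tiling scan shows the same specificity along the guide: the 6-mer
window at guide positions 2–7 peaks at 3.8-fold relative frequency in
the called target set, while windows outside the seed stay near 1:

```r
subset(res$tiling, relative_frequency == max(relative_frequency))
#>   guide_start guide_window match_kmer target_fraction background_fraction
#> 2           2       AACGGA     TCCGTT       0.6666667              0.1775
#>   relative_frequency
#> 2           3.755869
```

`runTargetProfile(..., outDir = "out/")` writes every result table
(seed matches, target scores, region proportions, bin profiles,
region comparisons, tiling profile) as TSV plus a run log.
Experiments can equally be read from files: `readRipExperiment()`
for abundance + design TSVs, `readTranscriptModels()` for transcript
FASTA + CDS-coordinate TSV.

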