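---
title: "Profiling miRNA targets from RIP enrichment and expression repression"
author: "ripTargets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling miRNA targets from RIP enrichment and expression repression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

A transfected miRNA acts through RISC: the guide strand directs the
complex to transcripts carrying a seed match, RISC association goes
up, and expression of the bound transcripts goes down. The package
quantifies both arms from four library classes — expression and
Argonaute-2 RIP, each under miRNA treatment and a control
transfection, with replicates — on FPKM-like per-gene abundances.

Three per-gene quantities summarize the design:

* **Repression** `R = expr_ctl / expr_trt`. The control is the
  numerator, so a gene knocked down by the miRNA scores above 1.
* **RIP enrichment** `E = (rip_trt / expr_trt) / (rip_ctl /
  expr_ctl)`. RIP abundances are normalized to the matched expression
  abundances before the treatment/control ratio is taken, so a gene
  that is merely abundant — or merely repressed — does not masquerade
  as RISC-enriched; `E > 1` requires miRNA-dependent association.
* **Target score** `S = (E + R) / 2`, with the target set defined by
  `S >= 1.5` (inclusive; the boundary value is a target).

Replicates are combined by arithmetic mean per library class before
the ratios are formed. The abundance floor (below) is applied after
averaging, which preserves information from replicates above the
floor; flooring before averaging is available by pre-processing with
`floorAbundances()` if a user prefers that convention.

### The abundance floor

Every class-mean abundance below 1 (FPKM units) is raised to 1
before any ratio is formed. This bounds denominators away from zero
and pins the ratios of undetected genes at exactly 1, at the cost of
compressing genuine effects among barely-detected genes. The floor
is a parameter (`floor`, default 1), as are the score threshold
(`threshold`, default 1.5) and the replicate-combination rule.

## Seed matches

The seed is the guide window starting at position 2; a seed match is
its perfect DNA reverse complement in a transcript. The default is
the 7-mer over guide positions 2–8 (the 7mer-m8 site, pure
complementarity). The window start and length are parameters of
`seedDefinition()`, so the 6-mer (positions 2–7) and 8-mer variants
are one argument away; the package deliberately does not assume an
A1-anchor variant, which would add an assumption about target-site
architecture that pure complementarity does not need.

Conventions, all chosen for determinism and testability:

* Coordinates are 1-based and inclusive everywhere a user sees them.
* `U`/`T` and case are normalized on input; guides are held as RNA,
  transcripts as DNA. `N` never matches.
* Overlapping occurrences are all reported; gene-level "has a match
  in region X" means at least one record there.
* The CDS coordinates partition each transcript into 5'UTR, CDS and
  3'UTR (either UTR may be empty). A match is assigned to the region
  containing its **start** position; a match spanning a boundary
  keeps that region and carries a `spans_boundary` flag, rather than
  being split, dropped or double-counted.

## Validation analyses

`runTargetProfile()` chains the analyses a target set should pass.

**Ranked bins.** Genes ranked by enrichment, repression or score are
cut into consecutive bins of 250; each bin's fraction of genes with
a 3'UTR seed match is divided by the same fraction over all profiled
genes. Seed-driven rankings give a top-heavy, declining profile. The
final partial bin is kept and flagged (dropping it would break the
conservation property that bin fractions, weighted by bin size,
average to the overall fraction). Ties in the ranking value are
broken by gene id so output order is reproducible.

**Region proportions and comparisons.** Genes are flagged per region
and tabulated in two modes: inclusive (a gene counts in every region
where it has a site) and exclusive (only single-region genes count,
with `multiple` and `none` making the counts partition the
universe). Distribution comparisons between location groups (is a
CDS-site gene more repressed than a 3'UTR-site gene?) default to
exclusive groups, because a gene with sites in two regions cannot
attribute its repression to either; inclusive grouping is a flag.
Ratios are log2-transformed before ECDFs and t-tests — ratio effects
are multiplicative, and on the log scale "no effect" sits at 0 with
symmetric tails. An optional subset restricted to genes at least
1.5-fold enriched (or repressed) reproduces the stronger-signal
curves alongside the all-genes comparison.

**Guide tiling.** Every 6-mer window along the guide is reverse
complemented and looked up in 3'UTRs; the fraction of target-set
genes containing the window's k-mer is divided by the background
fraction. A genuine seed-driven target set peaks only at the windows
contained in the seed region (window starts 2 and 3 for a 7mer-m8
seed); uniform elevation would indicate a composition artifact
rather than pairing. Windows whose k-mer never occurs in the
background are reported as `NA`, not an error, since single windows
can be legitimately absent in small universes.

**Statistical kernel.** Group comparisons use Welch's
unequal-variance t-test, implemented from its closed forms with an
explicit degenerate path: when both groups have zero variance the
standard error vanishes, and the test reports `t = ±Inf` with p = 0
or 1 by direction (or `t = 0`, p = 1 for identical constant groups)
and a `degenerate` flag, so tiny constant groups behave
deterministically instead of erroring. One-sided alternatives are
named (`a_greater`/`b_greater`) rather than positional. Pearson and
Spearman correlations (average ranks for ties) serve the
enrichment-vs-repression concordance and cross-platform checks. A
paired t-test is included for completeness but is not wired into the
pipeline.

## The synthetic study generator

`simulateStudy()` exists so that every stage is checkable by
parameter recovery. It emulates the statistical structure of a
RIP + expression profiling study, not its raw reads:

* Transcripts are iid random DNA at a configurable GC content, with
  Poisson region lengths (defaults 200/1,200/800 nt for
  5'UTR/CDS/3'UTR — typical mammalian transcript proportions). All
  sequence is rejection-sampled to be free of the seed k-mer; each
  true target then receives exactly one planted site at a uniform
  position in the configured region (3'UTR by default). Non-targets
  are therefore seed-free, giving bin and tiling analyses a clean
  expected signal; `backgroundSiteRate` re-introduces chance sites
  for realism.
* Baseline abundances are log-normal (median 50, log-sd 1),
  left-truncated at `minBaseline = 2` by resampling. The truncation
  keeps simulated genes in the detected regime: below the floor a
  gene's ratios are pinned at 1 and carry no information, so
  including such genes would only dilute recovery without exercising
  any additional code path.
* Effects are multiplicative on expectations: true targets have
  expression/treatment divided by `repressionFold` and a
  RIP/treatment level chosen so the **normalized** RISC-association
  ratio rises by `enrichmentFold` — i.e. the raw RIP expectation is
  `baseline * enrichmentFold / repressionFold`, because the RIP
  library samples the already-repressed transcript pool. This makes
  the scorer recover the configured folds exactly in the noise-free
  limit, which is the property the generator exists to provide.
  RIP/control stays at baseline (no treatment-independent loading).
* Each replicate multiplies its class expectation by an independent
  log-normal factor `exp(N(0, sigma^2))`, sigma = 0.25 by default on
  the natural-log scale. Real FPKM noise is heavy-tailed and
  mean-dependent; a single multiplicative sigma is the simplest
  model that exercises the ratio pipeline.

What the generator does **not** emulate: read-level sampling and
length biases, between-gene correlation, partial repression
heterogeneity, 3'-supplementary or non-canonical sites, and
microarray-specific noise. Passing recovery tests therefore shows
the pipeline computes its definitions correctly under a plausible
noise model — not that the experimental design has any particular
power on real data.

A structural property worth knowing when interpreting recovery
rates: `E` and `R` share the two expression class means
(`E = R * rip_trt/rip_ctl` algebraically), so their sampling errors
are positively correlated and the null distribution of
`S = (E + R)/2` has a heavier right tail than independent ratios
would give. At sigma = 0.25 with three replicates this makes the
score threshold of 1.5 an appreciably leaky null filter even though
recall of strong planted effects stays near 1 — the package's
acceptance script computes both rates, and more replicates or a
smaller sigma tighten precision rapidly.

## Problem sizes and determinism

The validation study the tests and `scripts/acceptance.R` run is
10,000 genes with 500 planted targets, three replicates per class,
folds (3, 2) and sigma = 0.25 — large enough for stable bin and
tiling profiles while keeping a full run in tens of seconds. Unit
tests use a few hundred genes. All randomness flows from a single
integer seed (`rngSeed`; the abundance draw uses `rngSeed + 1` so a
transcriptome can be reused across noise settings), simulations are
byte-reproducible, and every writer serializes numbers with the
shortest representation that round-trips the double, so identical
inputs give byte-identical output files.

## Known limitations

* One platform at a time: RNA-seq-like and array-like tables are
  scored separately, not averaged into a joint score.
* No FPKM estimation, read alignment or differential-expression
  modeling; the pipeline starts from abundance tables and has no
  per-gene significance machinery (by design — the target call is a
  fold-change construct, not a test).
* Transcript space only: one model per gene, no isoforms, no genomic
  coordinates or strand handling.
* No pairing thermodynamics, conservation or site-context features;
  the seed model is exact complementarity.
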