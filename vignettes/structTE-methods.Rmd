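---
title: "Methods: translational efficiency, 5'UTR structure, and the synthetic study design"
author: "structTE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translational efficiency, 5'UTR structure, and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structTE)
```

## The analysis problem

Eukaryotic translation initiation is rate-limited by loading of the 43S
preinitiation complex onto the mRNA and by scanning through the 5'
untranslated region (5'UTR). Initiation factors that engage the 40S
subunit — such as the N-terminal domain (NTD) of eIF4B — are thought to
help the complex load onto, and scan through, structured 5'UTRs. A
factorial ribosome-profiling experiment probes this directly: two strains
(wild type and an NTD-deletion mutant) by two growth conditions (standard
dextrose medium, with or without a urea stressor), each profiled with
paired RNA-seq (mRNA abundance) and Ribo-seq (ribosome footprints) in two
independent cultures — 16 libraries in all.

structTE implements the downstream analysis of such a design:

1. **Translational efficiency (TE).** Per gene, TE is the ratio of
   normalized Ribo-seq to normalized RNA-seq signal — ribosome loading per
   transcript. Contrasts between strain-by-condition cells yield per-gene
   log2 fold-changes of RNA, footprints, and TE.
2. **Fold-change gene sets.** Genes with a 1.5-fold-or-greater change are
   classified into up/down sets per assay, and overlap between sets
   (e.g. the WT and mutant urea responses) is tested with Fisher's exact
   test.
3. **5'UTR structure.** Per-nucleotide structure scores (PARS-style:
   higher = more double-stranded) are summed over named windows of the
   5'UTR and early CDS, and compared between gene sets with t tests.
4. **Term enrichment** of fold-change sets against user-supplied GMT
   maps, with hypergeometric tests and Benjamini-Hochberg correction.
5. **Polysome profiles.** Bulk initiation activity from sucrose-gradient
   absorbance traces, as the polysome-to-monosome (P:M) area ratio, plus
   percent-of-total distributions of proteins across gradient fractions.

A negative-binomial simulator with planted, structure-coupled TE effects
ties the stages together and lets every claim be validated end-to-end
against known ground truth.

## TE contrasts

Counts are normalized by median-of-ratios size factors: for sample $j$,
$s_j = \mathrm{median}_{i \in G} \, (k_{ij} / g_i)$ where
$g_i$ is the geometric mean of gene $i$'s counts across samples and $G$
is the set of genes with $g_i > 0$ (zero counts are excluded from the
median; the median of an even number of ratios is taken in log space).
CPM normalization (columns scaled to $10^6$) is available as a fallback
for matrices in which no gene is expressed everywhere.

For a contrast between two strain-by-condition cells, per-gene log2
fold-changes are ratios of replicate-mean normalized counts,

$$\mathrm{lfc}_{\mathrm{TE}} = \mathrm{lfc}_{\mathrm{Ribo}} -
  \mathrm{lfc}_{\mathrm{RNA}},$$

an identity that holds exactly in the output by construction. A gene is
*measurable* for a contrast when its raw counts, summed across
replicates, reach `minCount` (default 10) in **each** of the four
assay-by-cell combinations; only measurable genes receive fold-changes.
This filter is deliberately explicit and configurable — published
analyses typically report "genes with measurable expression" without
stating the rule.

Two numerical choices matter here:

* **Pseudocounts.** The standalone TE estimate
  `computeTE()` uses $(\bar R + c)/(\bar M + c)$ with $c = 0.5$
  normalized counts, so genes with zero mRNA signal stay finite. Contrast
  fold-changes, by contrast, are pseudocount-free by default: measurable
  genes have strictly positive means in all four cells, and omitting the
  pseudocount keeps contrast log2FCs *exactly* invariant when a sample is
  rescaled (the per-sample factor introduced by normalization cancels in
  the ratio; an additive constant would break the cancellation).
* **Threshold boundary.** Fold-change sets use the inclusive rule
  (ratio $\ge \tau$, default $\tau = 1.5$; down: $\le 1/\tau$), compared
  on the log2 scale with a $10^{-9}$ relative guard so that a ratio that
  is mathematically exactly $\tau$ is classified "up" despite
  floating-point round-trip through `log2`.

## Structure-score windows

Transcript coordinates are signed and 1-based: $+1$ is the first CDS
nucleotide, $-1$ the last 5'UTR nucleotide, and position 0 does not
exist. The named windows are the whole 5'UTR (`total5utr`), the first 30
5'UTR nucleotides from the cap (`first30`), 30 nucleotides surrounding
the start codon (`start30`, taken as 15 on either side: $-15..-1$,
$+1..+15$), and five 30-nt CDS windows `plus15` ($+1..+30$) through
`plus75` ($+61..+90$), named after their midpoints. The per-5'UTR mean
(`mean_5utr_per_nt`) is `total5utr` divided by the 5'UTR length.

A window that does not fully fit in the available 5'UTR or covered CDS is
**missing**, never truncated or zero-filled: a truncated sum is not
comparable across genes, and group means count only genes whose window is
defined (the per-cell `n` is reported). Group comparisons use the
pooled-variance (Student) two-sided t test at $\alpha = 0.05$; the Welch
form is available behind a flag. Two degenerate paths are defined
explicitly: equal constant groups return $p = 1$ with a degeneracy flag,
while constant groups with different means (zero pooled variance, nonzero
difference) raise an error rather than fabricating an infinite statistic.

## Overlap and enrichment statistics

Set overlap uses Fisher's exact test on the 2x2 table over a gene
universe. The two-sided p sums all hypergeometric tables whose
probability does not exceed the observed table's (with the standard
$1 + 10^{-7}$ relative guard for ties); the one-sided upper-tail
(enrichment) p is reported alongside, since published legends rarely
state sidedness. Odds ratios apply the Haldane 0.5 correction only when a
cell is zero. The universe defaults to the contrast's measurable genes
and is configurable — the appropriate background is study-specific.

Term enrichment is the classic GO-style upper-tail hypergeometric test
per term, intersected with the universe first, with BH correction across
tested terms. Rank stratification (`rankSelect`) takes the top or bottom
`floor(fraction * n)` genes (default 30%) with ties broken by ascending
gene id, so selections are deterministic.

## Polysome quantification

P:M ratios integrate the baseline-subtracted A254 signal (trapezoidal
rule, negative values clipped at 0) over operator-chosen monosome and
polysome intervals — peak boundaries are configuration, not auto-detected,
mirroring how traces are quantified in practice. The ratio is invariant
to uniform vertical scaling and to a declared constant baseline; a
per-interval linear baseline is supported. Protein distributions across
gradient fractions are renormalized to percent of total (summing to 100
by construction), and early-vs-late comparisons pool percent mass at or
after a configurable split index before the t test — the split between
mRNP and ribosome-containing fractions depends on the gradient and is the
caller's choice.

## The synthetic study design

`simulationConfig()` defines the generator's defaults, which are the
study conditions for all package-level validation:

| parameter | default | rationale |
|---|---|---|
| genes | 4000 | order of a yeast transcriptome passing expression filters |
| replicates | 2 | two independent cultures per cell; 16 libraries |
| library size | 5e6 | desk-scale sequencing depth per library |
| NB dispersion | 0.05 | typical biological variability for yeast bulk counts |
| membrane-like fraction | 0.2 | minority secretome-like class |
| 5'UTR length | log-normal; log-mean log(90)/log(60), log-sd 0.6 | membrane-like 5'UTRs longer, both classes in the yeast range of tens of nt |
| structure scores | normal; 5'UTR means 0.3 / -0.2, CDS means 0.0 / 0.2, sd 1 | membrane-like 5'UTRs more structured; the other class slightly more structured in the CDS |
| CDS length | 300 nt (first 90 scored) | covers every CDS window through `plus75` while bounding file size |
| beta (structure to TE) | 0.4 | mutant log2-TE penalty per SD of cumulative 5'UTR score |
| WT urea boost | 1 log2 | membrane-like genes gain TE in WT under urea only |

Per gene, mRNA abundance is log-normal (log-sd 1.2) and a gene-level
baseline log2 TE is normal with sd 0.25 (biological TE heterogeneity;
internal, not a design knob). RNA counts are negative binomial
(variance $\mu + \mu^2 \phi$) around abundance-proportional means; Ribo
means multiply the RNA means by the cell's TE, where

$$\log_2 \mathrm{TE} = \beta_0^{(g)}
  - \beta_{\mathrm{struct}} \, z_g \,[\text{mutant}]
  + b \,[\text{membrane-like, WT, urea}],$$

with $z_g$ the standardized cumulative 5'UTR score. Each library's mean
vector is rescaled to sum to the library size — sequencing depth is fixed
by design, as in real libraries — and the per-library factor is absorbed
by normalization, so the planted log2-TE contrasts in the truth table are
preserved exactly.

This generator emulates the *design* of the experiment, not its full
biology: no shared stress regulon across strains (so cross-strain
response correlations are near zero unless effects overlap by
construction), no uORFs, alternative transcription starts, GC bias, or
read-level artifacts, and structure scores are Gaussian rather than
empirically distributed. Passing tests therefore demonstrate that the
statistics recover what was planted under a faithful count model — not
that any biological conclusion transfers to a particular organism.

## Validation strategy and problem sizes

The test suite checks each operation against an independent oracle:
brute-force per-position summation for every window on 1000 random
transcripts; exhaustive hypergeometric enumeration for every 2x2 table
with universe up to 60 (about 6.4e5 tables, exact to 1e-12); closed-form
pooled-t, hypergeometric, and odds-ratio values; the reference
median-of-ratios implementation; and analytic Gaussian areas for P:M.
End-to-end recovery runs the full pipeline on 20 simulated studies of
4000 genes with $\beta_{\mathrm{struct}} = 0.4$ (and 20 null studies with
$\beta = 0$), requiring the mutant TE-down set to show elevated 5'UTR
structure only when the effect is planted, and the planted membrane-like
term to rank first for the mutant urea TE-down set in 10 of 10 seeds.
Determinism is enforced byte-for-byte on rerun of the full report bundle.

## Known limitations

* Point-estimate fold-change classification, not a dispersion-aware
  differential test: genes near the threshold flip with sampling noise,
  which is why validation criteria are set-level, not gene-level.
* The pooled t test assumes roughly equal group variances; for strongly
  heteroskedastic score distributions, use the Welch flag.
* The measurable-gene universe is a pragmatic default; enrichment
  conclusions can be sensitive to the choice of background.
* Structure tracks cover the 5'UTR plus the first 90 CDS nt only; windows
  deeper in the ORF would require extending the track format.
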