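# structTE

Translational efficiency and 5'UTR structure analysis for paired
Ribo-seq/RNA-seq experiments.

## What problem this solves

Initiation factors that engage the small ribosomal subunit — such as the
N-terminal domain (NTD) of eIF4B — are thought to help preinitiation
complexes load onto, and scan through, structured mRNA 5'UTRs. A factorial
ribosome-profiling design probes this genome-wide: two strains (wild type
vs. an NTD-deletion mutant) by two conditions (with/without a urea
stressor), each measured with paired RNA-seq and Ribo-seq in two
independent cultures (16 libraries). structTE is for computational
biologists analysing such designs: it takes per-gene count matrices, a
sample sheet, per-nucleotide structure-score tracks (PARS-style), and
gene-set maps, and produces the complete downstream analysis.

At its core are four quantities:

* **Translation efficiency** per gene and cell,
  `TE = (mean normalized Ribo + c) / (mean normalized RNA + c)`, and
  per-contrast log2 fold-changes with the exact identity
  `log2FC_TE = log2FC_Ribo − log2FC_RNA`. Counts are normalized by
  median-of-ratios size factors
  `s_j = median_i (k_ij / geomean_i(k))` (CPM available).
* **Fold-change gene sets** at an inclusive threshold (ratio ≥ τ, default
  τ = 1.5; down sets at ≤ 1/τ), with Fisher's exact tests for set
  overlap (two-sided by minimum-likelihood summation, one-sided
  enrichment p alongside).
* **Cumulative structure scores** over named windows — the full 5'UTR,
  the first 30 nt from the cap, 30 nt surrounding the start codon, and
  CDS windows +1..+30 through +61..+90 — with windows that do not fully
  fit reported as missing, never truncated; group contrasts via Student's
  t test.
* **Polysome-to-monosome (P:M) ratios** from sucrose-gradient A254 traces
  by trapezoidal area over operator-chosen peak intervals, plus
  percent-of-total protein distributions across fractions.

A seeded negative-binomial simulator generates the full study design —
annotations, structure tracks, class labels, counts — with planted,
structure-coupled TE effects, so the whole pipeline validates end-to-end
against known truth. A YAML-driven `runPipeline()` writes a reproducible
TSV/JSON report bundle (byte-identical under the same config and seed).

## Worked example

```r
library(structTE)

cfg <- simulationConfig(nGenes = 1000, librarySize = 1e6, seed = 42)
sim <- simulateExperiment(cfg)        # transcripts, counts, truth, term map
norm <- normalizeCounts(sim$experiment)

ct <- teContrast(norm,
                 numerator   = list(strain = "ntd-del", condition = "urea"),
                 denominator = list(strain = "WT",      condition = "urea"),
                 label = "ntd_vs_wt_urea")
ct
#> ContrastResult 'ntd_vs_wt_urea'
#>   1000 genes, 1000 measurable
#>   median |log2FC_te| (measurable) = 0.497

sets <- classifySets(ct, tau = 1.5)
sets$te_down
#> GeneSet 'ntd_vs_wt_urea.te_down' (te/down): 249 genes
```

Do the mRNAs that lose TE in the mutant have more structured 5'UTRs?

```r
tot <- cumulativeScore(sim$transcripts, "total5utr")
inSet <- names(tot) %in% members(sets$te_down)
compareGroups(tot[inSet], tot[!inSet])
#> GroupComparison (student t test, two-sided)
#>   mean A = 22.34 (n = 249), mean B = -14.13 (n = 751)
#>   t = 30.8, p = 5.726e-147 *
```

The TE-down set averages a cumulative 5'UTR score of 22.3 versus −14.1
for the rest of the transcriptome — the planted structure dependence,
recovered from counts alone. The planted membrane-like class tops the
enrichment of the same set:

```r
head(enrichTerms(sets$te_down, sim$termMap, measurableGenes(ct)))
#>               term term_size overlap             p             q
#> 2    membrane-like       200     192 3.294128e-141 6.588256e-141
#> 1 cytoplasmic-like       800      57  1.000000e+00  1.000000e+00
```

Bulk initiation activity from an absorbance trace:

```r
x <- seq(0, 12, by = 0.002)
trace <- GradientTrace(x, dnorm(x, 3, 0.3) + 2 * dnorm(x, 7, 0.5))
pmRatio(trace, mono = c(1.5, 4.5), poly = c(5, 9))
#> PMResult: mono area = 1, poly area = 2, P:M = 2
```

The full pipeline runs from a YAML config (or list) and writes contrast
tables, gene sets, overlap and enrichment tables, window-score summaries
with t tests, and a manifest with checksums:

```r
runPipeline(list(simulation = list(n_genes = 4000), seed = 7),
            outdir = "report")
```

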