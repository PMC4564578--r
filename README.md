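# restmech

Differential expression and mechanistic target classification for
two-clone neural cell models of the transcriptional repressor REST.

## The problem

REST (RE-1 silencing transcription factor / NRSF) silences neuronal genes
in non-neural cells by binding RE-1 elements and recruiting
chromatin-modifying complexes, often in cooperation with Polycomb
repressive complexes (PRC). Rare clones of neural cell lines such as PC12
spontaneously express REST at 50–80-fold higher levels than the wild-type
population, so comparing a high-REST and a low-REST clone of the same
line exposes the repressor's transcriptional program directly. The
analytical question is two-fold: which genes respond to REST, and by
which mechanism — direct REST binding, REST together with PRC, PRC alone,
or unknown?

`restmech` is for computational biologists who want that analysis as a
tested, reproducible pipeline rather than a pile of one-off scripts, and
for methodologists who want its statistical components — an exact
negative-binomial test, an Enrichr-style enrichment with rank-deviation
z-scores, evidence-based mechanistic classification — individually
accessible and individually validated against enumeration oracles and
planted-truth simulations.

## The statistics at its core

* **Differential expression.** Counts are normalized with median-of-ratios
  size factors; dispersions are method-of-moments estimates shared through
  a fitted trend α(μ) = a₀ + a₁/μ (final dispersion = max of per-gene and
  trend). Each gene is tested with the conditional NB exact test: summing
  replicates per condition, p = Σ P(a,b) over all splits of the pooled
  total no more probable than the observed one. The DE cascade is
  baseMean ≥ 5 → BH over survivors → FDR ≤ 0.01 → |log2FC| > 2 (strict).
* **Enrichment.** Fisher one-sided hypergeometric p against a background
  universe of expressed, ortholog-mapped genes; per-term z-score
  z = (rank − E[rank])/sd(rank) from B random input lists (set-size bias
  correction); combined score c = ln(p)·z; significant iff
  adjusted p < 0.05 and z < −1.5.
* **Classification.** A gene is a REST/PRC/H3K4me1/H3K27me3 target iff it
  belongs to ≥ 1 significantly enriched term of that factor group; the two
  flag pairs induce four subfamilies per evidence source and a 4×4 flow
  matrix between ChIP-based and histone-mark-based labelings.
* **Group statistics.** Median log2 fold changes compared by two-sided
  Wilcoxon rank-sum tests (exact for small untied samples), including the
  activator-TF (Smad3/Myod1) target-shift analysis.
* **Synthetic data.** A generator plants all of the above — NB counts for
  2 conditions × 2 replicates, subfamily structure at configurable
  fractions, gene-set libraries with sensitivity/background noise, an
  ortholog map — so every stage can be checked against ground truth.

See `vignettes/rest-mechanism-analysis.Rmd` for the full model
description and design rationale.

## Worked example

```r
library(restmech)
cfg <- sim_config(n_genes = 2500, frac_down = 0.12, frac_up = 0.12,
                  seed = 7)
res <- run_pipeline(pipeline_config(sim = cfg), out_dir = "run1")
cat(summarize_run(res), sep = "\n")
```

```
Two-clone REST transcriptome analysis - run summary
===================================================
Genes: 2500 (24 filtered; universe of 2405 mapped symbols)
DE genes: 285 downregulated, 287 upregulated

Downregulated genes (285):
  REST targets: 31.2% (89/285); nontargets: 68.8% (196/285)
  ChIP subfamilies: REST_only 5.6%, REST_and_PRC 25.6%, PRC_only 32.6%, unknown 36.1%
  Histone-mark subfamilies: H3K4me1_only 5.6%, H3K4me1_and_H3K27me3 25.6%, H3K27me3_only 33.0%, unknown 35.8%
  Largest subfamily flow: REST_and_PRC -> H3K27me3_only (4 genes)

Upregulated genes (287):
  REST targets: 17.4% (50/287); nontargets: 82.6% (237/287)
  ChIP subfamilies: REST_only 10.5%, REST_and_PRC 7.0%, PRC_only 24.7%, unknown 57.8%
  Histone-mark subfamilies: H3K4me1_only 9.4%, H3K4me1_and_H3K27me3 7.7%, H3K27me3_only 25.1%, unknown 57.8%
  Largest subfamily flow: unknown -> H3K27me3_only (7 genes)

Group comparisons (median log2 fold change):
  rest_target_vs_nontarget: REST_target -3.72 (n=139) vs REST_nontarget 2.74 (n=433) (Wilcoxon p 5.04e-09)
  down_rest_prc_vs_others: REST_and_PRC -4.63 (n=73) vs other_subfamilies -3.76 (n=212) (Wilcoxon p 6.53e-11)
  tf_shift_SMAD3: target 4.75 (n=67) vs nontarget 3.87 (n=220) (Wilcoxon p 2.63e-10)
  tf_shift_MYOD1: target 4.91 (n=68) vs nontarget 3.90 (n=219) (Wilcoxon p 4.31e-11)
```

Reading the output: of 2500 simulated genes, 285 were called
downregulated in the high-REST condition and 287 upregulated. Among
downregulated genes, 31.2% are potential direct REST targets (member of
at least one significantly enriched REST ChIP term), and the four
mechanistic subfamilies recover the planted fractions (5.1 / 24.4 / 34.3
/ 36.2%) to within sampling error. Genes attributed to REST *and* PRC
together are repressed more strongly (median log2 fold −4.63) than the
other downregulated subfamilies (−3.76), and planted Smad3/Myod1 targets
are shifted upward relative to nontargets — both patterns significant by
Wilcoxon rank-sum test. `run1/` contains every table (DE, enrichment per
library, per-gene classification, flow matrices, comparisons), the
gene-pathway network in GraphML, a JSON manifest and this report.

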