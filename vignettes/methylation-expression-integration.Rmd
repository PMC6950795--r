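---
title: "Integrating DNA methylation with gene expression: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating DNA methylation with gene expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methexpr)
```

## The problem

In many cancers, promoter hypermethylation of a CpG site is read as a
silencing mark, and most integrated analyses look only for the canonical
anticorrelation between DNA methylation and gene expression. But when
methylation (Illumina beta-value arrays, cancer versus normal tissue) is
crossed with expression changes measured on the same disease, a substantial
group of genes gains methylation *and* gains expression. `methexpr`
implements the full analysis needed to find and characterise such genes:

1. **Per-probe differential methylation** within each cohort: a two-sample
   test of beta values between cancer and normal samples, with the
   *delta-beta* (difference of group mean beta values, cancer minus normal)
   as the effect size — the "methylation fold change" on the beta scale.
2. **Cross-cohort consensus**: a probe counts as hyper- or hypomethylated
   only when it is testable and significant in the same direction in every
   required cohort.
3. **Regulation-pattern groups**: each gene's methylation direction is
   crossed with its expression status (an externally supplied UP/DOWN/NS
   table) to give UPUP, UPDOWN, DOWNUP and DOWNDOWN groups. Genes with
   consensus probes in both directions join both compatible groups and are
   flagged *inconsistent*.
4. **"-only" refinement on a dense manifest**: on the denser 450k-style
   probe set, a UPUP (UPDOWN) gene is kept only if it has at least one
   significantly hypermethylated probe and *no* significantly hypomethylated
   probe, giving the unambiguous UPUP-only / UPDOWN-only groups.
5. **Methylation–expression correlation** on matched samples, binned into
   eleven named groups from "very strong negative" to "very strong
   positive".
6. **Genomic context**: signed strand-aware probe-to-TSS distances, window
   counts, a distance histogram split by fold-change magnitude, CpG-island /
   shore / shelf summaries, and gene-region overlap fractions (5'UTR, 3'UTR,
   exons, coding exons, introns, and their strand-aware "first" ordinals).

A seeded synthetic-data generator plants all of this structure, so the whole
pipeline is testable end to end without downloading any cohort.

## The statistical model

### Differential methylation

For probe $j$ in one cohort, with beta values $x_{j1},\dots,x_{jn_1}$
(cancer) and $y_{j1},\dots,y_{jn_2}$ (normal), the package computes

$$\Delta\beta_j = \bar x_j - \bar y_j, \qquad
  t_j = \frac{\bar x_j - \bar y_j}
             {\sqrt{s_{x_j}^2/n_1 + s_{y_j}^2/n_2}},$$

with Welch–Satterthwaite degrees of freedom (a pooled-variance $t$ is
available via `test_config(test = "pooled")`). The call is HYPER when
$p < \alpha$ and $\Delta\beta_j > 0$, HYPO when $p < \alpha$ and
$\Delta\beta_j < 0$, otherwise NS. Choices worth making explicit:

* **Welch instead of a moderated t.** The intended cohorts have dozens of
  samples per arm, where empirical-Bayes variance moderation changes
  essentially nothing; a plain Welch test is exact, transparent, and easy to
  oracle-check. Moderation in the style of microarray linear-model packages
  is deliberately out of scope.
* **Beta scale, not M-values.** Fold changes and their 0.2/0.5 thresholds
  are interpreted in beta units, so tests run on beta values directly.
* **Raw p by default.** The significance threshold $\alpha = 0.05$ applies
  to raw p-values; Benjamini–Hochberg adjustment is available behind
  `test_config(adjust = "BH")` and is then used for the calls.
* **Degenerate probes.** A probe with zero variance in both groups has an
  undefined $t$; it is called NS with $p = 1$ and logged. Probes with fewer
  than three non-missing values in either group are *untestable* — excluded
  from output and consensus rather than silently called NS.

### Consensus and groups

Consensus is deliberately conservative: a probe untestable in any required
cohort is NONE, even if significant everywhere it was measured, because
cross-cohort claims should be restricted to probes with data everywhere.
Consequently adding a required cohort can only shrink the consensus sets
(this monotonicity is property-tested). The gene-level average fold change
is the unweighted mean of delta-beta over all mapped, testable
(probe, cohort) pairs — *all* corresponding probes, not only significant
ones — so that a gene's reported effect is not inflated by selection.

Genes whose expression status is NS (or missing) receive no group
membership: the groups are defined by the cross of two observed directions,
and an absent expression direction leaves nothing to cross.

### Correlation bins

Pearson correlation between each probe's methylation profile and its gene's
expression profile is computed across all matched samples pooled (cancer and
normal together), since the pooled contrast is exactly what the regulation
patterns describe; a per-condition analysis can be built from the same
functions by subsetting columns. The eleven bins use boundaries 0.1, 0.2,
0.4, 0.5 on $|r|$, with $r = 0$ its own "no correlation" bin. The sources
describing these groups write open ranges ("0.2 to 0.4") without stating
edge membership; this package fixes the convention *half-open on the
magnitude with the boundary belonging to the weaker bin* ($|r| = 0.4$ is
intermediate, $|r| = 0.5$ is strong) and tests it exhaustively. Undefined
correlations (constant profiles, fewer than three complete pairs) carry
`defined = FALSE` and are excluded from bin percentages — a zero-variance
profile carries no signal, and binning it would just relabel noise.

### TSS distances and gene regions

Distances are signed and strand-aware: negative means upstream of the TSS in
the gene's transcription direction, and a probe exactly at the TSS has
$d = 0$, counted on the downstream side. Probes are counted in symmetric
windows $|d| \le w$ for $w \in \{50, 100, 200, 300, 400, 500, 1000, 1500,
2000\}$ bp. Two deliberate conventions for genes with several TSSs:

* *window counting* uses membership relative to **any** TSS (a probe near an
  alternative start is still promoter-proximal);
* the *distance histogram* uses the **nearest** TSS, ties broken to the
  upstream (negative) side, with half-open bins $[lo, hi)$ partitioning the
  line at $\pm\{0, 50, 100, 200, 300, 400, 500, 1000, 1500, 2000\}$ bp.

The histogram splits probes at $|\Delta\beta| \ge 0.2$ ("high" fold changes,
which in beta units range up to about 0.5) versus below 0.2.

Gene-region fractions use BED12-derived geometry, not the manifest's region
tags: manifest tags are carried through for reference but UCSC-style
transcript models are the authority for exon/intron/UTR intervals. Internal
coordinates are 1-based closed — the Bioconductor convention — with BED's
0-based half-open coordinates converted on import by `rtracklayer`; Illumina
manifest positions are natively 1-based and used as-is. When a gene has
several transcripts, each region type uses the union of intervals, while
"first exon/coding exon/intron" is satisfied by the strand-aware first such
region of *any* transcript. A probe may legitimately count in several region
types at once (a coding-exon probe is also an exon probe), so fractions are
reported against explicit denominators rather than forced to sum to one.

## The synthetic-data generator

`sim_config()` fixes the study conditions; `simulate_study()` realises them.
What it emulates:

* **Cohort structure**: by default three cohorts sized like the real series
  the pipeline is designed around — 95/86 and 73/63 cancer/normal plus a
  497/35 matched cohort — one on a sparse 27k-style manifest (2 probes per
  gene) nested inside a dense 450k-style one (16 probes per gene,
  approximating the observed average of ~16 dense associations per gene).
* **Baseline methylation**: a bimodal mixture of Beta(2,10) and Beta(10,2),
  mimicking the characteristic two-mode shape of array beta values.
  Baselines are kept inside [0.01, 0.99] so that a planted effect always
  moves the group mean even after clipping.
* **Planted effects on the logit scale**: the cancer group mean is the
  baseline shifted by the planted delta-beta (clipped to [0.001, 0.999]),
  and per-sample noise is Gaussian on the logit scale, which preserves the
  unit interval by construction. With the default logit noise sd of 0.4 the
  per-probe test has essentially full power at the default arm sizes, and
  planted-null probes reject at the nominal 5% rate (this calibration is
  itself a test).
* **Group structure**: gene labels are drawn from configurable fractions
  (defaults 0.15/0.30/0.05/0.10/0.40 for UPUP/UPDOWN/DOWNUP/DOWNDOWN/NULL,
  echoing the observed predominance of the canonical UPDOWN pattern over
  UPUP and the smaller hypomethylated groups). A `frac_inconsistent` share
  of non-NULL genes (default 2%, matching the observed "<2% of multi-probe
  genes mix directions") receives exactly one opposite-direction probe,
  planted among the dense-only probes when the dense manifest is larger —
  mirroring how ambiguity surfaces only on the dense expansion and making
  the "-only" filter's behaviour directly testable.
* **Matched expression**: per gene, expression = baseline + sign × slope ×
  (mean probe methylation per sample) + Gaussian noise on a continuous
  log2-like scale, sign +1 for UPUP/DOWNDOWN, −1 for UPDOWN/DOWNUP, 0 for
  NULL. The slope is calibrated against the empirical spread of the gene's
  mean methylation so the population |Pearson r| approximates
  `expr_coupling`. No count model is used: the pipeline consumes processed
  expression, not raw counts.
* **Determinism**: every stage draws from an RNG stream derived from the
  master seed and a stage/cohort label, so outputs are byte-identical under
  a fixed seed and cohorts are stable under reordering.

What it does **not** emulate — and hence what passing tests cannot show
about real data: probe cross-reactivity and SNP-under-probe artifacts,
tissue-composition (stroma) confounding, array normalisation effects,
spatially correlated methylation along the genome, and realistic
heteroscedasticity across probes. The variance structure of real cohorts is
unknown; the logit-normal noise model is a configurable stand-in, which is
why every noise parameter is exposed in `sim_config()` rather than frozen.

## Problem sizes and numerical choices

The test-suite and acceptance analyses run at deliberately modest sizes
chosen to exercise every code path with comfortable statistical margins:
calibration uses 2000 planted-null probes at 50/50 samples; recovery uses
500 genes across three cohorts of 40+40; the correlation-direction analysis
uses 100 replicates of a 40-gene, 150-sample study. Recovery margins are
wide because power at the planted effect (delta-beta 0.2 against logit noise
0.25) is essentially 1 per probe and cohort.

Other numerical conventions: ties in gene ranking are broken
lexicographically by symbol; TSS-distance ties go upstream; bin and window
edges are documented half-open/closed as above; TSV writers emit doubles
with 17 significant digits so written tables round-trip exactly.

## Known limitations

* Region-level (DMR) calling is out of scope; the unit of analysis is the
  single probe.
* The expression status table is consumed as given; deriving it (e.g. by
  meta-analysis) is not reimplemented.
* "-only" refinement is defined for the hypermethylated groups (UPUP,
  UPDOWN); the hypomethylated mirror is available through the `directions`
  argument but is not part of the standard outputs.
* Gene identity is the symbol string, matching how probes are annotated in
  platform manifests; no identifier mapping is attempted.

## A worked run

```{r run, eval = FALSE}
cfg <- sim_config(seed = 1, n_genes = 200,
                  cohorts = data.frame(name = c("a", "b", "c"),
                                       n_cancer = c(40, 40, 60),
                                       n_normal = c(40, 40, 30),
                                       platform = c("sparse", "dense", "dense")))
res <- run_pipeline(cfg, outdir = "run1")
print(res)
res$ranked$UPUP          # most significantly hypermethylated UPUP-only genes
res$correlation$UPDOWN$summary   # the 11-bin correlation table
```
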