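# mempar

Integrative analysis of memory T-cell transcriptomes and chromatin
accessibility: differential testing, expression-module discovery,
rule-based classification of *patterned accessibility regions* (PARs) and
of memory-specific expression classes, peak-to-gene integration, motif
enrichment, transcription-factor PageRank, and metabolic assay metrics —
exercised end-to-end on synthetic data with planted ground truth.

## The scientific problem

Human memory T cells (T_CM, T_EM, and CD8-only T_EMRA) respond faster and
harder to restimulation than naive T cells. Part of that recall advantage
is chromatin-encoded: regulatory regions opened during a first activation
can stay accessible in resting memory cells — *primed* chromatin — so that
on restimulation the associated genes are induced to higher levels than
naive cells can reach (*augmented* expression). `mempar` implements the
computational machinery to detect and quantify that coupling from paired
RNA-seq and ATAC-seq of sorted subsets, before and after stimulation,
across donors.

The core pieces, in the field's standard notation:

* **Differential testing.** Counts are modeled as negative binomial,
  `K_ij ~ NB(mu_ij, alpha_i)` with `Var = mu + alpha mu^2` and
  `mu_ij = s_j q_ij`, where `s_j` are median-of-ratios size factors. A
  group-saturated NB GLM with log link and offsets `log s_j` is fit per
  feature; the Wald statistic `log2FC / se(log2FC)` is referred to a
  standard normal and Benjamini–Hochberg adjusted. Calls use
  `|log2FC| >= 1` and FDR <= 0.05 for genes (DEG) and `|log2FC| > 1.5`,
  FDR <= 0.05 for peaks (DAR).
* **PAR classification.** For each memory subset M, four contrasts are
  computed: C1 naive stim vs naive rest, C2 M rest vs naive rest, C3 M stim
  vs naive stim, C4 M stim vs M rest. A first-match decision table maps the
  call pattern to one of {conserved, stimulated, **primed** (C1 up and C2
  up), memory, naive, unclassified}.
* **Expression classes.** The analogous gene contrasts (R, S, I_M, I_N)
  feed a second table: **augmented** (R up, S up), **induced** (R ns, S up,
  I_M up), **expressed** (R up, S ns), else none.
* **Modules.** DEG passing an expression floor (>= 3 RPKM in all samples of
  some group) are clustered on z-scored group means by fuzzy c-means, with
  the fuzzifier `m` estimated from (N, D) and `c` chosen by the
  within-SSE elbow; tri-wise barycentric projection is provided for
  three-subset comparisons.
* **Integration.** Peaks are assigned to the nearest TSS; the package
  reports, e.g., the fraction of augmented genes with at least one primed
  peak in cis, PAR-type composition near each gene class vs the all-DEG
  background, and expression/accessibility fold-change correlations.
* **Motifs and TF importance.** PWM log-odds scanning, hypergeometric
  enrichment per PAR set with rank normalization and per-motif z-scaling
  across sets, bootstrap-supported dendrograms of peak sets, and
  personalized PageRank on a motif-derived TF→gene network (run in reverse
  so expression mass flows from targets to regulators), compared between
  memory and naive networks as `log2(score_M / score_naive)`.
* **Metabolism.** SCENITH dependence/capacity percentages from puromycin
  MFIs (`mito = 100 (ctrl − O)/(ctrl − DGO)`, etc.) and Seahorse
  glycolysis stress-test metrics from ECAR traces.

Because the original donor sequencing data are not redistributable, the
package ships a first-class synthetic-data generator
(`simulate_experiment()`) that reproduces the study design — 2 lineages ×
subsets × (rest, stim) × 4 donors, NB counts, planted effect gradients,
five expression modules, five PAR categories, primed↔augmented coupling at
a configurable rate, and PAR-specific motif placement — together with
ground-truth tables, so every stage is testable against planted truth.

## Worked example

```r
library(mempar)
library(dplyr)

res <- run_pipeline(pipeline_config(sim = sim_config(seed = 1)), quiet = TRUE)

filter(res$par_counts, lineage == "CD8", subset == "TCM")
#>   lineage subset par              n
#> 1 CD8     TCM    conserved     1117
#> 2 CD8     TCM    stimulated     168
#> 3 CD8     TCM    primed         338
#> 4 CD8     TCM    memory         132
#> 5 CD8     TCM    naive          149
#> 6 CD8     TCM    unclassified    96

res$coupling
#>   n_genes n_with_par fraction
#> 1     200        165    0.825

head(arrange(res$pagerank$changes, desc(log2_change)), 4)
#>   node  log2_change
#> 1 AP1         0.459
#> 2 NFYA        0.409
#> 3 BATF        0.381
#> 4 IRF4        0.293

res$modules$selection$c
#> [1] 5
```

Reading the output: of the 2,000 simulated CD8 peaks, the TCM contrasts
classify 338 as primed against 400 planted across categories weighted
toward primed; 82.5% of the genes called augmented have at least one
primed peak at their nearest TSS (the generator plants coupling at 80%);
the AP1/BATF/IRF4 activation motifs — planted into primed and stimulated
peaks — gain PageRank importance in the resting memory network relative to
naive; and the within-SSE elbow recovers the five planted expression
modules. `write_pipeline(res, "out/")` exports every table as TSV plus a
run manifest with configuration and result hashes.

Plot helpers (`plot_volcano()`, `plot_par_counts()`, `plot_triwise()`,
`plot_scenith()`, `autoplot()` on a fuzzy c-means fit) return ggplot
objects; `tidy()`/`glance()` methods cover the fitted objects. A thin CLI
wrapper lives at `inst/scripts/run_pipeline.R`.

## Vignette

`vignettes/mempar-methods.Rmd` documents the statistical model, every
tunable threshold with its default and rationale, what the generator does
and does not emulate, and the package's numerical conventions and known
limitations.
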