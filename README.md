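# epicart

Expression cartography of multi-class cohorts with self-organizing maps.

`epicart` reimplements, as a tested and reusable R pipeline, a portrait-based
analysis of gene expression heterogeneity in tumour cohorts — the kind of
analysis used to chart the transcriptional landscape of lymphoma subtypes and
to ask where functional gene groups such as the writers, erasers and readers
of histone and DNA methylation marks sit in that landscape. It is aimed at
computational biologists who want the individual building blocks (SOM
portraits, spot detection, enrichment, shrinkage t, wTO networks, pathway
signal flow) as composable functions, validated against synthetic cohorts
with planted structure.

## What it computes

Expression is handled throughout on the **log10 scale**, so a difference of 1
between two expression values is a ten-fold linear change. Gene profiles are
centred (`e'_gs = e_gs − mean_s(e_gs)`) so the map portrays differential
expression relative to the cohort mean.

* **SOM metagene portraits** — classic online Kohonen training of an
  `n × n` lattice of metagenes on the centred gene profiles. Each gene maps
  to its best-matching unit (Euclidean argmin); each sample's portrait is
  the metagene values arranged on the grid.
* **Overexpression spots** — per portrait, units at or above the q = 0.98
  expression quantile are marked; recurrent marked units form 8-connected
  components ("spots" A, B, C, …), the map's co-expression modules.
* **Map segmentation** — four corner quadrants Q1–Q4 and a central zone Z
  of near-invariant genes, with per-region counts of any annotated gene
  group and one-sided Fisher exact enrichment from the hypergeometric tail.
* **Shrinkage t-test** — per gene or per spot, `t = d / (s + s0)` with
  `d` the class-mean log10 difference, `s` the pooled-variance standard
  error and `s0` a cohort-wide additive fudge (median of the gene-wise
  standard errors by default); Student p-values and Benjamini–Hochberg FDR.
* **wTO spot network** — signed weighted topological overlap of the spot
  mean profiles,
  `w_ij = (Σ_k a_ik a_kj + a_ij) / (min(k_i, k_j) + 1 − |a_ij|)` with
  `k_i = Σ_{k≠i} |a_ik|`, thresholded at `|w| > 0.3` into positive and
  negative edges.
* **Pathway Signal Flow (PSF)** — a cyclic metabolic pathway (a toy TCA
  cycle ships in `inst/extdata/tca_toy.tsv`) is linearized by splitting one
  node (classically oxaloacetate) into an input and an output copy;
  expression-derived node weights (`10^Δlog10`, compounds pass through with
  weight 1) then propagate in topological order — activation multiplies by
  the upstream signal, inhibition by its reciprocal, joins aggregate by
  arithmetic mean — and signals are reported in log10.
* **Synthetic cohorts** — `generate_cohort()` plants disjoint co-expression
  modules, overexpressed in designated sample classes, on a log10 baseline
  with Gaussian noise, providing ground truth for every stage.

## Worked example

```r
library(epicart)

design <- default_cohort_design(seed = 7)   # 5 classes x 12 samples, 2000 genes,
cohort <- generate_cohort(design)           # 4 modules of 50 genes, effect 1.0
x      <- center_genes(cohort$expr)
som    <- train_som(x, n_rows = 20, n_cols = 20, seed = 7)

ov    <- overexpression_summary_map(all_portraits(som), q = 0.98)
spots <- detect_spots(ov$binary & (ov$summary >= 0.1), ov$summary, min_size = 4)
spots
#> spot_map: 4 spot(s) on a 20 x 20 grid
#>   label size peak
#> 1     A    8  0.2
#> 2     B    8  0.2
#> 3     C    8  0.2
#> 4     D    8  0.2
```

Four spots, one per planted module; each spot's `peak` of 0.2 says its units
were overexpressed in 12 of the 60 samples — exactly one class.
`spot_classes()` confirms the assignment (A → BL, B → IntL, C → DLBCL,
D → FL), and the spot-level shrinkage t for the BL-vs-MM contrast singles
out spot A:

```r
spot_t(x, cohort$classes, spots, som$gene_to_unit, "BL", "MM")
#>   gene        d       t        p      fdr
#> 1    A  1.01755 28.5037 7.28e-19 2.91e-18
#> 2    B -0.01302 -0.3595 7.23e-01 9.23e-01
#> 3    C -0.00384 -0.0975 9.23e-01 9.23e-01
#> 4    D  0.00360  0.1009 9.21e-01 9.23e-01
```

Spot A carries a mean log10 difference of about 1 — the planted ten-fold
effect. The planted module genes enrich perfectly in the detected spots
(all 200 fall inside them):

```r
fisher_enrichment(200, 200, 200, 2000)
#> Fisher exact enrichment (one-sided greater): p = 1.457e-281, OR = Inf
```

Signal propagation through an eight-enzyme toy cycle in which every enzyme
is two-fold up in the target class:

```r
toy <- generate_toy_pathway(8, weights = rep(2, 8))
psf(toy$graph, toy$expr, toy$classes, reference = "reference", target = "target")
#>                 node   kind   role weight signal log10_signal
#> 16  Oxaloacetate__in  input  input      1      1        0.000
#> 17 Oxaloacetate__out output output      1    256        2.408
```

The output signal is the product of the eight enzyme weights
(2^8 = 256, i.e. 8·log10 2 ≈ 2.41 in log10), illustrating how activity
entering an unbranched cycle passes through it end to end.

`run_pipeline(default_pipeline_config(seed = 7))` chains all stages and
writes every table plus `report.json` and `provenance.yaml`.

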