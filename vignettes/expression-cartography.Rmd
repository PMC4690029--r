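---
title: "Methods: expression cartography, spot statistics and pathway signal flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression cartography, spot statistics and pathway signal flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and procedures implemented in `epicart`,
the assumptions behind them, the tunable parameters and their defaults, and
the design choices made where several reasonable options existed. It states
no empirical result beyond what the package's tests and the acceptance
script themselves compute.

## Data model

The pipeline's universal input is a gene × sample matrix of **log10
expression** with a sample→class assignment. The log10 convention matters
everywhere downstream: a difference of 1 between two values is a ten-fold
linear change, differential effects are additive, and Pathway Signal Flow
converts log differences back to linear fold changes with `10^Δ`. Input on
a linear scale can be brought over with `to_log10()` (pseudocount of one
linear unit).

`center_genes()` subtracts each gene's mean across **all** samples. The
resulting map is a differential-expression portrait: a unit value of 0
means "at the cohort mean for these genes", positive values mean
overexpression relative to it. Centring across all samples (rather than
within classes) is deliberate — class-wise centring would erase exactly
the between-class structure the map is meant to show. Centring is
idempotent and preserves all within-gene differences, which the test suite
asserts.

## Self-organizing map portraits

`train_som()` implements classic online Kohonen training:

1. Metagenes (one prototype profile per map unit) are initialized from a
   seeded uniform sample of gene profiles. PCA-plane initialization is a
   known alternative; random profile sampling was chosen for simplicity
   and exact reproducibility from one integer seed.
2. In each of `epochs` passes (default 20) every gene profile is presented
   once, in an order reshuffled per epoch from the seeded stream. The
   best-matching unit (BMU) is the Euclidean argmin over metagenes, ties
   broken to the lowest row-major index.
3. All units move toward the presented profile under a Gaussian kernel
   around the BMU. Learning rate and kernel radius decay exponentially per
   presentation, from 0.5 to 0.01 and from `max(n_rows, n_cols)/2` to 0.5
   grid units respectively — standard Kohonen practice.

The default grid is 20 × 20 = 400 units, a desk-scale choice suited to
cohorts of a few thousand genes (roughly 5 genes per unit for the default
synthetic design); it is configurable and larger maps are advisable for
genome-wide cohorts. Units are indexed row-major, 1-based, unit 1 at the
top-left corner; every module of the package shares this convention.

After training, each gene is assigned to its BMU under the final
metagenes, so the assignment is a fixed point of the final map (tested).
A sample's **portrait** arranges its metagene values on the grid; class
portraits are means over the class's samples, and
`mean_total_expression()` summarizes a portrait by its plain unit average.

The inner training loop is compiled (Rcpp) with the randomness kept on the
R side, so two runs with the same data, parameters and seed agree
bit-wise.

## Overexpression spots

Per portrait, `overexpression_summary_map()` marks units at or above the
portrait's `q` quantile (default q = 0.98, the convention of the
portraying method's ecosystem). The quantile is the **type-1 (inverse CDF)
empirical quantile and ties at the cut are included** — stated explicitly
because marked-unit counts depend on it: a constant portrait marks all
units.

`detect_spots()` takes a binary map and labels its 8-connected components
of at least `min_size` units (default 4, which suppresses single-unit
noise spots on a 20 × 20 grid) as spots 'A', 'B', … in order of
decreasing peak summary value. The pipeline feeds it the units marked in
at least a fraction `min_portrait_fraction` (default 0.1) of portraits:
a spot is a *recurrent* overexpression pattern, and without this floor a
single sample's noise marks can bridge two distinct modules into one
component. On real maps spot borders are fuzzy; the crisp components here
are an operationalization, and both thresholds are exposed.

A spot is associated with the classes whose class-portrait mean over the
spot's units is positive and within 90% of the maximal class mean
(`spot_classes()`).

## Segmentation, region counts and enrichment

`segment_map()` partitions the grid into a central zone Z — the centred
rectangle with side `ceiling(central_fraction · dim)` per dimension
(default fraction 1/3) — and four corner quadrants. The orientation
(Q1 top-left, Q2 top-right, Q3 bottom-right, Q4 bottom-left) is a declared
convention recorded in the pipeline's provenance output; quadrant letters
on a SOM are arbitrary under rotation. Genes in low-variance units
(`invariant_units()`, metagene population variance at or below the 0.25
quantile by default) can be diverted to an extra "Inv" region, separating
the near-invariant genes from the quadrants proper.

`fisher_enrichment()` tests over-representation of an annotated gene group
inside a region with the one-sided (greater) Fisher exact test, i.e. the
upper hypergeometric tail. One-sided because enrichment is a directional
claim; the full 2 × 2 table and the sample odds ratio are returned for
reporting. The packaged annotation fixture `table1_modifiers.tsv` lists
histone-lysine and DNA-CpG methylation writers, erasers and readers
(symbol, mark, role, expected transcriptional effect); enzymes acting on
several marks appear once per mark.

## Shrinkage t-test

For a contrast of classes A and B, per gene:

* `d = mean_A − mean_B` (log10 units),
* `s` = pooled-variance standard error of `d`
  (`df = n_A + n_B − 2`),
* `t = d / (s + s0)`.

The fudge `s0` is one constant for all genes in a call — the SAM-style
additive shrinkage that keeps genes with accidentally tiny variance from
dominating the ranking. The default rule is the median of the gene-wise
standard errors; a 90%-quantile rule and a direct numeric value are
offered. With `s0 = 0` the statistic reduces exactly to the ordinary
pooled two-sample t-test, which is both a test oracle and the setting in
which the null calibration check (type-I error at α = 0.05 on 10⁴
simulated null genes) is run. Shrinkage makes p-values conservative; they
are computed from Student's t with pooled degrees of freedom and reported
next to a Benjamini–Hochberg FDR column. Welch-type unequal variances and
permutation p-values are out of scope.

The additive-fudge form is a documented stand-in for the shrinkage
estimator family; the exact variant used by any particular upstream
software is not claimed, and the rule in force is written into the
pipeline's provenance output.

Spot-level tests (`spot_t()`) apply the same statistic to each spot's
mean-gene profile. `overlay_maps()` projects gene results onto the grid:
per unit the mean `d`, and a combined significance via Fisher's method
(−2 Σ ln p against χ² with 2k df), reported as −log10 p; aggregation by
Fisher's method is a declared choice, made because a per-unit summary of
several gene-level p-values is needed and the method is exact under
independence.

## wTO spot networks

Spot profiles (mean member-gene expression per sample) are correlated with
Pearson's r across all samples to give a signed adjacency `a` (no
soft-power transform; `β = 1` keeps the simplest reading of a correlation
network at spot level). The **signed** weighted topological overlap

\[ w_{ij} = \frac{\sum_k a_{ik} a_{kj} + a_{ij}}{\min(k_i, k_j) + 1 - |a_{ij}|},
   \qquad k_i = \sum_{k \ne i} |a_{ik}| \]

keeps signs in the numerator (two spots anti-correlated with each other,
both correlated with the same neighbours, get negative overlap) while node
strengths use magnitudes. `w_ii = 1` by convention. Edges require
`|w| > τ` with τ = 0.3 by default, split into positive and negative sets.
The formula is oracle-tested against an independent triple loop; it is a
declared signed variant, chosen because a magnitude-only overlap cannot
distinguish the positive and negative module couplings the analysis needs.

Note one subtlety the tests encode: negating the *adjacency* does not
negate `w` (the shared-neighbour term is even in `a`), so the positive and
negative edge sets swap under negation of `w`, not of `a`.

## Pathway Signal Flow

A pathway is a directed graph of gene nodes (with member gene ids),
compound nodes, and activation/inhibition edges, serialized as a simple
TSV (`node` / `edge` / `reaction` records). KEGG-style
substrate–enzyme–product reactions convert to one-directional relations
(`S → E → P`; `rev` records orient against the written direction, and a
record with any other direction flag is rejected rather than guessed).

Cyclic topologies are linearized by **splitting one node** into an input
copy (keeping outgoing edges) and an output copy (keeping incoming edges)
— for the TCA cycle, the oxaloacetate node, which then acts as both
pathway input and final output. Graphs with residual cycles after the
split are an error naming the nodes involved, not a silent approximation.

Node weights come from expression: a gene node's weight is
`10^(mean_target − mean_reference)` of its member-gene mean log10
expression; compounds, inputs and outputs are pass-through (weight 1),
since metabolites have no transcript — the method estimates their activity
from the enzymes around them and deliberately ignores post-translational
regulation. The reference defaults to the cohort's control-like class;
per-class means are used (per-sample weighting can be composed from the
same functions).

Propagation runs in topological order: an input's signal is its weight;
every other node aggregates one contribution per incoming edge — the
upstream signal for activation, its reciprocal for inhibition — and
multiplies by its own weight. Aggregation at joins is the arithmetic mean
by default (`min` and `prod` are selectable). This rule is a declared
stand-in for the published propagation family: on chains it is exactly the
product of weights along the path, inhibition inverts, and raising any
weight never lowers a downstream signal on all-activation graphs — the
qualitative behaviour the analysis depends on, and the properties the test
suite asserts. Signals are reported in both linear and log10 form.

## Synthetic cohorts and what passing tests mean

`generate_cohort()` emulates the structure the analysis targets: several
sample classes, with disjoint gene modules co-overexpressed in designated
classes. Every entry is

```
baseline + effect · 1[gene ∈ module m, class ∈ up_classes(m)] + N(0, noise_sd)
```

on the log10 scale. The default design — five classes of 12 samples
(labelled after the lymphoma subtypes BL, DLBCL, IntL, FL, MM for
readability), 2000 genes, four 50-gene modules each ten-fold up
(effect 1.0) in one class, noise 0.3 log10 units — is a desk-scale
calibration choice: the source analyses state no effect or noise figures,
and 0.3 log10 units of i.i.d. noise with a 1.0 effect gives a
per-gene signal-to-noise regime in which single genes are noisy but
50-gene modules are unambiguous, which is what a planted-recovery test
should probe. The fifth class carries no module and serves as the quiet
reference for contrasts. One integer seed drives a single stream;
per-stage sub-streams are derived from it deterministically.

The generator emulates class-specific co-expression on a log scale with
additive Gaussian noise. It does **not** emulate correlated background
genes, probe-level effects, batch structure, heavy-tailed or count-based
noise, or partially overlapping programs. Passing recovery tests therefore
show that the pipeline's machinery is correct and well-calibrated under
its stated model — not that real cohorts will yield spots this clean.

`generate_toy_pathway()` builds the matching pathway fixture: a
compound/enzyme cycle with all-activation edges and a companion expression
matrix encoding each enzyme's fold change between a reference and a target
class.

## Numerical choices and degenerate inputs

* Quantiles are type-1 (inverse CDF) throughout; ties at cuts are
  included. BMU and component labelling ties break to the lowest
  row-major index.
* Zero-variance genes with `s0 = 0` yield an infinite t, p = 0, and a
  `flagged` marker rather than NaN; `d = 0` with zero variance gives
  t = 0, p = 1.
* Degenerate spot situations (no component passing `min_size`) degrade
  gracefully in the pipeline: spot-level statistics and the network are
  skipped with a warning instead of failing the run.
* Zero-variance spot profiles get correlation 0 rather than NA before the
  wTO step.
* p-values are floored at the smallest positive double before Fisher
  combination.
* JSON reports are written with full precision and no timestamps, so a
  fixed config and seed reproduce `report.json` byte for byte.

## Problem sizes

The test suite and acceptance script run entirely on synthetic data at the
default design size (2000 genes × 60 samples, 20 × 20 map, 20 epochs),
plus 10⁴-gene null matrices for calibration and exhaustive small-universe
enumeration (≤ 60) for the hypergeometric oracle. These sizes were chosen
so the whole validation runs in well under a minute on one core while
keeping every statistic in a regime where its behaviour is
distinguishable from chance.

## Interfaces

The package's interface is its exported functions; `run_pipeline()`
orchestrates the full chain from one config list (or YAML file) and writes
a report bundle (stage tables, `report.json`, `provenance.yaml`) whose
parameters and conventions are recorded in the provenance file. Per-stage
functions expose every intermediate, so each number in the report can be
reproduced in isolation.

## Known limitations

* Online SOM training only — no batch SOM, toroidal topology, or GPU
  path.
* The spot/segmentation geometry is crisp; fuzzy borders are not modelled.
* The shrinkage rule and the PSF combination rule are declared variants of
  their published families, not bit-compatible reimplementations of any
  specific upstream tool.
* Under-expression spots, gene-level WGCNA, GSZ-type set statistics,
  KGML parsing and figure rendering are out of scope.
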