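# Shared fixtures, built lazily and cached for the whole test run so the
# SOM is trained once per design/seed.
.fixtures <- new.env(parent = emptyenv())

# Default five-class cohort, centred, with a trained 20x20 map and the
# recurrent-overexpression spot map used by the pipeline.
default_fit <- function(seed = 1) {
  key <- paste0("fit_", seed)
  if (is.null(.fixtures[[key]])) {
    cohort <- generate_cohort(default_cohort_design(seed = seed))
    x <- center_genes(cohort$expr)
    grid <- train_som(x, seed = seed)
    portraits <- all_portraits(grid)
    ov <- overexpression_summary_map(portraits, q = 0.98)
    spotmap <- detect_spots(ov$binary & (ov$summary >= 0.1), ov$summary,
                            min_size = 4)
    .fixtures[[key]] <- list(cohort = cohort, x = x, grid = grid,
                             portraits = portraits, overexpression = ov,
                             spotmap = spotmap)
  }
  .fixtures[[key]]
}

# Planted-module gene sets of a synthetic cohort.
module_gene_sets <- function(cohort) {
  truth <- cohort$truth$module_of_gene
  split(names(truth)[!is.na(truth)], truth[!is.na(truth)])
}

# Best Jaccard between one gene set and any spot's gene set.
best_spot_jaccard <- function(gene_set, spot_gene_sets) {
  max(vapply(spot_gene_sets, function(s) {
    length(intersect(s, gene_set)) / length(union(s, gene_set))
  }, 0))
}

# Tiny labelled matrix helper.
lab_matrix <- function(values, n_genes, n_samples) {
  matrix(values, n_genes, n_samples,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(n_samples))))
}
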