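#' Describe a planted co-expression module
#'
#' A module is a disjoint block of genes jointly overexpressed (additively,
#' on the log10 scale) in the samples of one or more designated classes.
#'
#' @param id module identifier (character scalar).
#' @param n_genes number of member genes.
#' @param up_classes character vector of class labels in which the module is
#'   overexpressed.
#' @param effect additive overexpression effect in log10 units (>= 0); an
#'   effect of 1 corresponds to a ten-fold linear change.
#' @param genes optional explicit gene identifiers for the module members
#'   (length `n_genes`); by default genes are drawn from the cohort's
#'   generic identifier pool.
#' @return an object of class `planted_module`.
#' @export
planted_module <- function(id, n_genes, up_classes, effect = 1, genes = NULL) {
  stopifnot(is.character(id), length(id) == 1L, n_genes >= 1)
  if (effect < 0) stopf("module effect must be >= 0, got %g", effect)
  if (!is.null(genes) && length(genes) != n_genes) {
    stopf("module '%s': %d gene ids supplied for n_genes = %d",
          id, length(genes), n_genes)
  }
  structure(
    list(id = id, n_genes = as.integer(n_genes),
         up_classes = as.character(up_classes), effect = effect,
         genes = genes),
    class = "planted_module"
  )
}

#' Define a synthetic cohort design
#'
#' The design fixes the class structure of the cohort (class labels and
#' per-class sample counts), the planted modules, the additive Gaussian
#' noise level and the baseline, all on the log10 expression scale.
#'
#' @param n_genes total number of genes.
#' @param classes named integer vector: class label -> number of samples.
#' @param modules list of [planted_module()] objects; member gene sets must
#'   be disjoint and fit into `n_genes`.
#' @param noise_sd standard deviation of additive Gaussian noise
#'   (log10 units, >= 0).
#' @param baseline baseline log10 expression added to every entry.
#' @param seed integer seed driving the cohort's pseudorandom stream.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(n_genes, classes, modules = list(),
                          noise_sd = 0.3, baseline = 2, seed = 1) {
  if (n_genes < 1) stopf("n_genes must be positive")
  if (is.null(names(classes)) || any(names(classes) == "")) {
    stopf("`classes` must be a named vector: class label -> sample count")
  }
  if (anyDuplicated(names(classes))) stopf("duplicate class labels")
  if (any(classes < 1)) stopf("every class needs at least one sample")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  modules <- lapply(modules, function(m) {
    if (!inherits(m, "planted_module")) stopf("modules must be planted_module objects")
    unknown <- setdiff(m$up_classes, names(classes))
    if (length(unknown)) {
      stopf("module '%s' references unknown class(es): %s",
            m$id, paste(unknown, collapse = ", "))
    }
    m
  })
  ids <- vapply(modules, `[[`, "", "id")
  if (anyDuplicated(ids)) stopf("duplicate module ids")
  if (sum(vapply(modules, `[[`, 1L, "n_genes")) > n_genes) {
    stopf("module genes exceed n_genes")
  }
  explicit <- unlist(lapply(modules, `[[`, "genes"))
  if (anyDuplicated(explicit)) stopf("planted module gene sets overlap")
  structure(
    list(n_genes = as.integer(n_genes),
         classes = stats::setNames(as.integer(classes), names(classes)),
         modules = modules, noise_sd = noise_sd, baseline = baseline,
         seed = as.integer(seed)),
    class = "cohort_design"
  )
}

#' Default desk-scale cohort design
#'
#' Five tumour-like classes of 12 samples each, 2000 genes, four planted
#' 50-gene modules each overexpressed (effect 1.0 log10 units, i.e. a
#' ten-fold change) in one distinct class, Gaussian noise of 0.3 log10
#' units. The fifth class carries no planted module and serves as the
#' quiet reference.
#'
#' @param seed integer seed.
#' @param class_labels labels of the five classes.
#' @return a `cohort_design`.
#' @export
default_cohort_design <- function(seed = 1,
                                  class_labels = c("BL", "DLBCL", "IntL",
                                                   "FL", "MM")) {
  stopifnot(length(class_labels) == 5L)
  classes <- stats::setNames(rep(12L, 5L), class_labels)
  modules <- lapply(1:4, function(i) {
    planted_module(paste0("M", i), 50L, class_labels[i], effect = 1.0)
  })
  cohort_design(2000L, classes, modules, noise_sd = 0.3, baseline = 2,
                seed = seed)
}

#' Generate a synthetic expression cohort with planted modules
#'
#' Every matrix entry is
#' `baseline + effect * 1[gene in module m and sample class in up_classes(m)]
#'  + Normal(0, noise_sd)`, on the log10 scale. Module genes occupy the
#' leading rows (in module order) unless explicit gene ids were given;
#' ground truth records the planted membership either way.
#'
#' @param design a [cohort_design()].
#' @return a list of class `synthetic_cohort` with elements
#'   `expr` (gene x sample matrix, log10 scale),
#'   `classes` (named character vector sample -> class label) and
#'   `truth` (list with `module_of_gene` and `class_of_sample`).
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  n_samples <- sum(design$classes)
  class_of_sample <- rep(names(design$classes), design$classes)
  sample_ids <- paste0(class_of_sample, "_s",
                       unlist(lapply(design$classes, seq_len)))
  names(class_of_sample) <- sample_ids

  gene_ids <- sprintf("g%04d", seq_len(design$n_genes))
  module_of_gene <- rep(NA_character_, design$n_genes)
  cursor <- 0L
  for (m in design$modules) {
    if (is.null(m$genes)) {
      idx <- cursor + seq_len(m$n_genes)
      cursor <- cursor + m$n_genes
    } else {
      idx <- cursor + seq_len(m$n_genes)
      cursor <- cursor + m$n_genes
      gene_ids[idx] <- m$genes
    }
    module_of_gene[idx] <- m$id
  }
  names(module_of_gene) <- gene_ids

  signal <- matrix(design$baseline, design$n_genes, n_samples,
                   dimnames = list(gene_ids, sample_ids))
  for (m in design$modules) {
    rows <- which(module_of_gene == m$id)
    cols <- which(class_of_sample %in% m$up_classes)
    signal[rows, cols] <- signal[rows, cols] + m$effect
  }
  expr <- with_seed(design$seed, {
    signal + matrix(rnorm(length(signal), sd = design$noise_sd),
                    nrow(signal), ncol(signal))
  })
  dimnames(expr) <- dimnames(signal)

  structure(
    list(expr = expr, classes = class_of_sample,
         truth = list(module_of_gene = module_of_gene,
                      class_of_sample = class_of_sample),
         design = design),
    class = "synthetic_cohort"
  )
}

#' Generate a toy cyclic metabolic pathway with companion expression
#'
#' Builds a compound/enzyme cycle in the style of the TCA (Krebs) cycle:
#' `compound_1 -> enzyme_1 -> compound_2 -> ... -> enzyme_n -> compound_1`,
#' all edges of type "activation". One compound is given `split_label` so
#' the cycle can later be linearized at that node. The companion expression
#' matrix encodes each enzyme's linear-scale fold change `weights[i]` as a
#' log10 difference between a "target" and a "reference" sample class.
#'
#' @param n_enzymes number of enzymes (>= 2); the cycle has the same number
#'   of compounds.
#' @param split_label label for the designated split compound (default
#'   "Oxaloacetate", the classical split point of the TCA cycle).
#' @param weights numeric vector of length `n_enzymes`, positive
#'   linear-scale fold changes.
#' @param n_per_class samples per class in the companion matrix.
#' @return list with `graph` (a `pathway_graph`), `expr` (enzyme x sample
#'   log10 matrix) and `classes` (sample -> "reference"/"target").
#' @export
generate_toy_pathway <- function(n_enzymes, split_label = "Oxaloacetate",
                                 weights = rep(1, n_enzymes),
                                 n_per_class = 2L) {
  if (n_enzymes < 2) stopf("n_enzymes must be >= 2")
  if (length(weights) != n_enzymes) stopf("need one weight per enzyme")
  if (any(weights <= 0)) stopf("weights must be positive fold changes")

  compounds <- paste0("Cmp", seq_len(n_enzymes))
  compounds[1L] <- split_label
  enzymes <- paste0("Enz", seq_len(n_enzymes))
  nodes <- data.frame(
    id = c(compounds, enzymes),
    kind = rep(c("compound", "gene"), each = n_enzymes),
    stringsAsFactors = FALSE
  )
  nodes$genes <- c(vector("list", n_enzymes), as.list(enzymes))
  edges <- data.frame(
    from = c(compounds, enzymes),
    to = c(enzymes, compounds[c(seq_len(n_enzymes)[-1L], 1L)]),
    type = "activation",
    stringsAsFactors = FALSE
  )
  graph <- pathway_graph(nodes, edges)

  sample_ids <- c(paste0("ref_", seq_len(n_per_class)),
                  paste0("tgt_", seq_len(n_per_class)))
  classes <- stats::setNames(rep(c("reference", "target"), each = n_per_class),
                             sample_ids)
  expr <- cbind(
    matrix(0, n_enzymes, n_per_class),
    matrix(log10(weights), n_enzymes, n_per_class)
  )
  dimnames(expr) <- list(enzymes, sample_ids)

  list(graph = graph, expr = expr, classes = classes)
}
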