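#' Shrinkage t-test for differential expression
#'
#' Two-sample t-statistic per gene with an additive, cohort-wide fudge
#' constant in the denominator (SAM-style):
#' `t = d / (s + s0)` where `d = mean(class_a) - mean(class_b)` (log10
#' units), `s` is the pooled-variance standard error of `d`, and `s0` is
#' a single shrinkage constant shared by all genes. The fudge stabilizes
#' the statistic for genes with accidentally small variance. Two-sided
#' p-values come from Student's t with `n_a + n_b - 2` degrees of
#' freedom, with a Benjamini-Hochberg FDR column alongside.
#'
#' With `s0_rule = "none"` (s0 = 0) the statistic reduces exactly to the
#' ordinary pooled two-sample t-test.
#'
#' @param x gene x sample log10 expression matrix.
#' @param classes named character vector sample -> class label.
#' @param class_a,class_b the contrasted classes (each >= 2 samples).
#' @param s0_rule `"median"` (default: s0 = median of gene-wise standard
#'   errors), `"q90"` (90% quantile), `"none"` (s0 = 0), or a nonnegative
#'   number used directly.
#' @return data.frame of class `shrinkage_t` with columns gene, d, s, t,
#'   p, fdr and a logical `flagged` column marking genes whose statistic
#'   degenerated (zero variance and s0 = 0); attributes `s0` and `df`.
#' @export
shrinkage_t <- function(x, classes, class_a, class_b, s0_rule = "median") {
  check_expression_matrix(x)
  classes <- check_classes(classes, x)
  a <- names(classes)[classes == class_a]
  b <- names(classes)[classes == class_b]
  if (length(a) < 2L) stopf("class '%s' has fewer than 2 samples", class_a)
  if (length(b) < 2L) stopf("class '%s' has fewer than 2 samples", class_b)
  na <- length(a); nb <- length(b)
  xa <- x[, a, drop = FALSE]; xb <- x[, b, drop = FALSE]
  d <- rowMeans(xa) - rowMeans(xb)
  va <- rowSums((xa - rowMeans(xa))^2) / (na - 1)
  vb <- rowSums((xb - rowMeans(xb))^2) / (nb - 1)
  s2p <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  s <- sqrt(s2p * (1 / na + 1 / nb))
  s0 <- if (is.numeric(s0_rule)) {
    if (s0_rule < 0) stopf("numeric s0 must be >= 0")
    s0_rule
  } else {
    switch(match.arg(s0_rule, c("median", "q90", "none")),
           median = median(s),
           q90 = quantile(s, 0.9, type = 1, names = FALSE),
           none = 0)
  }
  denom <- s + s0
  t_stat <- ifelse(denom > 0, d / denom, ifelse(d == 0, 0, sign(d) * Inf))
  flagged <- denom == 0 & d != 0
  df <- na + nb - 2
  p <- ifelse(is.infinite(t_stat), 0, 2 * pt(-abs(t_stat), df))
  p[denom == 0 & d == 0] <- 1
  out <- data.frame(gene = rownames(x), d = unname(d), s = unname(s),
                    t = unname(t_stat), p = unname(p),
                    fdr = p.adjust(unname(p), method = "BH"),
                    flagged = unname(flagged), row.names = NULL)
  attr(out, "s0") <- s0
  attr(out, "df") <- df
  class(out) <- c("shrinkage_t", "data.frame")
  out
}

#' Spot-level shrinkage t-test
#'
#' Applies the shrinkage t-test to each spot's mean-gene profile (per
#' sample, the mean expression over the spot's member genes). Spots
#' without any mapped gene are omitted with a warning. The fudge s0 is
#' estimated across spots.
#'
#' @inheritParams shrinkage_t
#' @param spotmap a `spot_map`.
#' @param gene_to_unit named integer vector gene -> unit index.
#' @return `shrinkage_t` data.frame with one row per spot (column `gene`
#'   holds the spot label).
#' @export
spot_t <- function(x, classes, spotmap, gene_to_unit, class_a, class_b,
                   s0_rule = "median") {
  profiles <- spot_expression_profiles(x, spotmap, gene_to_unit)
  shrinkage_t(profiles, classes, class_a, class_b, s0_rule)
}

#' Differential expression and significance map overlays
#'
#' Projects a gene-level result onto the map: per unit the mean
#' difference `d` of its genes, and a combined significance via Fisher's
#' method (`-2 * sum(log p)` against chi-squared with `2k` df), reported
#' as `-log10(p_combined)`. Units without genes carry `NA`.
#'
#' @param result a `shrinkage_t` result over the grid's genes.
#' @param gene_to_unit named integer vector gene -> unit index.
#' @param grid the `som_grid` (for dimensions).
#' @return list with matrices `d` and `neg_log10_p`.
#' @export
overlay_maps <- function(result, gene_to_unit, grid) {
  stopifnot(inherits(grid, "som_grid"))
  n_units <- grid$n_rows * grid$n_cols
  idx <- match(names(gene_to_unit), result$gene)
  if (anyNA(idx)) stopf("result does not cover all mapped genes")
  d_mean <- rep(NA_real_, n_units)
  neglog <- rep(NA_real_, n_units)
  for (u in unique(gene_to_unit)) {
    genes <- which(gene_to_unit == u)
    d_mean[u] <- mean(result$d[idx[genes]])
    pv <- pmax(result$p[idx[genes]], .Machine$double.xmin)
    stat <- -2 * sum(log(pv))
    neglog[u] <- -log10(pchisq(stat, df = 2 * length(pv), lower.tail = FALSE))
  }
  list(d = matrix(d_mean, grid$n_rows, grid$n_cols, byrow = TRUE),
       neg_log10_p = matrix(neglog, grid$n_rows, grid$n_cols, byrow = TRUE))
}

#' Mean expression profile of a gene set
#'
#' Per-sample mean over the set's genes present in the matrix; set genes
#' absent from the matrix are ignored, and a set with no present gene is
#' an error naming the set.
#'
#' @param x gene x sample matrix.
#' @param genes character vector of set member gene ids.
#' @param set_name label used in messages.
#' @return named numeric vector per sample, with attribute
#'   `n_genes_used`.
#' @export
set_mean_profile <- function(x, genes, set_name = "gene set") {
  present <- intersect(genes, rownames(x))
  if (!length(present)) stopf("no gene of set '%s' present in the matrix", set_name)
  prof <- colMeans(x[present, , drop = FALSE])
  attr(prof, "n_genes_used") <- length(present)
  prof
}

#' Class-mean expression profile of a gene set
#'
#' @inheritParams set_mean_profile
#' @param classes named character vector sample -> class.
#' @return named numeric vector per class, with attribute
#'   `n_genes_used`.
#' @export
set_mean_class_profile <- function(x, genes, classes, set_name = "gene set") {
  prof <- set_mean_profile(x, genes, set_name)
  classes <- check_classes(classes, x)
  out <- tapply(prof[names(classes)], classes, mean)
  res <- stats::setNames(as.numeric(out), names(out))
  attr(res, "n_genes_used") <- attr(prof, "n_genes_used")
  res
}
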