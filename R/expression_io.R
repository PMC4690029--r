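#' Read a tab-separated expression matrix
#'
#' Expected layout: first row sample identifiers, first column gene
#' identifiers, numeric body, UTF-8, '.' decimal separator, no quoting.
#' The first header cell is ignored.
#'
#' @param path path to the TSV file.
#' @return numeric gene x sample matrix with dimnames.
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stopf("'%s': need a header line and at least one gene row", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  n_samples <- length(header) - 1L
  if (n_samples < 1L) stopf("'%s': header declares no samples", path)
  sample_ids <- header[-1L]
  body <- fields[-1L]
  widths <- lengths(body)
  bad <- which(widths != n_samples + 1L)
  if (length(bad)) {
    stopf("'%s' line %d: expected %d fields, found %d",
          path, bad[1L] + 1L, n_samples + 1L, widths[bad[1L]])
  }
  gene_ids <- vapply(body, `[[`, "", 1L)
  if (anyDuplicated(gene_ids)) {
    stopf("'%s': duplicate gene identifiers: %s", path,
          paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  cells <- vapply(body, function(f) suppressWarnings(as.numeric(f[-1L])),
                  numeric(n_samples))
  # vapply gives samples x genes; transpose back
  x <- if (n_samples == 1L) matrix(cells, ncol = 1L) else t(cells)
  if (anyNA(x)) {
    row_bad <- which(rowSums(is.na(x)) > 0L)[1L]
    stopf("'%s' line %d: non-numeric expression value for gene '%s'",
          path, row_bad + 1L, gene_ids[row_bad])
  }
  dimnames(x) <- list(gene_ids, sample_ids)
  check_expression_matrix(x)
  x
}

#' Write an expression matrix as TSV
#'
#' @param x gene x sample numeric matrix with dimnames.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_expression_tsv <- function(x, path) {
  check_expression_matrix(x)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(v)
    paste(format(v, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Centre gene expression profiles
#'
#' Subtracts each gene's mean across all samples, turning absolute log10
#' expression into differential expression relative to the cohort mean —
#' the preprocessing behind differential-expression SOM portraits. A
#' centred difference of 1 between two samples still corresponds to a
#' ten-fold linear change.
#'
#' @param x gene x sample log10 matrix.
#' @return matrix of the same shape with zero row means.
#' @export
center_genes <- function(x) {
  check_expression_matrix(x)
  x - rowMeans(x)
}

#' Log10-transform a linear-scale matrix
#'
#' Convenience for linear-scale input: `log10(x + eps)` with a pseudocount
#' of one linear unit by default.
#'
#' @param x nonnegative linear-scale matrix.
#' @param eps pseudocount in linear units.
#' @return log10-scale matrix.
#' @export
to_log10 <- function(x, eps = 1) {
  if (any(x + eps <= 0)) stopf("values must satisfy x + eps > 0")
  log10(x + eps)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene identifiers. Genes absent from a given expression
#' matrix are retained; filtering happens downstream against the matrix
#' universe.
#'
#' @param path path to the GMT file.
#' @return list with `sets` (named list of gene-id vectors) and
#'   `description` (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("'%s': empty GMT file", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names_)) stopf("'%s': duplicate set names", path)
  empty <- lengths(fields) < 3L
  if (any(empty)) {
    stopf("'%s': gene set '%s' has no member genes", path, names_[which(empty)[1L]])
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- names_
  desc <- stats::setNames(vapply(fields, `[[`, "", 2L), names_)
  list(sets = sets, description = desc)
}

#' Read a two-column sample-class table
#'
#' TSV with header `sample<TAB>class`.
#'
#' @param path path to the TSV file.
#' @return named character vector sample -> class label.
#' @export
read_classes_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character")
  if (ncol(df) < 2L) stopf("'%s': need two columns (sample, class)", path)
  if (anyDuplicated(df[[1L]])) stopf("'%s': duplicate sample ids", path)
  stats::setNames(df[[2L]], df[[1L]])
}

#' Write a sample-class table
#' @param classes named character vector sample -> class.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_classes_tsv <- function(classes, path) {
  df <- data.frame(sample = names(classes), class = unname(classes))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.modifier_marks <- c("H3K4", "H3K9", "H3K27", "H3K36", "H3K79", "DNA")
.modifier_roles <- c("writer", "eraser", "reader")
.modifier_effects <- c("act", "rep", "unknown")

#' Read a chromatin-modifier annotation table
#'
#' Four tab-separated columns with header: `symbol` (gene symbol), `mark`
#' (the targeted mark: H3K4, H3K9, H3K27, H3K36, H3K79 or DNA), `role`
#' (writer, eraser or reader of that mark) and `effect` (expected net
#' effect on transcription of the affected targets: act, rep or unknown).
#' A gene may appear in several rows when it acts on several marks. The
#' packaged fixture `table1_modifiers.tsv` lists histone-lysine and
#' DNA-CpG methyltransferases, demethylases and readers with relevance
#' for lymphoma.
#'
#' @param path path to the TSV file; defaults to the packaged fixture.
#' @return data.frame with columns symbol, mark, role, effect.
#' @export
read_annotation_tsv <- function(path = system.file("extdata",
                                                   "table1_modifiers.tsv",
                                                   package = "epicart")) {
  df <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                   colClasses = "character")
  need <- c("symbol", "mark", "role", "effect")
  if (!all(need %in% names(df))) {
    stopf("'%s': expected columns %s", path, paste(need, collapse = ", "))
  }
  df <- df[need]
  bad_mark <- setdiff(unique(df$mark), .modifier_marks)
  if (length(bad_mark)) stopf("unknown mark(s): %s", paste(bad_mark, collapse = ", "))
  bad_role <- setdiff(unique(df$role), .modifier_roles)
  if (length(bad_role)) stopf("unknown role(s): %s", paste(bad_role, collapse = ", "))
  bad_eff <- setdiff(unique(df$effect), .modifier_effects)
  if (length(bad_eff)) stopf("unknown effect(s): %s", paste(bad_eff, collapse = ", "))
  df
}
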