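#' Train a self-organizing map of metagenes on gene expression profiles
#'
#' Classic online Kohonen training on the gene profiles of a (preferably
#' gene-centred) log10 expression matrix. Each map unit holds a "metagene"
#' — a prototype expression profile over all samples. Per presented gene
#' profile the best-matching unit (BMU, Euclidean argmin) is found and all
#' units are pulled towards the profile with a Gaussian neighbourhood
#' kernel whose radius and learning rate decay exponentially over the
#' epochs. After training every gene is assigned to its BMU under the
#' final metagenes, so similar genes come to occupy nearby map units.
#'
#' Units are indexed row-major with unit 1 at the top-left corner;
#' unit `(r, c)` has index `(r - 1) * n_cols + c`. All other map-level
#' operations in the package share this convention.
#'
#' @param x gene x sample numeric matrix (log10 scale, gene-centred; a
#'   warning is issued when rows are visibly uncentred).
#' @param n_rows,n_cols grid dimensions; the default 20 x 20 map is a
#'   desk-scale choice for cohorts of a few thousand genes.
#' @param epochs number of passes over all genes.
#' @param alpha length-2 vector, initial and final learning rate.
#' @param radius length-2 vector, initial and final neighbourhood radius
#'   (grid units); defaults to `max(n_rows, n_cols) / 2` decaying to 0.5.
#' @param seed integer seed; initial metagenes are sampled from the gene
#'   profiles and presentation order is reshuffled per epoch from this
#'   stream, so training is fully reproducible.
#' @return an object of class `som_grid`: list with `codebook`
#'   (unit x sample metagene matrix), `n_rows`, `n_cols`, `gene_to_unit`
#'   (named integer vector, 1-based row-major unit index per gene) and
#'   `params`.
#' @export
train_som <- function(x, n_rows = 20, n_cols = 20, epochs = 20,
                      alpha = c(0.5, 0.01), radius = NULL, seed = 1) {
  check_expression_matrix(x)
  n_units <- n_rows * n_cols
  if (n_units < 1) stopf("grid must have at least one unit")
  if (n_units > 1e6) stopf("refusing to train a grid with more than 1e6 units")
  if (max(abs(rowMeans(x))) > 1e-6) {
    warnf("input rows are not centred; consider center_genes() for differential-expression portraits")
  }
  if (is.null(radius)) radius <- c(max(n_rows, n_cols) / 2, 0.5)
  stopifnot(length(alpha) == 2L, length(radius) == 2L,
            all(alpha > 0), all(radius > 0))

  n_genes <- nrow(x)
  coords <- unit_coords(n_rows, n_cols)
  init_order <- with_seed(derive_seed(seed, "som_init"),
                          sample.int(n_genes, n_units, replace = n_units > n_genes))
  codebook <- x[init_order, , drop = FALSE]
  orders <- with_seed(derive_seed(seed, "som_order"), {
    do.call(rbind, lapply(seq_len(epochs), function(e) sample.int(n_genes)))
  })
  cb <- som_train_cpp(x, codebook, orders, coords$row, coords$col,
                      alpha[1L], alpha[2L], radius[1L], radius[2L])
  rownames(cb) <- unit_ids(n_rows, n_cols)
  colnames(cb) <- colnames(x)
  grid <- structure(
    list(codebook = cb, n_rows = as.integer(n_rows),
         n_cols = as.integer(n_cols), gene_to_unit = NULL,
         params = list(epochs = epochs, alpha = alpha, radius = radius,
                       seed = seed)),
    class = "som_grid"
  )
  grid$gene_to_unit <- assign_genes(x, grid)
  grid
}

unit_coords <- function(n_rows, n_cols) {
  list(row = rep(seq_len(n_rows), each = n_cols),
       col = rep(seq_len(n_cols), times = n_rows))
}

unit_ids <- function(n_rows, n_cols) {
  co <- unit_coords(n_rows, n_cols)
  sprintf("u_%d_%d", co$row, co$col)
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("som_grid: %d x %d units, %d samples, %s genes assigned\n",
              x$n_rows, x$n_cols, ncol(x$codebook),
              if (is.null(x$gene_to_unit)) "no" else length(x$gene_to_unit)))
  invisible(x)
}

#' Best-matching unit of a profile
#'
#' Euclidean argmin over the grid's metagenes; ties are broken by the
#' lowest row-major unit index.
#'
#' @param profile numeric vector of length `n_samples`.
#' @param grid a `som_grid`.
#' @return 1-based row-major unit index.
#' @export
best_matching_unit <- function(profile, grid) {
  stopifnot(inherits(grid, "som_grid"))
  if (length(profile) != ncol(grid$codebook)) {
    stopf("profile length %d does not match the grid's %d samples",
          length(profile), ncol(grid$codebook))
  }
  d2 <- rowSums(grid$codebook^2) - 2 * drop(grid$codebook %*% profile)
  unname(which.min(d2))
}

#' Assign every gene of a matrix to its best-matching unit
#'
#' @param x gene x sample matrix with the grid's samples.
#' @param grid a `som_grid`.
#' @return named integer vector gene -> unit index.
#' @export
assign_genes <- function(x, grid) {
  stopifnot(inherits(grid, "som_grid"), ncol(x) == ncol(grid$codebook))
  cb <- grid$codebook
  # squared distances up to a per-gene constant; argmin is unaffected
  d2 <- matrix(rowSums(cb^2), nrow(x), nrow(cb), byrow = TRUE) - 2 * x %*% t(cb)
  stats::setNames(max.col(-d2, ties.method = "first"), rownames(x))
}

#' Mean quantization error of a map
#'
#' Mean Euclidean distance between each gene profile and its BMU metagene.
#'
#' @param x gene x sample matrix.
#' @param grid a `som_grid`.
#' @return nonnegative scalar.
#' @export
quantization_error <- function(x, grid) {
  units <- assign_genes(x, grid)
  mean(sqrt(rowSums((x - grid$codebook[units, , drop = FALSE])^2)))
}

new_portrait <- function(values, grid, id) {
  m <- matrix(values, grid$n_rows, grid$n_cols, byrow = TRUE)
  structure(m, class = c("portrait", "matrix"), sample_id = id)
}

#' Per-sample expression portrait
#'
#' Arranges the metagene values of one sample on the grid: the portrait
#' value at unit `(r, c)` is that unit's metagene expression in the
#' sample. Class portraits average the portraits of a class's samples.
#'
#' @param grid a trained `som_grid`.
#' @param sample_id a sample of the grid's training matrix.
#' @return `n_rows x n_cols` matrix of class `portrait`.
#' @export
sample_portrait <- function(grid, sample_id) {
  stopifnot(inherits(grid, "som_grid"))
  if (!sample_id %in% colnames(grid$codebook)) {
    stopf("unknown sample '%s'", sample_id)
  }
  new_portrait(grid$codebook[, sample_id], grid, sample_id)
}

#' Class-mean expression portrait
#'
#' @param grid a trained `som_grid`.
#' @param classes named character vector sample -> class covering the
#'   grid's samples.
#' @param class_label class to portray.
#' @return `portrait` matrix, the elementwise mean of the class's sample
#'   portraits.
#' @export
class_portrait <- function(grid, classes, class_label) {
  stopifnot(inherits(grid, "som_grid"))
  members <- names(classes)[classes == class_label]
  members <- intersect(colnames(grid$codebook), members)
  if (!length(members)) stopf("unknown or empty class '%s'", class_label)
  new_portrait(rowMeans(grid$codebook[, members, drop = FALSE]),
               grid, class_label)
}

#' Mean total expression per portrait
#'
#' Arithmetic mean over all grid units of each portrait's values; on
#' centred data this summarizes a sample's overall transcriptional
#' activity relative to the cohort mean.
#'
#' @param portraits list of `portrait` matrices sharing one grid.
#' @return named numeric vector (names taken from each portrait's id).
#' @export
mean_total_expression <- function(portraits) {
  if (!length(portraits)) return(numeric(0))
  dims <- vapply(portraits, dim, integer(2))
  if (any(dims != dims[, 1L])) stopf("portraits must share one grid")
  stats::setNames(vapply(portraits, mean, 0),
                  vapply(portraits, attr, "", "sample_id"))
}

#' All per-sample portraits of a trained map
#'
#' @param grid a trained `som_grid`.
#' @return named list of `portrait` matrices, one per sample.
#' @export
all_portraits <- function(grid) {
  stopifnot(inherits(grid, "som_grid"))
  ids <- colnames(grid$codebook)
  stats::setNames(lapply(ids, function(s) sample_portrait(grid, s)), ids)
}
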