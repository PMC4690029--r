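#' Overexpression summary map
#'
#' For every portrait, units whose value reaches the portrait's `q`
#' empirical quantile (type-1 / inverse-CDF definition, ties at the cut
#' included) are marked as overexpressed. The summary map records the
#' fraction of portraits marking each unit; the binary map is the union
#' of all marks — together the per-cohort "overexpression spot summary".
#'
#' @param portraits list of `portrait` matrices (same grid).
#' @param q marking quantile in (0, 1); default 0.98 marks roughly the
#'   top 2% of units per portrait.
#' @return list with `summary` (fraction-of-portraits matrix) and
#'   `binary` (logical matrix, union of marks).
#' @export
overexpression_summary_map <- function(portraits, q = 0.98) {
  if (!length(portraits)) stopf("need at least one portrait")
  if (q <= 0 || q >= 1) stopf("q must lie strictly between 0 and 1")
  marks <- lapply(portraits, function(p) {
    cut <- quantile(as.vector(p), probs = q, type = 1, names = FALSE)
    p >= cut
  })
  summary <- Reduce(`+`, lapply(marks, function(m) m * 1)) / length(marks)
  binary <- Reduce(`|`, marks)
  attr(summary, "sample_id") <- NULL
  list(summary = unclass(summary), binary = unclass(binary))
}

# 8-connected component labelling on a logical grid (iterative BFS).
label_components <- function(binary) {
  n_rows <- nrow(binary); n_cols <- ncol(binary)
  lab <- matrix(0L, n_rows, n_cols)
  cur <- 0L
  for (r0 in seq_len(n_rows)) for (c0 in seq_len(n_cols)) {
    if (!binary[r0, c0] || lab[r0, c0] != 0L) next
    cur <- cur + 1L
    queue <- matrix(c(r0, c0), 1L)
    lab[r0, c0] <- cur
    while (nrow(queue)) {
      r <- queue[1L, 1L]; c <- queue[1L, 2L]
      queue <- queue[-1L, , drop = FALSE]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1L || rr > n_rows || cc < 1L || cc > n_cols) next
        if (binary[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
  }
  lab
}

#' Detect overexpression spots
#'
#' 8-connected components of marked units with at least `min_size` units
#' become spots, labelled 'A', 'B', ... in order of decreasing peak
#' summary value. Smaller components are discarded as noise.
#'
#' @param binary logical `n_rows x n_cols` matrix of marked units.
#' @param summary numeric matrix of the same shape (fraction of portraits
#'   marking each unit) used to rank spots by their peak; defaults to the
#'   binary map itself, in which case ties are ranked by size.
#' @param min_size minimum spot size in units.
#' @return object of class `spot_map`: list with `unit_label` (character
#'   vector over row-major units, `NA` off-spot), `spots` (data.frame:
#'   label, size, peak) and grid dimensions.
#' @export
detect_spots <- function(binary, summary = NULL, min_size = 4) {
  stopifnot(is.matrix(binary))
  binary <- binary != 0
  if (is.null(summary)) summary <- binary * 1
  stopifnot(all(dim(summary) == dim(binary)))
  lab <- label_components(binary)
  n_comp <- max(lab)
  keep <- integer(0)
  peaks <- sizes <- numeric(0)
  for (k in seq_len(n_comp)) {
    sz <- sum(lab == k)
    if (sz >= min_size) {
      keep <- c(keep, k)
      sizes <- c(sizes, sz)
      peaks <- c(peaks, max(summary[lab == k]))
    }
  }
  ord <- order(-peaks, -sizes, keep)
  labels <- spot_labels(length(keep))
  unit_label <- rep(NA_character_, length(binary))
  lab_rm <- as.vector(t(lab))  # row-major unit order
  for (i in seq_along(ord)) {
    unit_label[lab_rm == keep[ord[i]]] <- labels[i]
  }
  structure(
    list(unit_label = unit_label,
         spots = data.frame(label = labels,
                            size = as.integer(sizes[ord]),
                            peak = peaks[ord]),
         n_rows = nrow(binary), n_cols = ncol(binary)),
    class = "spot_map"
  )
}

#' @export
print.spot_map <- function(x, ...) {
  cat(sprintf("spot_map: %d spot(s) on a %d x %d grid\n",
              nrow(x$spots), x$n_rows, x$n_cols))
  if (nrow(x$spots)) print(x$spots)
  invisible(x)
}

#' Genes mapped to each spot
#'
#' @param spotmap a `spot_map`.
#' @param gene_to_unit named integer vector gene -> row-major unit index.
#' @return named list spot label -> character vector of gene ids.
#' @export
spot_genes <- function(spotmap, gene_to_unit) {
  stopifnot(inherits(spotmap, "spot_map"))
  lab <- spotmap$unit_label[gene_to_unit]
  split(names(gene_to_unit)[!is.na(lab)], lab[!is.na(lab)])
}

#' Associate spots with the sample classes that overexpress them
#'
#' A spot is associated with every class whose class-portrait mean over
#' the spot's units is positive and within `frac` of the maximal class
#' mean for that spot.
#'
#' @param spotmap a `spot_map`.
#' @param grid the trained `som_grid`.
#' @param classes named character vector sample -> class.
#' @param frac fraction of the maximal class mean (default 0.9).
#' @return named list spot label -> character vector of class labels.
#' @export
spot_classes <- function(spotmap, grid, classes, frac = 0.9) {
  stopifnot(inherits(spotmap, "spot_map"), inherits(grid, "som_grid"))
  out <- list()
  for (lb in spotmap$spots$label) {
    units <- which(spotmap$unit_label == lb)
    means <- vapply(unique(classes), function(cl) {
      mean(class_portrait(grid, classes, cl)[matrix_index(units, spotmap$n_cols)])
    }, 0)
    top <- max(means)
    out[[lb]] <- if (top <= 0) character(0) else
      names(means)[means > 0 & means >= frac * top]
  }
  out
}

# row-major unit indices -> (row, col) index matrix for matrix subsetting
matrix_index <- function(units, n_cols) {
  cbind((units - 1L) %/% n_cols + 1L, (units - 1L) %% n_cols + 1L)
}

#' Segment the map into four quadrants and a central zone
#'
#' The central zone Z is the centred rectangle whose side is
#' `ceiling(central_fraction * dim)` in each dimension; the remaining
#' units fall into the four corner quadrants: Q1 top-left, Q2 top-right,
#' Q3 bottom-right, Q4 bottom-left (a declared convention — on real maps
#' the quadrant letters are arbitrary under rotation). Units above/left
#' of the grid midline count as top/left.
#'
#' @param n_rows,n_cols grid dimensions (at least 2 x 2).
#' @param central_fraction side fraction of the central zone, in (0, 1).
#' @return object of class `map_segmentation`: character vector over
#'   row-major units with values Q1..Q4/Z, plus dimension attributes.
#' @export
segment_map <- function(n_rows, n_cols, central_fraction = 1 / 3) {
  if (n_rows < 2 || n_cols < 2) stopf("grid must be at least 2 x 2")
  if (central_fraction <= 0 || central_fraction >= 1) {
    stopf("central_fraction must lie strictly between 0 and 1")
  }
  zr <- ceiling(central_fraction * n_rows)
  zc <- ceiling(central_fraction * n_cols)
  r0 <- floor((n_rows - zr) / 2) + 1L
  c0 <- floor((n_cols - zc) / 2) + 1L
  co <- unit_coords(n_rows, n_cols)
  in_z <- co$row >= r0 & co$row < r0 + zr & co$col >= c0 & co$col < c0 + zc
  top <- co$row <= n_rows / 2
  left <- co$col <= n_cols / 2
  region <- ifelse(in_z, "Z",
            ifelse(top & left, "Q1",
            ifelse(top & !left, "Q2",
            ifelse(!top & !left, "Q3", "Q4"))))
  structure(region, class = "map_segmentation",
            n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
            central_fraction = central_fraction)
}

#' Count genes and annotated genes per map region or spot
#'
#' Tallies, for every region of a segmentation (or every spot of a spot
#' map), the total number of genes mapped there and how many of them
#' belong to an annotated gene group — the region-wise counting used to
#' ask where, e.g., writers and erasers of methylation marks sit on the
#' map. Annotated genes absent from `gene_to_unit` are dropped with a
#' warning. If `invariant_units` is supplied, genes in those units are
#' reported under the extra region "Inv" instead of their nominal region.
#'
#' @param gene_to_unit named integer vector gene -> unit index.
#' @param regions a `map_segmentation` or `spot_map`.
#' @param annotated character vector of annotated gene ids.
#' @param invariant_units optional integer vector of low-variance units
#'   (see [invariant_units()]).
#' @return data.frame with columns region, n_genes, n_annotated; totals
#'   over regions equal the number of genes.
#' @export
count_by_region <- function(gene_to_unit, regions, annotated = character(0),
                            invariant_units = NULL) {
  if (inherits(regions, "spot_map")) {
    region_of_unit <- regions$unit_label
    region_of_unit[is.na(region_of_unit)] <- "none"
    levels <- c(regions$spots$label, "none")
  } else if (inherits(regions, "map_segmentation")) {
    region_of_unit <- as.character(regions)
    levels <- c("Q1", "Q2", "Q3", "Q4", "Z")
  } else {
    stopf("`regions` must be a map_segmentation or spot_map")
  }
  unknown <- setdiff(annotated, names(gene_to_unit))
  if (length(unknown)) {
    warnf("dropping %d annotated gene(s) absent from the map: %s",
          length(unknown), paste(utils::head(unknown, 5L), collapse = ", "))
    annotated <- setdiff(annotated, unknown)
  }
  gene_region <- region_of_unit[gene_to_unit]
  if (!is.null(invariant_units)) {
    gene_region[gene_to_unit %in% invariant_units] <- "Inv"
    levels <- c(levels, "Inv")
  }
  is_annot <- names(gene_to_unit) %in% annotated
  data.frame(
    region = levels,
    n_genes = vapply(levels, function(l) sum(gene_region == l), 0L),
    n_annotated = vapply(levels, function(l) sum(gene_region == l & is_annot), 0L),
    row.names = NULL
  )
}

# Upper hypergeometric tail P(X >= k) for X ~ Hypergeom(N, K, n);
# vectorized over its arguments.
hyper_tail_p <- function(k, K, N, n) {
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' One-sided Fisher exact enrichment of an annotated group in a region
#'
#' Tests whether annotated genes over-represent inside a map region (or
#' the union of spots) relative to the gene universe, via the upper
#' hypergeometric tail: the probability of observing at least the given
#' overlap when `n_in_region` genes are drawn from a universe of
#' `n_universe` containing `n_annot` annotated ones.
#'
#' @param n_overlap annotated genes inside the region.
#' @param n_in_region genes inside the region.
#' @param n_annot annotated genes in the universe.
#' @param n_universe size of the gene universe.
#' @return object of class `enrichment_result`: list with the 2x2
#'   `contingency` table, `odds_ratio`, one-sided `p_value` and
#'   `direction = "greater"`.
#' @export
fisher_enrichment <- function(n_overlap, n_in_region, n_annot, n_universe) {
  k <- n_overlap; n <- n_in_region; K <- n_annot; N <- n_universe
  if (any(c(k, n, K, N) < 0) || k > n || k > K || n > N || K > N ||
      (n - k) > (N - K)) {
    stopf("inconsistent contingency margins")
  }
  tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2L, 2L,
                dimnames = list(annotated = c("yes", "no"),
                                in_region = c("yes", "no")))
  p <- hyper_tail_p(k, K, N, n)
  num <- k * (N - K - n + k)
  den <- (K - k) * (n - k)
  or <- if (den == 0) Inf else num / den
  structure(
    list(contingency = tab, odds_ratio = or, p_value = p,
         direction = "greater"),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Fisher exact enrichment (one-sided greater): p = %.4g, OR = %.4g\n",
              x$p_value, x$odds_ratio))
  print(x$contingency)
  invisible(x)
}

#' Metagene variance map
#'
#' Population variance of each unit's metagene profile across samples;
#' low-variance units collect genes of near-invariant expression.
#'
#' @param grid a trained `som_grid`.
#' @return `n_rows x n_cols` numeric matrix of unit variances.
#' @export
variance_map <- function(grid) {
  stopifnot(inherits(grid, "som_grid"))
  v <- rowMeans(grid$codebook^2) - rowMeans(grid$codebook)^2
  matrix(v, grid$n_rows, grid$n_cols, byrow = TRUE)
}

#' Invariant (low-variance) units
#'
#' Units whose metagene variance lies at or below the `q` type-1 quantile
#' of all unit variances.
#'
#' @param vmap variance matrix from [variance_map()].
#' @param q quantile in (0, 1].
#' @return integer vector of row-major unit indices.
#' @export
invariant_units <- function(vmap, q = 0.25) {
  if (q <= 0 || q > 1) stopf("q must lie in (0, 1]")
  v <- as.vector(t(vmap))  # row-major
  cut <- quantile(v, probs = q, type = 1, names = FALSE)
  which(v <= cut)
}
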