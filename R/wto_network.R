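#' Spot mean expression profiles
#'
#' Per spot, the mean expression of its member genes in every sample —
#' the node profiles of the spot correlation network. Spots without any
#' mapped gene are omitted with a warning.
#'
#' @param x gene x sample expression matrix.
#' @param spotmap a `spot_map`.
#' @param gene_to_unit named integer vector gene -> unit index.
#' @return spot x sample numeric matrix (rownames = spot labels).
#' @export
spot_expression_profiles <- function(x, spotmap, gene_to_unit) {
  stopifnot(inherits(spotmap, "spot_map"))
  genes <- spot_genes(spotmap, gene_to_unit)
  empty <- setdiff(spotmap$spots$label, names(genes))
  if (length(empty)) {
    warnf("omitting spot(s) without mapped genes: %s",
          paste(empty, collapse = ", "))
  }
  labels <- intersect(spotmap$spots$label, names(genes))
  if (!length(labels)) stopf("no spot has mapped genes")
  profs <- t(vapply(labels,
                    function(lb) colMeans(x[genes[[lb]], , drop = FALSE]),
                    numeric(ncol(x))))
  rownames(profs) <- labels
  profs
}

#' Signed weighted topological overlap
#'
#' Augments a signed correlation adjacency with shared-neighbour
#' correlation:
#' `w_ij = (sum_k a_ik a_kj + a_ij) / (min(k_i, k_j) + 1 - |a_ij|)`
#' with node strength `k_i = sum_{k != i} |a_ik|`. The numerator keeps
#' signs (so anti-correlated modules yield negative overlap) while the
#' denominator uses magnitudes; `w_ii = 1` by convention.
#'
#' @param a symmetric adjacency matrix with zero diagonal and entries in
#'   `[-1, 1]` (typically signed Pearson correlations).
#' @return symmetric wTO matrix `w` with unit diagonal.
#' @export
wto <- function(a) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  if (max(abs(a - t(a))) > 1e-9) stopf("adjacency must be symmetric")
  if (max(abs(diag(a))) > 1e-9) stopf("adjacency must have a zero diagonal")
  if (max(abs(a)) > 1 + 1e-9) stopf("adjacency entries must lie in [-1, 1]")
  diag(a) <- 0
  k <- rowSums(abs(a))
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - abs(a)
  w <- num / den
  diag(w) <- 1
  dimnames(w) <- dimnames(a)
  w
}

#' Threshold a wTO matrix into signed edges
#'
#' @param w symmetric wTO matrix.
#' @param tau absolute-overlap threshold; edges require `|w_ij| > tau`.
#'   The default 0.3 extracts the module backbone.
#' @return data.frame with columns source, target, w, sign
#'   (`"positive"`/`"negative"`), one row per unordered node pair.
#' @export
threshold_edges <- function(w, tau = 0.3) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  nodes <- rownames(w)
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(w)))
  pairs <- which(upper.tri(w) & abs(w) > tau, arr.ind = TRUE)
  data.frame(
    source = nodes[pairs[, 1L]],
    target = nodes[pairs[, 2L]],
    w = w[pairs],
    sign = ifelse(w[pairs] > 0, "positive", "negative"),
    row.names = NULL
  )
}

#' Spot wTO correlation network
#'
#' Builds the full network in one step: spot mean profiles, signed
#' Pearson adjacency across all samples, signed weighted topological
#' overlap, and the `|w| > tau` edge list split into positive and
#' negative correlations.
#'
#' @inheritParams spot_expression_profiles
#' @param tau edge threshold on `|w|` (default 0.3).
#' @return object of class `wto_network`: list with `profiles`,
#'   `adjacency`, `w`, `edges` and `tau`.
#' @export
wto_network <- function(x, spotmap, gene_to_unit, tau = 0.3) {
  profiles <- spot_expression_profiles(x, spotmap, gene_to_unit)
  if (nrow(profiles) < 2L) {
    a <- matrix(0, nrow(profiles), nrow(profiles),
                dimnames = list(rownames(profiles), rownames(profiles)))
  } else {
    a <- cor(t(profiles))
    a[!is.finite(a)] <- 0  # zero-variance profiles carry no correlation
    diag(a) <- 0
  }
  w <- wto(a)
  structure(
    list(profiles = profiles, adjacency = a, w = w,
         edges = threshold_edges(w, tau), tau = tau),
    class = "wto_network"
  )
}

#' @export
print.wto_network <- function(x, ...) {
  cat(sprintf("wto_network: %d node(s), %d edge(s) with |w| > %.2f (%d positive, %d negative)\n",
              nrow(x$profiles), nrow(x$edges), x$tau,
              sum(x$edges$sign == "positive"), sum(x$edges$sign == "negative")))
  invisible(x)
}
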