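.node_kinds <- c("gene", "compound", "input", "output")
.edge_types <- c("activation", "inhibition")

#' Construct a validated pathway graph
#'
#' Directed graph of gene and compound nodes connected by activation or
#' inhibition edges, optionally still carrying substrate-enzyme-product
#' reaction records prior to conversion (see
#' [reactions_to_relations()]).
#'
#' @param nodes data.frame with columns `id`, `kind` (gene, compound,
#'   input or output) and optionally a list column `genes` of member
#'   gene ids for gene nodes.
#' @param edges data.frame with columns `from`, `to`, `type`
#'   (activation/inhibition).
#' @param reactions optional data.frame with columns `substrate`,
#'   `enzyme`, `product`, `direction` (`"fwd"`/`"rev"`).
#' @return object of class `pathway_graph`.
#' @export
pathway_graph <- function(nodes, edges, reactions = NULL) {
  stopifnot(is.data.frame(nodes), all(c("id", "kind") %in% names(nodes)))
  if (anyDuplicated(nodes$id)) stopf("duplicate node ids")
  bad_kind <- setdiff(unique(nodes$kind), .node_kinds)
  if (length(bad_kind)) stopf("unknown node kind(s): %s", paste(bad_kind, collapse = ", "))
  if (is.null(nodes$genes)) nodes$genes <- vector("list", nrow(nodes))
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        type = character(0))
  }
  stopifnot(all(c("from", "to", "type") %in% names(edges)))
  bad_type <- setdiff(unique(edges$type), .edge_types)
  if (length(bad_type)) stopf("unknown edge type(s): %s", paste(bad_type, collapse = ", "))
  dangling <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
  if (length(dangling)) {
    stopf("edge endpoint(s) not declared as nodes: %s",
          paste(dangling, collapse = ", "))
  }
  if (!is.null(reactions)) {
    stopifnot(all(c("substrate", "enzyme", "product", "direction") %in%
                  names(reactions)))
    r_nodes <- unique(unlist(reactions[c("substrate", "enzyme", "product")]))
    missing <- setdiff(r_nodes, nodes$id)
    if (length(missing)) {
      stopf("reaction participant(s) not declared as nodes: %s",
            paste(missing, collapse = ", "))
    }
  }
  structure(list(nodes = nodes, edges = edges, reactions = reactions),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("pathway_graph: %d node(s), %d edge(s)%s%s\n",
              nrow(x$nodes), nrow(x$edges),
              if (!is.null(x$reactions)) sprintf(", %d reaction record(s)", nrow(x$reactions)) else "",
              if (pathway_is_acyclic(x)) ", acyclic" else ", cyclic"))
  invisible(x)
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(g$edges[c("from", "to")], directed = TRUE,
                                vertices = g$nodes$id)
}

#' Is the pathway graph acyclic?
#' @param g a `pathway_graph`.
#' @return logical scalar.
#' @export
pathway_is_acyclic <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  if (!nrow(g$edges)) return(TRUE)
  igraph::is_dag(as_igraph(g))
}

#' Read a pathway graph from its TSV serialization
#'
#' Line dialect (tab-separated):
#' \itemize{
#'   \item `node <id> <kind> [gene,gene,...]`
#'   \item `edge <src> <dst> <activation|inhibition>`
#'   \item `reaction <substrate> <enzyme> <product> <fwd|rev>`
#' }
#' The packaged fixture `tca_toy.tsv` encodes an eight-enzyme TCA-like
#' cycle (compounds Citrate, Isocitrate, 2-Oxoglutarate, Succinyl-CoA,
#' Succinate, Fumarate, Malate and Oxaloacetate alternating with their
#' enzymes) as 16 nodes and 16 activation edges.
#'
#' @param path path to the TSV file; defaults to the packaged fixture.
#' @return a `pathway_graph`.
#' @export
read_pathway_tsv <- function(path = system.file("extdata", "tca_toy.tsv",
                                                package = "epicart")) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  if (!any(keep)) stopf("'%s': empty pathway file", path)
  nodes <- list(); edges <- list(); reactions <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    rec <- f[1L]
    if (rec == "node") {
      if (length(f) < 3L) stopf("'%s' line %d: node needs id and kind", path, i)
      genes <- if (length(f) >= 4L && nzchar(f[4L])) {
        strsplit(f[4L], ",", fixed = TRUE)[[1L]]
      }
      nodes[[length(nodes) + 1L]] <- list(id = f[2L], kind = f[3L],
                                          genes = genes)
    } else if (rec == "edge") {
      if (length(f) < 4L) stopf("'%s' line %d: edge needs source, target, type", path, i)
      edges[[length(edges) + 1L]] <- data.frame(from = f[2L], to = f[3L],
                                                type = f[4L])
    } else if (rec == "reaction") {
      if (length(f) < 5L) {
        stopf("'%s' line %d: reaction needs substrate, enzyme, product, direction",
              path, i)
      }
      reactions[[length(reactions) + 1L]] <-
        data.frame(substrate = f[2L], enzyme = f[3L], product = f[4L],
                   direction = f[5L])
    } else {
      stopf("'%s' line %d: unknown record type '%s'", path, i, rec)
    }
  }
  if (!length(nodes)) stopf("'%s': no node records", path)
  node_df <- data.frame(id = vapply(nodes, `[[`, "", "id"),
                        kind = vapply(nodes, `[[`, "", "kind"))
  node_df$genes <- lapply(nodes, `[[`, "genes")
  pathway_graph(node_df,
                if (length(edges)) do.call(rbind, edges) else NULL,
                if (length(reactions)) do.call(rbind, reactions) else NULL)
}

#' Convert substrate-enzyme-product reactions to directed relations
#'
#' Each reaction record `(S, E, P)` becomes two one-directional
#' activation edges `S -> E` and `E -> P` (the KEGG "reaction" to
#' "relation" conversion); reaction records marked `rev` are oriented
#' against the written direction, i.e. `P -> E` and `E -> S`. Reaction
#' records are consumed.
#'
#' @param g a `pathway_graph` with reaction records.
#' @return a `pathway_graph` without reaction records.
#' @export
reactions_to_relations <- function(g) {
  stopifnot(inherits(g, "pathway_graph"))
  if (is.null(g$reactions) || !nrow(g$reactions)) {
    stopf("graph carries no reaction records")
  }
  bad <- setdiff(unique(g$reactions$direction), c("fwd", "rev"))
  if (length(bad)) {
    stopf("reaction(s) with undeclared orientation: direction must be 'fwd' or 'rev', got %s",
          paste(bad, collapse = ", "))
  }
  new_edges <- do.call(rbind, lapply(seq_len(nrow(g$reactions)), function(i) {
    r <- g$reactions[i, ]
    if (r$direction == "fwd") {
      data.frame(from = c(r$substrate, r$enzyme),
                 to = c(r$enzyme, r$product), type = "activation")
    } else {
      data.frame(from = c(r$product, r$enzyme),
                 to = c(r$enzyme, r$substrate), type = "activation")
    }
  }))
  edges <- unique(rbind(g$edges, new_edges))
  pathway_graph(g$nodes, edges, reactions = NULL)
}

#' Linearize a cyclic pathway by splitting one node
#'
#' Duplicates the node named `split_label` into `<label>__in` (kind
#' `input`, keeping the outgoing edges) and `<label>__out` (kind
#' `output`, keeping the incoming edges), the transformation that turns
#' a metabolic cycle such as the TCA cycle into a linear one-directional
#' chain with the split metabolite as both pathway input and final
#' output. The result must be acyclic; residual cycles are an error
#' naming the nodes involved.
#'
#' @param g a `pathway_graph`.
#' @param split_label node to split (classically "Oxaloacetate").
#' @return an acyclic `pathway_graph` with one node more than `g`.
#' @export
linearize_cycle <- function(g, split_label) {
  stopifnot(inherits(g, "pathway_graph"))
  if (!split_label %in% g$nodes$id) {
    stopf("split node '%s' not present in the graph", split_label)
  }
  in_id <- paste0(split_label, "__in")
  out_id <- paste0(split_label, "__out")
  nodes <- g$nodes[g$nodes$id != split_label, , drop = FALSE]
  orig <- g$nodes[g$nodes$id == split_label, , drop = FALSE]
  dup <- data.frame(id = c(in_id, out_id), kind = c("input", "output"))
  dup$genes <- rep(orig$genes, 2L)
  nodes <- rbind(nodes, dup)
  edges <- g$edges
  edges$from[edges$from == split_label] <- in_id
  edges$to[edges$to == split_label] <- out_id
  out <- pathway_graph(nodes, edges, g$reactions)
  if (!pathway_is_acyclic(out)) {
    ig <- as_igraph(out)
    ord <- tryCatch(igraph::topo_sort(ig), warning = function(w) NULL,
                    error = function(e) NULL)
    residual <- setdiff(out$nodes$id, names(ord))
    stopf("graph remains cyclic after splitting '%s'; residual cycle involves: %s",
          split_label, paste(residual, collapse = ", "))
  }
  out
}

#' Expression-derived node weights
#'
#' A gene node's weight is the linear-scale fold change
#' `10^(mean_target - mean_reference)` of the mean log10 expression of
#' its member genes between a target and a reference sample set; a
#' log10 difference of 1 therefore gives a weight of 10. Compound,
#' input and output nodes have no transcript and carry weight 1
#' (pass-through). Member genes absent from the matrix are dropped with
#' a warning; a gene node with no measured member falls back to
#' weight 1 with a warning.
#'
#' @param g a `pathway_graph`.
#' @param x gene x sample log10 expression matrix.
#' @param reference_samples,target_samples non-empty character vectors
#'   of sample ids in `x`.
#' @return named numeric vector node -> weight (positive, linear scale).
#' @export
node_weights <- function(g, x, reference_samples, target_samples) {
  stopifnot(inherits(g, "pathway_graph"))
  if (!length(reference_samples) || !length(target_samples)) {
    stopf("reference and target sample sets must be non-empty")
  }
  missing_s <- setdiff(c(reference_samples, target_samples), colnames(x))
  if (length(missing_s)) {
    stopf("sample(s) absent from the matrix: %s", paste(missing_s, collapse = ", "))
  }
  weights <- stats::setNames(rep(1, nrow(g$nodes)), g$nodes$id)
  for (i in seq_len(nrow(g$nodes))) {
    if (g$nodes$kind[i] != "gene") next
    members <- g$nodes$genes[[i]]
    present <- intersect(members, rownames(x))
    dropped <- setdiff(members, present)
    if (length(dropped)) {
      warnf("node '%s': dropping unmeasured member gene(s): %s",
            g$nodes$id[i], paste(dropped, collapse = ", "))
    }
    if (!length(present)) {
      warnf("node '%s': no measured member gene, using weight 1", g$nodes$id[i])
      next
    }
    m_ref <- mean(colMeans(x[present, reference_samples, drop = FALSE]))
    m_tgt <- mean(colMeans(x[present, target_samples, drop = FALSE]))
    weights[i] <- 10^(m_tgt - m_ref)
  }
  weights
}

#' Propagate Pathway Signal Flow through an acyclic pathway
#'
#' Nodes are processed in topological order. An input node's signal is
#' its own weight. Every other node receives one contribution per
#' incoming edge — the upstream signal for an activation edge, its
#' reciprocal for an inhibition edge — aggregates multiple contributions
#' (arithmetic mean by default) and multiplies by its own weight.
#' Signals are reported on the linear and the log10 scale.
#'
#' @param g an acyclic `pathway_graph` with at least one node without
#'   incoming edges.
#' @param weights named positive numeric vector node -> weight (see
#'   [node_weights()]).
#' @param aggregate how to combine multiple incoming contributions:
#'   `"mean"` (default), `"min"` or `"prod"`.
#' @return object of class `psf_result`: data.frame with columns node,
#'   kind, role (input/intermediate/output), weight, signal,
#'   log10_signal.
#' @export
propagate_psf <- function(g, weights, aggregate = c("mean", "min", "prod")) {
  stopifnot(inherits(g, "pathway_graph"))
  aggregate <- match.arg(aggregate)
  if (!pathway_is_acyclic(g)) stopf("PSF propagation needs an acyclic graph")
  missing_w <- setdiff(g$nodes$id, names(weights))
  if (length(missing_w)) {
    stopf("missing weight(s) for node(s): %s", paste(missing_w, collapse = ", "))
  }
  weights <- weights[g$nodes$id]
  if (any(!is.finite(weights) | weights <= 0)) {
    stopf("node weights must be positive and finite")
  }
  ids <- g$nodes$id
  has_in <- ids %in% g$edges$to
  has_out <- ids %in% g$edges$from
  if (!any(!has_in)) stopf("graph has no input node")
  role <- ifelse(!has_in, "input", ifelse(!has_out, "output", "intermediate"))
  ord <- if (nrow(g$edges)) {
    names(igraph::topo_sort(as_igraph(g), mode = "out"))
  } else ids
  agg_fun <- switch(aggregate, mean = mean, min = min, prod = prod)
  signal <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (v in ord) {
    inc <- g$edges[g$edges$to == v, , drop = FALSE]
    if (!nrow(inc)) {
      signal[v] <- weights[v]
    } else {
      contrib <- ifelse(inc$type == "activation",
                        signal[inc$from], 1 / signal[inc$from])
      signal[v] <- agg_fun(contrib) * weights[v]
    }
  }
  out <- data.frame(node = ids, kind = g$nodes$kind, role = role,
                    weight = unname(weights), signal = unname(signal[ids]),
                    log10_signal = unname(log10(signal[ids])),
                    row.names = NULL)
  class(out) <- c("psf_result", "data.frame")
  attr(out, "aggregate") <- aggregate
  out
}

#' One-step Pathway Signal Flow from expression data
#'
#' Convenience wrapper: linearizes the (possibly cyclic) pathway at
#' `split_label`, derives node weights from a class contrast and
#' propagates the signal.
#'
#' @inheritParams node_weights
#' @param split_label node at which to split the cycle; `NULL` to skip
#'   linearization for graphs that are already acyclic.
#' @param classes named character vector sample -> class.
#' @param reference,target class labels contrasted for the node
#'   weights (reference plays the role of the healthy control classes).
#' @param aggregate passed to [propagate_psf()].
#' @return a `psf_result`.
#' @export
psf <- function(g, x, classes, reference, target,
                split_label = "Oxaloacetate",
                aggregate = "mean") {
  if (!is.null(split_label)) g <- linearize_cycle(g, split_label)
  ref_s <- names(classes)[classes %in% reference]
  tgt_s <- names(classes)[classes %in% target]
  w <- node_weights(g, x, ref_s, tgt_s)
  propagate_psf(g, w, aggregate)
}
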