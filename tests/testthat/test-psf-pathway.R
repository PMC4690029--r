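chain_graph <- function(weights, kinds = NULL, types = NULL) {
  n <- length(weights)
  ids <- paste0("n", seq_len(n))
  if (is.null(kinds)) kinds <- c("input", rep("gene", n - 2), "output")
  nodes <- data.frame(id = ids, kind = kinds)
  edges <- data.frame(from = ids[-n], to = ids[-1],
                      type = if (is.null(types)) "activation" else types)
  g <- pathway_graph(nodes, edges)
  list(graph = g, weights = stats::setNames(weights, ids))
}

test_that("the packaged TCA-like fixture loads as a 16-node cycle", {
  g <- read_pathway_tsv()
  expect_equal(nrow(g$nodes), 16L)
  expect_equal(nrow(g$edges), 16L)
  expect_false(pathway_is_acyclic(g))
  expect_true(all(c("Oxaloacetate", "Citrate", "Isocitrate", "2-Oxoglutarate",
                    "Succinyl-CoA", "Succinate", "Fumarate", "Malate")
                  %in% g$nodes$id))
  expect_null(g$reactions)
  # exactly one cycle: removing any single edge makes it acyclic
  expect_true(pathway_is_acyclic(pathway_graph(g$nodes, g$edges[-1, ])))
})

test_that("pathway parsing rejects malformed files", {
  f <- tempfile()
  writeLines(character(0), f)
  expect_error(read_pathway_tsv(f), "empty")
  writeLines(c("node\tA\tcompound", "edge\tA\tB\tactivation"), f)
  expect_error(read_pathway_tsv(f), "B")
  writeLines(c("node\tA\tcompound", "wat\tA"), f)
  expect_error(read_pathway_tsv(f), "unknown record")
})

test_that("reactions convert to one-directional relations", {
  nodes <- data.frame(id = c("S", "E", "P"),
                      kind = c("compound", "gene", "compound"))
  rx <- data.frame(substrate = "S", enzyme = "E", product = "P",
                   direction = "fwd")
  g <- pathway_graph(nodes, NULL, rx)
  conv <- reactions_to_relations(g)
  expect_null(conv$reactions)
  expect_equal(nrow(conv$edges), 2L)
  expect_identical(conv$edges$from, c("S", "E"))
  expect_identical(conv$edges$to, c("E", "P"))
  expect_true(all(conv$edges$type == "activation"))

  # reversed reactions orient against the written direction
  rx$direction <- "rev"
  conv_r <- reactions_to_relations(pathway_graph(nodes, NULL, rx))
  expect_identical(conv_r$edges$from, c("P", "E"))
  rx$direction <- "both"
  expect_error(reactions_to_relations(pathway_graph(nodes, NULL, rx)),
               "orientation")
  expect_error(reactions_to_relations(conv), "no reaction")

  # an n-reaction cycle converts to 2n alternating edges
  n <- 5
  cyc <- data.frame(
    substrate = paste0("C", 1:n), enzyme = paste0("E", 1:n),
    product = paste0("C", c(2:n, 1)), direction = "fwd")
  nodes_c <- data.frame(id = c(paste0("C", 1:n), paste0("E", 1:n)),
                        kind = rep(c("compound", "gene"), each = n))
  conv_c <- reactions_to_relations(pathway_graph(nodes_c, NULL, cyc))
  expect_equal(nrow(conv_c$edges), 2L * n)
  expect_false(pathway_is_acyclic(conv_c))
})

test_that("splitting a cycle node yields an acyclic in/out pair", {
  nodes <- data.frame(id = c("A", "B", "C"), kind = "compound")
  edges <- data.frame(from = c("A", "B", "C"), to = c("B", "C", "A"),
                      type = "activation")
  g <- pathway_graph(nodes, edges)
  lin <- linearize_cycle(g, "A")
  expect_equal(nrow(lin$nodes), 4L)
  expect_true(pathway_is_acyclic(lin))
  expect_identical(sort(lin$nodes$id), c("A__in", "A__out", "B", "C"))
  kinds <- stats::setNames(lin$nodes$kind, lin$nodes$id)
  expect_identical(unname(kinds[c("A__in", "A__out")]), c("input", "output"))

  # splitting a node of an acyclic graph only duplicates it
  acy <- pathway_graph(nodes, edges[-3, ])
  lin2 <- linearize_cycle(acy, "A")
  expect_equal(nrow(lin2$nodes), 4L)
  expect_true(pathway_is_acyclic(lin2))

  expect_error(linearize_cycle(g, "Z"), "not present")
  # two interleaved cycles cannot be linearized by one split
  nodes2 <- data.frame(id = c("A", "B", "C", "D"), kind = "compound")
  edges2 <- data.frame(from = c("A", "B", "C", "B", "D"),
                       to = c("B", "C", "A", "D", "B"), type = "activation")
  expect_error(linearize_cycle(pathway_graph(nodes2, edges2), "A"),
               "residual cycle")
})

test_that("the TCA fixture linearizes to 17 topologically ordered nodes", {
  g <- linearize_cycle(read_pathway_tsv(), "Oxaloacetate")
  expect_equal(nrow(g$nodes), 17L)
  expect_true(pathway_is_acyclic(g))
  # a topological order exists and respects every edge
  ord <- names(igraph::topo_sort(igraph::graph_from_data_frame(
    g$edges[c("from", "to")], vertices = g$nodes$id)))
  pos <- match(g$edges$from, ord)
  expect_true(all(pos < match(g$edges$to, ord)))
})

test_that("node weights are linear-scale fold changes of member means", {
  toy <- generate_toy_pathway(3, split_label = "X", weights = c(1, 10, 2))
  ref <- names(toy$classes)[toy$classes == "reference"]
  tgt <- names(toy$classes)[toy$classes == "target"]
  w <- node_weights(toy$graph, toy$expr, ref, tgt)
  expect_equal(unname(w[c("Enz1", "Enz2", "Enz3")]), c(1, 10, 2),
               tolerance = 1e-12)
  # compounds are pass-through regardless of the matrix
  expect_true(all(w[toy$graph$nodes$id[toy$graph$nodes$kind == "compound"]] == 1))
  # a log10 difference of one means a ten-fold weight
  expect_equal(unname(w["Enz2"]), 10, tolerance = 1e-12)
  expect_error(node_weights(toy$graph, toy$expr, character(0), tgt),
               "non-empty")
  # unmeasured members fall back to weight 1 with a warning
  g2 <- toy$graph
  g2$nodes$genes[[4]] <- "ghost"
  expect_warning(
    expect_warning(w2 <- node_weights(g2, toy$expr, ref, tgt), "ghost"),
    "weight 1")
  expect_equal(unname(w2["Enz1"]), 1)
})

test_that("signal propagation follows the activation/inhibition rules", {
  # all-unit weights: every signal 1, log10 0
  toy <- generate_toy_pathway(4, split_label = "X", weights = rep(1, 4))
  res <- psf(toy$graph, toy$expr, toy$classes, "reference", "target",
             split_label = "X")
  expect_true(all(abs(res$signal - 1) < 1e-12))
  expect_true(all(abs(res$log10_signal) < 1e-12))

  # hand-propagated chain: input(1) -> enzyme(2) -> compound(1) -> enzyme(5)
  ch <- chain_graph(c(1, 2, 1, 5), kinds = c("input", "gene", "compound", "gene"))
  res2 <- propagate_psf(ch$graph, ch$weights)
  expect_equal(res2$signal, c(1, 2, 2, 10), tolerance = 1e-12)
  expect_equal(res2$log10_signal[4], 1, tolerance = 1e-12)
  expect_identical(res2$role, c("input", "intermediate", "intermediate",
                                "output"))

  # inhibition contributes the reciprocal of the upstream signal
  inh <- chain_graph(c(2, 4), kinds = c("input", "gene"), types = "inhibition")
  res3 <- propagate_psf(inh$graph, inh$weights)
  expect_equal(res3$signal[2], 4 / 2, tolerance = 1e-12)

  expect_error(propagate_psf(chain_graph(c(1, -1))$graph,
                             stats::setNames(c(1, -1), c("n1", "n2"))),
               "positive")
  toy2 <- generate_toy_pathway(2, split_label = "Y")
  expect_error(propagate_psf(toy2$graph,
                             stats::setNames(rep(1, 4), toy2$graph$nodes$id)),
               "acyclic")
})

test_that("chain signals equal the product of weights along the path", {
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(3:8, 1)
      w <- 10^runif(n, -1, 1)
      ch <- chain_graph(w)
      res <- propagate_psf(ch$graph, ch$weights)
      expect_equal(res$signal, cumprod(w), tolerance = 1e-9)
      # duality: inverting all weights inverts all signals
      inv <- propagate_psf(ch$graph, 1 / ch$weights)
      expect_equal(inv$signal, 1 / res$signal, tolerance = 1e-9)
      expect_equal(inv$log10_signal, -res$log10_signal, tolerance = 1e-9)
    }
  })
})

test_that("raising one weight never decreases downstream activation signals", {
  withr::with_seed(17, {
    toy <- generate_toy_pathway(6, split_label = "X",
                                weights = 10^runif(6, -0.5, 0.5))
  })
  lin <- linearize_cycle(toy$graph, "X")
  ref <- names(toy$classes)[toy$classes == "reference"]
  tgt <- names(toy$classes)[toy$classes == "target"]
  w <- node_weights(lin, toy$expr, ref, tgt)
  base <- propagate_psf(lin, w)
  w2 <- w; w2["Enz3"] <- w2["Enz3"] * 5
  up <- propagate_psf(lin, w2)
  expect_true(all(up$signal >= base$signal - 1e-12))
})

test_that("PSF output tracks the class with planted enzyme overexpression", {
  # enzymes of the cycle all up in class X relative to the reference
  design <- cohort_design(
    40, c(Ctrl = 6, X = 6),
    modules = list(planted_module("ENZ", 8, "X", effect = 0.5,
                                  genes = paste0("Enz", 1:8))),
    noise_sd = 0.1, baseline = 1, seed = 5)
  co <- generate_cohort(design)
  toy <- generate_toy_pathway(8, split_label = "Oxaloacetate")
  per_class <- vapply(c("Ctrl", "X"), function(cl) {
    res <- psf(toy$graph, co$expr, co$classes, reference = "Ctrl",
               target = cl, split_label = "Oxaloacetate")
    res$log10_signal[res$role == "output"]
  }, 0)
  expect_identical(names(which.max(per_class)), "X")
  # eight enzymes each ~0.5 log10 up: output near 4 on the log10 scale
  expect_equal(unname(per_class["X"]), 4, tolerance = 0.5)
})
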