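test_that("overexpression marking follows the type-1 quantile rule", {
  p <- matrix(1:100, 10, 10, byrow = TRUE)
  class(p) <- c("portrait", "matrix"); attr(p, "sample_id") <- "s"
  ov <- overexpression_summary_map(list(p), q = 0.98)
  expect_equal(sum(ov$binary), 3L)  # values 98, 99, 100
  ov2 <- overexpression_summary_map(list(p), q = 1e-9)
  expect_true(all(ov2$binary))
  cst <- p; cst[] <- 7
  expect_true(all(overexpression_summary_map(list(cst), q = 0.98)$binary))
  expect_error(overexpression_summary_map(list(p), q = 1), "between 0 and 1")
  expect_error(overexpression_summary_map(list()), "at least one")
})

test_that("summary map records the fraction of marking portraits", {
  a <- matrix(c(10, 0, 0, 0), 2, 2)
  b <- matrix(c(0, 11, 0, 0), 2, 2)
  ov <- overexpression_summary_map(list(a, b), q = 0.8)
  # each portrait marks only its own top unit; fractions are 1/2 there
  expect_equal(ov$summary[1, 1], 0.5)
  expect_equal(ov$summary[2, 1], 0.5)
  expect_identical(sum(ov$binary), 2L)
})

test_that("spot detection matches a flood-fill oracle with 8-connectivity", {
  flood_oracle <- function(binary) {
    # independent recursive flood fill
    lab <- matrix(0L, nrow(binary), ncol(binary)); cur <- 0L
    fill <- function(r, c) {
      if (r < 1 || c < 1 || r > nrow(binary) || c > ncol(binary)) return()
      if (!binary[r, c] || lab[r, c] != 0L) return()
      lab[r, c] <<- cur
      for (dr in -1:1) for (dc in -1:1) if (dr || dc) fill(r + dr, c + dc)
    }
    for (r in seq_len(nrow(binary))) for (c in seq_len(ncol(binary)))
      if (binary[r, c] && lab[r, c] == 0L) { cur <- cur + 1L; fill(r, c) }
    lab
  }

  # two separated 3x3 blocks
  b <- matrix(FALSE, 10, 10)
  b[1:3, 1:3] <- TRUE; b[6:8, 6:8] <- TRUE
  sm <- detect_spots(b, min_size = 4)
  expect_equal(nrow(sm$spots), 2L)
  expect_true(all(sm$spots$size == 9L))
  expect_identical(sm$spots$label, c("A", "B"))

  # single marked unit falls below min_size
  b1 <- matrix(FALSE, 5, 5); b1[3, 3] <- TRUE
  expect_equal(nrow(detect_spots(b1, min_size = 4)$spots), 0L)

  # a diagonal chain is one spot under 8-connectivity
  bd <- matrix(FALSE, 6, 6); for (i in 1:6) bd[i, i] <- TRUE
  smd <- detect_spots(bd, min_size = 4)
  expect_equal(nrow(smd$spots), 1L)
  expect_equal(smd$spots$size, 6L)

  # random grids agree with the oracle in component count and membership
  withr::with_seed(99, {
    for (rep in 1:10) {
      br <- matrix(runif(64) < 0.35, 8, 8)
      oracle <- flood_oracle(br)
      sm <- detect_spots(br, min_size = 1)
      expect_equal(nrow(sm$spots), max(oracle))
      # same partition: matched component sizes
      expect_identical(sort(sm$spots$size),
                       sort(as.integer(table(oracle[oracle > 0]))))
    }
  })
})

test_that("spots are disjoint, connected, and ranked by peak", {
  fit <- default_fit()
  sm <- fit$spotmap
  lab <- sm$unit_label
  expect_true(all(table(lab[!is.na(lab)]) >= 4))
  expect_true(all(diff(sm$spots$peak) <= 0))
  # each spot is a single 8-connected component
  for (lb in sm$spots$label) {
    b <- matrix(FALSE, sm$n_rows, sm$n_cols)
    units <- which(lab == lb)
    b[cbind((units - 1) %/% sm$n_cols + 1, (units - 1) %% sm$n_cols + 1)] <- TRUE
    expect_equal(nrow(detect_spots(b, min_size = 1)$spots), 1L)
  }
})

test_that("map segmentation partitions the grid with a centred zone", {
  seg <- segment_map(6, 6, central_fraction = 1 / 3)
  counts <- table(seg)
  expect_equal(unname(counts["Z"]), 4L)
  expect_true(all(counts[c("Q1", "Q2", "Q3", "Q4")] == 8L))
  # Z is the central 2x2 of the 6x6 grid (row-major units)
  z_units <- which(seg == "Z")
  expect_identical(z_units, c(15L, 16L, 21L, 22L))
  # Q1 is top-left
  expect_identical(as.vector(seg[1]), "Q1")
  expect_identical(as.vector(seg[6]), "Q2")
  expect_identical(as.vector(seg[36]), "Q3")
  expect_identical(as.vector(seg[31]), "Q4")

  # the regions always partition the grid, whatever the geometry
  for (dims in list(c(2, 2), c(5, 7), c(20, 20), c(9, 4))) {
    for (cf in c(0.05, 1 / 3, 0.6, 0.95)) {
      s <- segment_map(dims[1], dims[2], cf)
      expect_length(s, dims[1] * dims[2])
      expect_true(all(s %in% c("Q1", "Q2", "Q3", "Q4", "Z")))
    }
  }
  expect_error(segment_map(1, 6, 0.3), "2 x 2")
  expect_error(segment_map(6, 6, 0), "strictly between")
})

test_that("region counts match a brute-force tally and sum to n_genes", {
  seg <- segment_map(6, 6, 1 / 3)
  withr::with_seed(5, {
    g2u <- stats::setNames(sample.int(36, 100, replace = TRUE),
                           paste0("g", 1:100))
    annotated <- sample(names(g2u), 30)
  })
  counts <- count_by_region(g2u, seg, annotated)
  expect_equal(sum(counts$n_genes), 100L)
  expect_equal(sum(counts$n_annotated), 30L)
  for (r in counts$region) {
    in_r <- names(g2u)[seg[g2u] == r]
    expect_equal(counts$n_genes[counts$region == r], length(in_r))
    expect_equal(counts$n_annotated[counts$region == r],
                 length(intersect(in_r, annotated)))
  }
  # all genes on one unit
  one <- stats::setNames(rep(1L, 12), paste0("h", 1:12))
  c1 <- count_by_region(one, seg)
  expect_equal(c1$n_genes[c1$region == "Q1"], 12L)
  expect_equal(sum(c1$n_genes), 12L)
  expect_true(all(c1$n_annotated == 0L))
  # unknown annotated genes are dropped with a warning
  expect_warning(count_by_region(one, seg, c("h1", "ghost")), "ghost")
  # invariant units divert genes to the Inv region
  ci <- count_by_region(one, seg, invariant_units = 1L)
  expect_equal(ci$n_genes[ci$region == "Inv"], 12L)
  expect_equal(sum(ci$n_genes), 12L)
})

test_that("fisher enrichment reproduces exact hypergeometric examples", {
  # all four annotated genes inside a 4-gene region of an 8-gene universe
  e <- fisher_enrichment(4, 4, 4, 8)
  expect_equal(e$p_value, 1 / 70, tolerance = 1e-12)
  expect_identical(e$direction, "greater")
  expect_true(is.infinite(e$odds_ratio))
  # overlap at expectation in a tiny table
  expect_equal(fisher_enrichment(1, 2, 2, 4)$p_value, 5 / 6, tolerance = 1e-12)
  # annotated set equal to the universe: certain event
  expect_equal(fisher_enrichment(3, 3, 6, 6)$p_value, 1)
  expect_error(fisher_enrichment(5, 4, 4, 8), "inconsistent")
  # agrees with stats::fisher.test as an independent cross-check
  ft <- stats::fisher.test(matrix(c(7, 3, 12, 78), 2), alternative = "greater")
  expect_equal(fisher_enrichment(7, 19, 10, 100)$p_value, ft$p.value,
               tolerance = 1e-10)
})

test_that("variance map flags invariant units", {
  cb <- rbind(c(0, 0), c(-1, 1))
  grid <- structure(list(codebook = cb, n_rows = 2L, n_cols = 1L),
                    class = "som_grid")
  v <- variance_map(grid)
  expect_equal(as.vector(v), c(0, 1))  # population variance
  expect_identical(invariant_units(v, q = 0.5), 1L)
  expect_identical(invariant_units(v, q = 1), c(1L, 2L))
  # constant codebook: everything invariant
  gridc <- structure(list(codebook = matrix(3, 4, 5), n_rows = 2L,
                          n_cols = 2L), class = "som_grid")
  expect_true(all(variance_map(gridc) == 0))
})

test_that("spots associate with the classes that overexpress them", {
  fit <- default_fit()
  sc <- spot_classes(fit$spotmap, fit$grid, fit$cohort$classes)
  mods <- module_gene_sets(fit$cohort)
  sg <- spot_genes(fit$spotmap, fit$grid$gene_to_unit)
  # the spot recovering module M1 must be associated with M1's up-class
  up <- fit$cohort$design$modules[[1]]$up_classes
  best <- names(which.max(vapply(sg, function(s)
    length(intersect(s, mods$M1)) / length(union(s, mods$M1)), 0)))
  expect_true(up %in% sc[[best]])
})
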