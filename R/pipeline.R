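#' Default pipeline configuration
#'
#' A self-contained synthetic run: the default five-class cohort with
#' four planted 50-gene modules, plus a small planted "TCA enzyme"
#' module whose genes are the member genes of the packaged toy TCA
#' pathway (overexpressed in the first class), so the PSF stage has
#' measured enzymes to work with.
#'
#' @param seed master seed for all pipeline randomness.
#' @param out_dir output directory.
#' @return a named list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1, out_dir = "epicart_run") {
  list(
    simulate = TRUE,
    tca_module = TRUE,
    seed = seed,
    out_dir = out_dir,
    n_rows = 20, n_cols = 20, epochs = 20,
    quantile = 0.98, min_spot_size = 4, min_portrait_fraction = 0.1,
    central_fraction = 1 / 3,
    s0_rule = "median", tau = 0.3,
    pathway = system.file("extdata", "tca_toy.tsv", package = "epicart"),
    split_node = "Oxaloacetate",
    psf_target = "BL", psf_reference = "MM",
    contrast = c("BL", "MM")
  )
}

pathway_member_genes <- function(g) {
  unique(unlist(g$nodes$genes[g$nodes$kind == "gene"]))
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or a YAML path")
  defaults <- default_pipeline_config()
  defaults$simulate <- NULL
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  has_files <- !is.null(config$matrix) && !is.null(config$classes)
  if (is.null(config$simulate)) config$simulate <- !has_files
  if (!config$simulate && !has_files) {
    stopf("config must either set simulate = TRUE or provide matrix and classes paths")
  }
  if (!config$simulate) {
    for (p in c(config$matrix, config$classes)) {
      if (!file.exists(p)) stopf("input file not found: %s", p)
    }
  }
  if (config$quantile <= 0 || config$quantile >= 1) stopf("quantile out of (0,1)")
  if (config$central_fraction <= 0 || config$central_fraction >= 1) {
    stopf("central_fraction out of (0,1)")
  }
  config
}

stage_msg <- function(stage, t0) {
  message(sprintf("[epicart] %-10s done in %.1fs", stage,
                  as.numeric(proc.time()[3L]) - t0))
}

#' Run the full expression-cartography pipeline
#'
#' Executes simulate (or load) -> centre -> SOM training -> spot
#' detection and segmentation -> region counts and enrichment ->
#' shrinkage-t differential expression -> wTO spot network -> PSF, and
#' writes every stage's tables plus a machine-readable `report.json`
#' and a `provenance.yaml` into the output directory. All randomness
#' derives from the single config seed, so a fixed config yields a
#' byte-identical report.
#'
#' @param config named list or path to a YAML file; see
#'   [default_pipeline_config()] for the recognised fields. File-based
#'   runs set `matrix`/`classes` (TSV paths) instead of
#'   `simulate = TRUE`.
#' @return invisibly, the report as a named list.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  config <- read_pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  t0 <- as.numeric(proc.time()[3L])

  ## stage: input ------------------------------------------------------
  truth <- NULL
  if (isTRUE(config$simulate)) {
    design <- if (!is.null(config$design)) config$design else {
      d <- default_cohort_design(seed = derive_seed(config$seed, "cohort"))
      if (isTRUE(config$tca_module)) {
        pw <- read_pathway_tsv(config$pathway)
        enz <- pathway_member_genes(pw)
        d$modules <- c(d$modules,
                       list(planted_module("TCA", length(enz),
                                           config$psf_target, effect = 1.0,
                                           genes = enz)))
        d <- cohort_design(d$n_genes, d$classes, d$modules,
                           noise_sd = d$noise_sd, baseline = d$baseline,
                           seed = d$seed)
      }
      d
    }
    cohort <- generate_cohort(design)
    x_raw <- cohort$expr
    classes <- cohort$classes
    truth <- cohort$truth
    write_expression_tsv(x_raw, file.path(out_dir, "expr.tsv"))
    write_classes_tsv(classes, file.path(out_dir, "classes.tsv"))
    truth_df <- data.frame(gene = names(truth$module_of_gene),
                           module = unname(truth$module_of_gene))
    write.table(truth_df, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    x_raw <- read_expression_tsv(config$matrix)
    classes <- check_classes(read_classes_tsv(config$classes), x_raw)
  }
  stage_msg("input", t0); t0 <- as.numeric(proc.time()[3L])

  ## stage: centre + SOM ----------------------------------------------
  x <- center_genes(x_raw)
  grid <- train_som(x, n_rows = config$n_rows, n_cols = config$n_cols,
                    epochs = config$epochs,
                    seed = derive_seed(config$seed, "som"))
  write_expression_tsv(grid$codebook, file.path(out_dir, "metagenes.tsv"))
  g2u <- data.frame(gene = names(grid$gene_to_unit),
                    unit = unname(grid$gene_to_unit))
  write.table(g2u, file.path(out_dir, "gene_to_unit.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  stage_msg("som", t0); t0 <- as.numeric(proc.time()[3L])

  ## stage: spots ------------------------------------------------------
  portraits <- all_portraits(grid)
  ov <- overexpression_summary_map(portraits, q = config$quantile)
  # spots must recur across samples: keep units overexpressed in at least
  # min_portrait_fraction of the portraits, not one-off noise marks
  recurrent <- ov$binary & (ov$summary >= config$min_portrait_fraction)
  spotmap <- detect_spots(recurrent, ov$summary,
                          min_size = config$min_spot_size)
  sclasses <- spot_classes(spotmap, grid, classes)
  spot_tab <- spotmap$spots
  spot_tab$classes <- vapply(sclasses[spot_tab$label], paste,
                             "", collapse = ",")
  write.table(spot_tab, file.path(out_dir, "spots.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  seg <- segment_map(config$n_rows, config$n_cols, config$central_fraction)
  vmap <- variance_map(grid)
  inv_units <- invariant_units(vmap, q = 0.25)
  annotated <- if (!is.null(config$annotation)) {
    read_annotation_tsv(config$annotation)$symbol
  } else if (!is.null(truth)) {
    # synthetic runs: the planted module genes play the role of the
    # annotated gene group
    names(truth$module_of_gene)[!is.na(truth$module_of_gene)]
  } else character(0)
  annotated <- intersect(annotated, names(grid$gene_to_unit))
  region_counts <- count_by_region(grid$gene_to_unit, seg, annotated,
                                   invariant_units = inv_units)
  write.table(region_counts, file.path(out_dir, "region_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  in_spot_units <- which(!is.na(spotmap$unit_label))
  genes_in_spots <- names(grid$gene_to_unit)[grid$gene_to_unit %in% in_spot_units]
  enr <- fisher_enrichment(length(intersect(annotated, genes_in_spots)),
                           length(genes_in_spots), length(annotated),
                           length(grid$gene_to_unit))
  stage_msg("spots", t0); t0 <- as.numeric(proc.time()[3L])

  ## stage: differential expression ------------------------------------
  class_a <- config$contrast[1L]; class_b <- config$contrast[2L]
  dex <- shrinkage_t(x, classes, class_a, class_b, s0_rule = config$s0_rule)
  write.table(dex[c("gene", "d", "s", "t", "p", "fdr")],
              file.path(out_dir, "dex.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  have_spots <- nrow(spotmap$spots) > 0L
  sdex <- if (have_spots) {
    spot_t(x, classes, spotmap, grid$gene_to_unit, class_a, class_b,
           s0_rule = config$s0_rule)
  } else {
    warnf("no spot passed the size filter; spot-level statistics skipped")
    data.frame(gene = character(0), d = numeric(0), t = numeric(0),
               p = numeric(0))
  }
  stage_msg("dex", t0); t0 <- as.numeric(proc.time()[3L])

  ## stage: network -----------------------------------------------------
  net <- if (have_spots) {
    wto_network(x, spotmap, grid$gene_to_unit, tau = config$tau)
  } else {
    list(edges = data.frame(source = character(0), target = character(0),
                            w = numeric(0), sign = character(0)))
  }
  write.table(net$edges, file.path(out_dir, "network.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  stage_msg("network", t0); t0 <- as.numeric(proc.time()[3L])

  ## stage: PSF ---------------------------------------------------------
  psf_tab <- NULL
  if (!is.null(config$pathway) && nzchar(config$pathway)) {
    pw <- read_pathway_tsv(config$pathway)
    psf_tab <- suppressWarnings(
      psf(pw, x_raw, classes, reference = config$psf_reference,
          target = config$psf_target, split_label = config$split_node)
    )
    write.table(psf_tab, file.path(out_dir, "psf.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  stage_msg("psf", t0)

  ## report -------------------------------------------------------------
  mte <- mean_total_expression(portraits)
  mte_class <- tapply(mte[names(classes)], classes, mean)
  report <- list(
    n_spots = nrow(spotmap$spots),
    spots = spot_tab,
    region_counts = region_counts,
    enrichment = list(p_value = enr$p_value, odds_ratio = enr$odds_ratio,
                      n_overlap = enr$contingency[1L, 1L],
                      n_in_spots = length(genes_in_spots),
                      n_annotated = length(annotated),
                      n_universe = length(grid$gene_to_unit)),
    mean_total_expression_by_class = as.list(mte_class),
    contrast = list(class_a = class_a, class_b = class_b,
                    n_significant_fdr05 = sum(dex$fdr < 0.05),
                    spot_t = sdex[c("gene", "d", "t", "p")]),
    network = list(n_edges = nrow(net$edges),
                   n_positive = sum(net$edges$sign == "positive"),
                   n_negative = sum(net$edges$sign == "negative")),
    psf = if (!is.null(psf_tab))
      psf_tab[c("node", "kind", "role", "weight", "signal", "log10_signal")]
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  prov <- list(
    package = "epicart",
    version = as.character(utils::packageVersion("epicart")),
    seed = config$seed,
    parameters = config[setdiff(names(config), c("design", "out_dir"))],
    conventions = list(
      unit_indexing = "row-major, 1-based, unit 1 top-left",
      quadrants = "Q1 top-left, Q2 top-right, Q3 bottom-right, Q4 bottom-left",
      quantile_type = "type-1 (inverse CDF), ties at the cut included",
      shrinkage = "additive fudge s0, pooled-variance t",
      wto = "signed numerator, magnitude node strength",
      psf_rule = "activation multiplies, inhibition reciprocal, mean aggregation"
    )
  )
  yaml::write_yaml(prov, file.path(out_dir, "provenance.yaml"))
  invisible(report)
}
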