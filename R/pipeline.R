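#' Default analysis-stage parameters for the pipeline
#'
#' Thresholds mirror the analysis conventions the package implements: 20%
#' within-group prevalence with 2.5% summed relative abundance for the
#' feature filter, 0.1%/1% abundance-class cuts, tau = 0.7 for
#' specificity-occupancy key calling, |rho| >= 0.6 with BH q < 0.05 for
#' co-occurrence edges, |log2FC| > 1 with p < 0.05 for genes, FDR < 0.05 for
#' taxa, and rho > 0.8 with p < 0.01 for taxon-gene links.
#'
#' @param ... Named overrides.
#' @return Named list of stage parameters.
#' @export
pipeline_params <- function(...) {
  par <- list(
    min_group_prevalence = 0.20,
    min_total_relabund = 0.025,
    rare_cut = 0.001,
    abundant_cut = 0.01,
    spec_occ_tau = 0.7,
    indicator_alpha = 0.05,
    n_permutations = 999,
    rho_min = 0.6,
    network_alpha = 0.05,
    network_correction = "bh",
    per_group_networks = TRUE,
    lfc_min = 1,
    de_alpha = 0.05,
    fdr_alpha = 0.05,
    omics_r_min = 0.8,
    omics_alpha = 0.01,
    trait_r_min = 0.05,
    trait_alpha = 0.05,
    procrustes_axes = 2)
  over <- list(...)
  for (i in seq_along(over)) par[[names(over)[i]]] <- over[[i]]
  par
}

#' Run the full synthetic-study analysis pipeline
#'
#' Orchestrates synthesize -> partition -> diversity/ordination ->
#' indicators/spec-occ -> co-occurrence networks -> differential features ->
#' Procrustes -> multi-omics network from one configuration and one global
#' seed (expanded deterministically into per-stage seeds), and returns a
#' machine-readable report. With an \code{outdir}, stage tables, the truth
#' record and the JSON report are written to disk.
#'
#' The taxa carried into the multi-omics network are the union of the
#' specificity-occupancy key species, the significant indicator taxa and the
#' network keystone nodes; the genes are the significant differential genes
#' together with genes passing the trait-correlation screen
#' (p < trait_alpha and |r| > trait_r_min).
#'
#' @param config Synthetic-study configuration from \code{\link{synth_config}}.
#' @param seed Global integer seed.
#' @param outdir Optional output directory.
#' @param params Stage parameters from \code{\link{pipeline_params}}.
#' @return Named list (the run report).
#' @export
run_pipeline <- function(config = synth_config(), seed = 1L, outdir = NULL,
                         params = pipeline_params()) {
  stage_seed <- function(k) as.integer(seed + 101L * k)

  comm <- generate_community(config, seed = stage_seed(0))
  expr <- generate_expression(comm$truth, config, seed = stage_seed(1))
  trt <- generate_traits(expr$truth, config, seed = stage_seed(2))
  truth <- trt$truth
  counts <- comm$counts
  meta <- comm$metadata
  genes <- expr$counts
  traits <- trt$traits

  rel <- to_relative_abundance(counts)
  classes <- classify_abundance(rel, params$rare_cut, params$abundant_cut)
  rel_f <- prevalence_filter(rel, meta, params$min_group_prevalence,
                             params$min_total_relabund)

  div <- alpha_diversity(counts)
  d <- bray_curtis(rel_f)
  ord <- pcoa(d)
  perma <- permanova(d, meta, n_permutations = params$n_permutations,
                     seed = stage_seed(3))

  ind <- indicator_analysis(rel_f, meta, n_permutations = params$n_permutations,
                            alpha = params$indicator_alpha,
                            seed = stage_seed(4))
  so <- specificity_occupancy(rel_f, meta, tau = params$spec_occ_tau)

  cls_f <- classes[classes$feature_id %in% rownames(rel_f),
                   c("feature_id", "class")]
  sm <- spearman_matrix(rel_f)
  net <- build_network(sm$rho, sm$p, rho_min = params$rho_min,
                       alpha = params$network_alpha,
                       correction = params$network_correction,
                       node_attributes = cls_f)
  net <- node_centralities(net)
  net <- detect_modules(net, seed = stage_seed(5))
  keys <- keystone_nodes(net)

  group_networks <- NULL
  if (isTRUE(params$per_group_networks)) {
    group_networks <- lapply(levels(meta$group), function(g) {
      idx <- meta$sample_id[meta$group == g]
      smg <- spearman_matrix(rel_f[, idx, drop = FALSE])
      ng <- build_network(smg$rho, smg$p, rho_min = params$rho_min,
                          alpha = params$network_alpha,
                          correction = params$network_correction,
                          node_attributes = cls_f)
      ng <- node_centralities(ng)
      keystone_nodes(ng)$per_metric
    })
    names(group_networks) <- levels(meta$group)
  }

  de_pair <- config$de_pair
  de_taxa <- differential_test(counts, meta, de_pair, method = "nb_exact",
                               fdr_alpha = params$fdr_alpha,
                               mode = "microbiome", seed = stage_seed(6))
  de_genes <- differential_test(genes, meta, de_pair, method = "nb_exact",
                                lfc_min = params$lfc_min,
                                alpha = params$de_alpha, mode = "gene",
                                seed = stage_seed(7))

  gene_cpm <- normalized_cpm(genes, tmm_factors(genes))
  ord_genes <- pca_ordination(log2(gene_cpm))
  proc <- procrustes_test(ord, ord_genes, n_axes = params$procrustes_axes,
                          n_permutations = params$n_permutations,
                          seed = stage_seed(8))

  key_taxa <- sort(unique(c(so$feature_id[so$key],
                            ind$feature_id[ind$significant],
                            unlist(keys$per_metric))))
  gene_trait <- trait_feature_correlation(log2(gene_cpm), traits,
                                          cor_min = params$trait_r_min,
                                          alpha = params$trait_alpha)
  sel_genes <- sort(unique(c(de_genes$feature_id[de_genes$significant],
                             gene_trait$feature_id[gene_trait$pass])))
  if (!length(sel_genes))
    sel_genes <- de_genes$feature_id[order(de_genes$p)][seq_len(min(20L, nrow(de_genes)))]
  onet <- omics_network(rel[key_taxa, , drop = FALSE],
                        log2(gene_cpm[sel_genes, , drop = FALSE]),
                        traits,
                        r_min = params$omics_r_min, alpha = params$omics_alpha,
                        trait_r_min = params$trait_r_min,
                        trait_alpha = params$trait_alpha)

  report <- list(
    seed = seed,
    params = params,
    design = as.list(truth$group_design),
    n_features = nrow(counts),
    n_features_filtered = nrow(rel_f),
    abundance_class_counts = as.list(table(classes$class)),
    alpha_diversity = list(mean_observed = mean(div$observed),
                           mean_shannon = mean(div$shannon)),
    permanova = list(pseudo_F = perma$pseudo_F, R2 = perma$R2, p = perma$p),
    pcoa_percent_axis1 = 100 * ord$proportion_explained[1],
    pcoa_percent_axis2 = 100 * ord$proportion_explained[2],
    n_indicator_taxa = sum(ind$significant),
    n_key_species_calls = sum(so$key),
    keystone_nodes = keys$per_metric,
    keystone_nodes_per_group = group_networks,
    network = list(n_nodes = nrow(net$nodes), n_edges = nrow(net$edges),
                   n_modules = length(unique(net$nodes$module))),
    differential = list(
      pair = de_pair,
      n_significant_taxa = sum(de_taxa$significant),
      n_significant_genes = sum(de_genes$significant)),
    procrustes = list(m2 = proc$m2, t = proc$t_stat, p = proc$p),
    omics_network_edges = as.list(table(factor(onet$edges$type,
      levels = c("taxon-gene", "taxon-trait", "gene-trait")))))

  result <- list(report = report, truth = truth, counts = counts, meta = meta,
                 genes = genes, traits = traits, rel_filtered = rel_f,
                 classes = classes, diversity = div, ordination = ord,
                 permanova = perma, indicators = ind, spec_occ = so,
                 network = net, keystones = keys, de_taxa = de_taxa,
                 de_genes = de_genes, procrustes = proc, omics = onet,
                 gene_trait = gene_trait, key_taxa = key_taxa,
                 selected_genes = sel_genes)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_count_table(counts, file.path(outdir, "counts.tsv"))
    write_count_table(genes, file.path(outdir, "genes.tsv"), "gene_id")
    utils::write.table(meta, file.path(outdir, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_traits(traits, file.path(outdir, "traits.tsv"))
    utils::write.table(classes, file.path(outdir, "classes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(ind, file.path(outdir, "indicators.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(so, file.path(outdir, "spec_occ.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_network(net, file.path(outdir, "network_edges.tsv"), "edge_list_tsv")
    write_network(net, file.path(outdir, "network.graphml"), "graphml")
    utils::write.table(de_genes, file.path(outdir, "de_genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(de_taxa, file.path(outdir, "de_taxa.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_truth(truth, file.path(outdir, "truth.json"))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(result)
}
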