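#' Planted-structure recovery study
#'
#' Repeatedly synthesises the default study (community, expression, traits),
#' runs the analysis stages, and scores recovery of every planted structure:
#' indicator taxa (significant, with the planted group in the best
#' combination), specificity-occupancy key species (key in the planted
#' group), the hub as degree-argmax keystone of the pooled co-occurrence
#' network, planted differential genes (significant in gene mode),
#' taxon-gene couplings (rho > 0.8, p < 0.01 edge present), and the full
#' hub -> key set -> coupled gene -> trait chain.
#'
#' @param n_seeds Number of independent replicates.
#' @param config Generator configuration.
#' @param seed Base seed; replicate seeds are derived deterministically.
#' @param params Analysis-stage parameters.
#' @param n_permutations Permutations used in the indicator analysis.
#' @return data.frame with one row per replicate and columns
#'   \code{indicator_sensitivity}, \code{specocc_sensitivity},
#'   \code{hub_degree_argmax}, \code{de_sensitivity}, \code{coupling_rate},
#'   \code{chain_recovered}; replicate means are the study's summary.
#' @export
recovery_study <- function(n_seeds = 50, config = synth_config(), seed = 1,
                           params = pipeline_params(),
                           n_permutations = 999) {
  rows <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    base <- seed + 1000L * s
    comm <- generate_community(config, seed = base)
    expr <- generate_expression(comm$truth, config, seed = base + 1L)
    trt <- generate_traits(expr$truth, config, seed = base + 2L)
    truth <- trt$truth
    meta <- comm$metadata
    rel <- to_relative_abundance(comm$counts)
    rel_f <- prevalence_filter(rel, meta, params$min_group_prevalence,
                               params$min_total_relabund)

    ind <- indicator_analysis(rel_f, meta, n_permutations = n_permutations,
                              alpha = params$indicator_alpha, seed = base + 3L)
    hit_ind <- vapply(seq_len(nrow(truth$indicator_map)), function(i) {
      f <- truth$indicator_map$feature_id[i]
      row <- ind[ind$feature_id == f, ]
      nrow(row) == 1 && row$significant &&
        truth$indicator_map$group[i] %in%
          strsplit(row$group_combination, "+", fixed = TRUE)[[1]]
    }, logical(1))

    so <- specificity_occupancy(rel_f, meta, tau = params$spec_occ_tau)
    hit_so <- vapply(seq_len(nrow(truth$indicator_map)), function(i) {
      row <- so[so$feature_id == truth$indicator_map$feature_id[i] &
                  so$group == truth$indicator_map$group[i], ]
      nrow(row) == 1 && row$key
    }, logical(1))

    sm <- spearman_matrix(rel_f)
    net <- build_network(sm$rho, sm$p, rho_min = params$rho_min,
                         alpha = params$network_alpha,
                         correction = params$network_correction)
    net <- node_centralities(net)
    keys <- keystone_nodes(net)
    hub_argmax <- truth$hub_id %in% keys$per_metric$degree

    de <- differential_test(expr$counts, meta, config$de_pair,
                            method = "nb_exact", lfc_min = params$lfc_min,
                            alpha = params$de_alpha, mode = "gene")
    hit_de <- truth$de_genes$gene %in% de$feature_id[de$significant]

    cpm <- log2(normalized_cpm(expr$counts, tmm_factors(expr$counts)))
    onet <- omics_network(rel[truth$hub_id, , drop = FALSE],
                          cpm[truth$coupling_map$gene, , drop = FALSE],
                          trt$traits,
                          r_min = params$omics_r_min,
                          alpha = params$omics_alpha,
                          trait_r_min = params$trait_r_min,
                          trait_alpha = params$trait_alpha)
    coupled_edge <- truth$coupling_map$gene %in%
      onet$edges$to[onet$edges$type == "taxon-gene" &
                      onet$edges$from == truth$hub_id]
    hub_trait_edge <- any(onet$edges$type == "taxon-trait" &
                            onet$edges$from == truth$hub_id)

    key_set <- unique(c(so$feature_id[so$key],
                        ind$feature_id[ind$significant],
                        unlist(keys$per_metric)))
    chain <- (truth$hub_id %in% key_set) && any(coupled_edge) && hub_trait_edge

    rows[[s]] <- data.frame(indicator_sensitivity = mean(hit_ind),
                            specocc_sensitivity = mean(hit_so),
                            hub_degree_argmax = as.numeric(hub_argmax),
                            de_sensitivity = mean(hit_de),
                            coupling_rate = mean(coupled_edge),
                            chain_recovered = as.numeric(chain))
  }
  do.call(rbind, rows)
}

#' Type-I-error calibration study for the pipeline's permutation tests
#'
#' Simulates data with no group structure (or no association) and measures
#' the empirical rejection rate at nominal alpha = 0.05 for: one-way
#' PERMANOVA on Bray-Curtis distances, the NB exact and permutation
#' differential tests, the Procrustes permutation test, and the Spearman
#' p-value underlying the omics edge rule.
#'
#' @param n_reps Replicates for PERMANOVA and Procrustes (each rep is one
#'   null dataset); the differential and Spearman nulls use one dataset with
#'   \code{n_reps} features/pairs.
#' @param seed Base seed.
#' @param n_permutations Permutations per PERMANOVA/Procrustes replicate; the
#'   rejection rule p < 0.05 is evaluated on the add-one permutation p.
#' @return Named numeric vector of empirical type-I error rates.
#' @export
calibration_study <- function(n_reps = 1000, seed = 1, n_permutations = 199) {
  rates <- c(permanova = NA_real_, nb_exact = NA_real_,
             permutation = NA_real_, protest = NA_real_,
             spearman_edge = NA_real_)

  set.seed(seed)
  meta12 <- data.frame(sample_id = paste0("s", 1:12),
                       group = rep(c("A", "B"), each = 6),
                       stringsAsFactors = FALSE)
  rej <- 0L
  for (r in seq_len(n_reps)) {
    m <- matrix(stats::rpois(30 * 12, 20), 30, 12,
                dimnames = list(paste0("f", 1:30), meta12$sample_id))
    d <- bray_curtis(to_relative_abundance(m))
    if (permanova(d, meta12, n_permutations = n_permutations)$p < 0.05)
      rej <- rej + 1L
  }
  rates["permanova"] <- rej / n_reps

  set.seed(seed + 1L)
  meta20 <- data.frame(sample_id = paste0("s", 1:20),
                       group = rep(c("A", "B"), each = 10),
                       stringsAsFactors = FALSE)
  mu <- exp(stats::rnorm(n_reps, 4, 1))
  cnt <- matrix(stats::rnbinom(n_reps * 20, size = 10, mu = rep(mu, 20)),
                n_reps, 20,
                dimnames = list(paste0("g", seq_len(n_reps)), meta20$sample_id))
  nb <- differential_test(cnt, meta20, c("A", "B"), method = "nb_exact",
                          mode = "gene")
  rates["nb_exact"] <- mean(nb$p < 0.05)
  pm <- differential_test(cnt, meta20, c("A", "B"), method = "permutation",
                          mode = "gene", n_permutations = 999,
                          seed = seed + 2L)
  rates["permutation"] <- mean(pm$p < 0.05)

  set.seed(seed + 3L)
  rej <- 0L
  for (r in seq_len(n_reps)) {
    X <- matrix(stats::rnorm(40), 20, 2, dimnames = list(paste0("s", 1:20), NULL))
    Y <- matrix(stats::rnorm(40), 20, 2, dimnames = list(paste0("s", 1:20), NULL))
    if (procrustes_test(X, Y, n_permutations = n_permutations)$p < 0.05)
      rej <- rej + 1L
  }
  rates["protest"] <- rej / n_reps

  set.seed(seed + 4L)
  n <- 40
  A <- matrix(stats::rnorm(n * n_reps), n)
  B <- matrix(stats::rnorm(n * n_reps), n)
  pvals <- vapply(seq_len(n_reps), function(i) {
    r <- stats::cor(A[, i], B[, i], method = "spearman")
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), n - 2)
  }, numeric(1))
  rates["spearman_edge"] <- mean(pvals < 0.05)
  rates
}
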