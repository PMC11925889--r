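#' Default configuration for the synthetic study generator
#'
#' Encodes the emulated study design: four treatment groups (Control, HA, P,
#' HAP) with 15 animals each, a compositional ASV table spanning rare to
#' abundant tiers, three planted indicator taxa per group, one correlation
#' hub with ten satellites, a transcriptome with planted differential genes
#' and taxon-coupled genes, and a behavior/antioxidant trait panel coupled to
#' the hub and to a planted gene. Values can be overridden per call.
#'
#' @param ... Named overrides of any default listed below.
#' @return Named list of generator parameters.
#' @export
synth_config <- function(...) {
  cfg <- list(
    groups = c("Control", "HA", "P", "HAP"),
    n_per_group = 15L,
    n_features = 300L,
    # intended abundance tiers (proportions of features; must sum to 1) and
    # the latent mean relative-abundance range drawn log-uniformly per tier
    tier_proportions = c(rare = 0.55, moderate = 0.35, abundant = 0.10),
    tier_ra_ranges = list(rare = c(1e-5, 1.5e-4),
                          moderate = c(5e-4, 3e-3),
                          abundant = c(5e-3, 2e-2)),
    sigma_log = 0.8,           # per-feature log-normal noise sd (latent scale)
    depth_range = c(20000, 60000),  # sequencing depth, drawn log-uniformly
    # group-specific indicator taxa (drawn from the moderate tier)
    n_indicators_per_group = 3L,
    indicator_fold = 16,       # fold-enrichment on the latent scale
    # planted correlation hub (abundant) with its satellites (moderate)
    n_satellites = 10L,
    rho_hub = 0.8,
    allow_hub_indicator_overlap = FALSE,
    # transcriptome
    n_genes = 1000L,
    gene_log_mean = c(3.5, 1.2),   # mean and sd of baseline log counts
    gene_dispersion = 0.1,
    n_de_genes = 20L,
    de_pair = c("Control", "HA"),
    de_log2fc = 2,
    n_coupled_genes = 5L,
    coupling_coefficient = 1.0,
    gene_libsize_range = c(0.7, 1.4),
    # trait panel: name -> list(weights = c(id = w), noise_sd)
    traits = NULL)
  over <- list(...)
  for (i in seq_along(over)) cfg[[names(over)[i]]] <- over[[i]]
  cfg
}

#' Generate a synthetic microbial community with planted structure
#'
#' Latent per-sample log-abundances follow a Gaussian copula: every feature
#' gets an independent normal deviate except the hub-satellite block, where
#' satellites share the hub's deviate with correlation \code{rho_hub}.
#' Indicator taxa add \code{log(indicator_fold)} to their latent mean in
#' their group. Latents are exponentiated to a composition and counts drawn
#' multinomially at a log-uniform sequencing depth, so per-sample counts sum
#' exactly to the drawn depth.
#'
#' @param config From \code{\link{synth_config}}.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with \code{counts} (feature x sample matrix),
#'   \code{metadata} (sample_id, group) and \code{truth} (planted structure:
#'   tier, indicator and hub maps, latent matrix, seed).
#' @export
generate_community <- function(config = synth_config(), seed = 1L) {
  cfg <- config
  if (abs(sum(cfg$tier_proportions) - 1) > 1e-9)
    stop("tier_proportions must sum to 1")
  set.seed(seed)
  groups <- cfg$groups
  n <- cfg$n_per_group * length(groups)
  Fn <- cfg$n_features
  sample_ids <- paste0("S", sprintf("%02d", seq_len(n)))
  meta <- sample_metadata(data.frame(
    sample_id = sample_ids,
    group = rep(groups, each = cfg$n_per_group),
    stringsAsFactors = FALSE))
  feature_ids <- paste0("ASV", seq_len(Fn))

  tiers <- rep(names(cfg$tier_proportions),
               times = round(cfg$tier_proportions * Fn))
  tiers <- c(tiers, rep(names(cfg$tier_proportions)[1], Fn - length(tiers)))
  tiers <- sample(tiers)
  names(tiers) <- feature_ids
  base_ra <- numeric(Fn)
  for (tr in names(cfg$tier_ra_ranges)) {
    idx <- tiers == tr
    rng <- log(cfg$tier_ra_ranges[[tr]])
    base_ra[idx] <- exp(stats::runif(sum(idx), rng[1], rng[2]))
  }
  names(base_ra) <- feature_ids

  # plant the hub (abundant) and its satellites (moderate)
  hub_id <- sample(feature_ids[tiers == "abundant"], 1L)
  satellites <- sample(setdiff(feature_ids[tiers == "moderate"], hub_id),
                       cfg$n_satellites)
  # plant group indicators in the moderate tier, outside the hub block
  pool <- setdiff(feature_ids[tiers == "moderate"], c(hub_id, satellites))
  if (!cfg$allow_hub_indicator_overlap &&
      length(pool) < cfg$n_indicators_per_group * length(groups))
    stop("not enough moderate-tier features to plant disjoint indicators")
  ind_ids <- sample(pool, cfg$n_indicators_per_group * length(groups))
  indicator_map <- data.frame(
    feature_id = ind_ids,
    group = rep(groups, each = cfg$n_indicators_per_group),
    fold = cfg$indicator_fold,
    stringsAsFactors = FALSE)

  shift <- matrix(0, Fn, n, dimnames = list(feature_ids, sample_ids))
  for (i in seq_len(nrow(indicator_map))) {
    gidx <- meta$group == indicator_map$group[i]
    shift[indicator_map$feature_id[i], gidx] <- log(indicator_map$fold[i])
  }

  eps <- matrix(stats::rnorm(Fn * n, 0, cfg$sigma_log), Fn, n,
                dimnames = list(feature_ids, sample_ids))
  z_hub <- stats::rnorm(n)
  eps[hub_id, ] <- cfg$sigma_log * z_hub
  for (s_id in satellites) {
    eps[s_id, ] <- cfg$sigma_log *
      (cfg$rho_hub * z_hub + sqrt(1 - cfg$rho_hub^2) * stats::rnorm(n))
  }

  latent <- log(base_ra) + shift + eps
  comp <- exp(latent)
  comp <- sweep(comp, 2L, colSums(comp), "/")
  depth <- round(exp(stats::runif(n, log(cfg$depth_range[1]),
                                  log(cfg$depth_range[2]))))
  counts <- matrix(0, Fn, n, dimnames = list(feature_ids, sample_ids))
  for (j in seq_len(n)) {
    counts[, j] <- stats::rmultinom(1L, depth[j], comp[, j])[, 1L]
  }

  truth <- list(seed = seed,
                group_design = stats::setNames(rep(cfg$n_per_group, length(groups)),
                                               groups),
                tier_map = tiers,
                base_ra = base_ra,
                indicator_map = indicator_map,
                hub_id = hub_id,
                satellites = satellites,
                rho_hub = cfg$rho_hub,
                depth = stats::setNames(depth, sample_ids),
                latent = latent,
                de_genes = NULL,
                coupling_map = NULL,
                trait_model = NULL)
  list(counts = count_table(counts), metadata = meta, truth = truth)
}

#' Generate synthetic gene expression coupled to the community
#'
#' Gene counts are negative-binomial around log-linear means. Planted
#' differential genes shift their group mean by the latent log2 fold change
#' between the two groups of \code{de_pair} (alternating sign); coupled genes
#' add \code{coupling_coefficient} times the standardised latent value of
#' their taxon (the hub by default), tying the transcriptome to the
#' microbiome.
#'
#' @param truth Truth record from \code{\link{generate_community}}.
#' @param config From \code{\link{synth_config}}.
#' @param seed Integer seed.
#' @return List with \code{counts} (gene x sample matrix) and the updated
#'   \code{truth} (fields \code{de_genes}, \code{coupling_map},
#'   \code{gene_latent} filled in).
#' @export
generate_expression <- function(truth, config = synth_config(), seed = 1L) {
  cfg <- config
  set.seed(seed)
  sample_ids <- colnames(truth$latent)
  n <- length(sample_ids)
  G <- cfg$n_genes
  gene_ids <- paste0("gene", sprintf("%04d", seq_len(G)))
  group_of <- rep(names(truth$group_design), times = truth$group_design)

  beta0 <- stats::rnorm(G, cfg$gene_log_mean[1], cfg$gene_log_mean[2])
  logmu <- matrix(beta0, G, n, dimnames = list(gene_ids, sample_ids))

  de_ids <- sample(gene_ids, cfg$n_de_genes)
  de_sign <- rep(c(1, -1), length.out = cfg$n_de_genes)
  de_genes <- data.frame(gene = de_ids,
                         group_a = rep(cfg$de_pair[1], length(de_ids)),
                         group_b = rep(cfg$de_pair[2], length(de_ids)),
                         log2fc = cfg$de_log2fc * de_sign,
                         stringsAsFactors = FALSE)
  in_b <- group_of == cfg$de_pair[2]
  for (i in seq_len(nrow(de_genes))) {
    logmu[de_genes$gene[i], in_b] <- logmu[de_genes$gene[i], in_b] +
      de_genes$log2fc[i] * log(2)
  }

  coupled_ids <- sample(setdiff(gene_ids, de_ids), cfg$n_coupled_genes)
  coupling_map <- data.frame(gene = coupled_ids,
                             taxon = rep(truth$hub_id, length(coupled_ids)),
                             coefficient = rep(cfg$coupling_coefficient,
                                               length(coupled_ids)),
                             stringsAsFactors = FALSE)
  for (i in seq_len(nrow(coupling_map))) {
    tx <- coupling_map$taxon[i]
    if (!tx %in% rownames(truth$latent))
      stop("coupling to unknown taxon: ", tx)
    zt <- as.numeric(scale(truth$latent[tx, ]))
    logmu[coupling_map$gene[i], ] <- logmu[coupling_map$gene[i], ] +
      coupling_map$coefficient[i] * zt
  }

  sf <- exp(stats::runif(n, log(cfg$gene_libsize_range[1]),
                         log(cfg$gene_libsize_range[2])))
  mu <- sweep(exp(logmu), 2L, sf, "*")
  counts <- matrix(stats::rnbinom(G * n, size = 1 / cfg$gene_dispersion,
                                  mu = as.vector(mu)),
                   G, n, dimnames = list(gene_ids, sample_ids))
  truth$de_genes <- de_genes
  truth$coupling_map <- coupling_map
  truth$gene_latent <- logmu
  list(counts = count_table(counts), truth = truth)
}

default_trait_model <- function(truth) {
  hub <- truth$hub_id
  first_gene <- if (!is.null(truth$coupling_map)) truth$coupling_map$gene[1] else NULL
  model <- list(
    exploration_ratio = list(weights = stats::setNames(1.0, hub), noise_sd = 0.3),
    open_arm_duration = list(weights = stats::setNames(0.8, truth$indicator_map$feature_id[1]),
                             noise_sd = 0.4),
    t_aoc = if (is.null(first_gene))
      list(weights = numeric(0), noise_sd = 1) else
      list(weights = stats::setNames(0.8, first_gene), noise_sd = 0.4),
    sod = list(weights = numeric(0), noise_sd = 1),
    cat_activity = list(weights = numeric(0), noise_sd = 1),
    mda = list(weights = stats::setNames(-0.8, hub), noise_sd = 0.4))
  model
}

#' Generate a synthetic trait panel (behavior / antioxidant analogues)
#'
#' Each trait is an intercept plus a weighted sum of standardised latent
#' values of the referenced taxa and/or genes, plus Gaussian noise. The
#' default panel couples an exploration-ratio analogue to the hub taxon, an
#' antioxidant analogue to the first coupled gene, and leaves the remaining
#' traits as pure noise.
#'
#' @param truth Truth record (after \code{\link{generate_expression}} if any
#'   trait references a gene).
#' @param config From \code{\link{synth_config}}; \code{config$traits}
#'   overrides the default panel.
#' @param seed Integer seed.
#' @return List with \code{traits} (data.frame: sample_id + one numeric
#'   column per trait) and updated \code{truth} (\code{trait_model} filled).
#' @export
generate_traits <- function(truth, config = synth_config(), seed = 1L) {
  set.seed(seed)
  model <- if (!is.null(config$traits)) config$traits else default_trait_model(truth)
  sample_ids <- colnames(truth$latent)
  n <- length(sample_ids)
  out <- data.frame(sample_id = sample_ids, stringsAsFactors = FALSE)
  for (nm in names(model)) {
    spec <- model[[nm]]
    if (length(spec$weights) == 0 && identical(spec$noise_sd, 0))
      stop("trait '", nm, "' has zero weights and zero noise: constant trait")
    val <- rep(0, n)
    for (id in names(spec$weights)) {
      latent <- if (id %in% rownames(truth$latent)) truth$latent[id, ]
        else if (!is.null(truth$gene_latent) && id %in% rownames(truth$gene_latent))
          truth$gene_latent[id, ]
        else stop("trait '", nm, "' references unknown feature/gene: ", id)
      val <- val + spec$weights[[id]] * as.numeric(scale(latent))
    }
    out[[nm]] <- val + stats::rnorm(n, 0, spec$noise_sd)
  }
  truth$trait_model <- model
  list(traits = out, truth = truth)
}

#' Write a truth record as JSON
#'
#' Large latent matrices are omitted; the planted ids, effects and design
#' are kept so recovery can be audited from the file.
#'
#' @param truth Truth record.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  slim <- truth[setdiff(names(truth), c("latent", "gene_latent"))]
  slim$trait_model <- lapply(slim$trait_model, function(m)
    list(weights = as.list(m$weights), noise_sd = m$noise_sd))
  jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
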