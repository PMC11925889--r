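test_that("all three generators are deterministic under a fixed seed", {
  cfg <- small_config()
  a <- generate_community(cfg, seed = 42)
  b <- generate_community(cfg, seed = 42)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth$indicator_map, b$truth$indicator_map)
  ea <- generate_expression(a$truth, cfg, seed = 43)
  eb <- generate_expression(b$truth, cfg, seed = 43)
  expect_identical(ea$counts, eb$counts)
  ta <- generate_traits(ea$truth, cfg, seed = 44)
  tb <- generate_traits(eb$truth, cfg, seed = 44)
  expect_identical(ta$traits, tb$traits)
  # different seed changes the data
  expect_false(identical(a$counts, generate_community(cfg, seed = 43)$counts))
})

test_that("per-sample counts sum to the drawn depth and respect the design", {
  cfg <- small_config()
  out <- generate_community(cfg, seed = 7)
  expect_equal(unname(colSums(out$counts)), unname(out$truth$depth))
  expect_true(all(colSums(out$counts) >= cfg$depth_range[1]))
  expect_equal(as.vector(attr(out$metadata, "group_sizes")),
               rep(cfg$n_per_group, 4))
  expect_equal(sort(unique(as.character(out$metadata$group))),
               sort(cfg$groups))
  # every planted id exists in the emitted table
  expect_true(all(out$truth$indicator_map$feature_id %in% rownames(out$counts)))
  expect_true(out$truth$hub_id %in% rownames(out$counts))
})

test_that("tier proportions must sum to one", {
  cfg <- small_config(tier_proportions = c(rare = 0.5, moderate = 0.2,
                                           abundant = 0.1))
  expect_error(generate_community(cfg, seed = 1), "sum to 1")
})

test_that("hub-satellite correlations exceed the background on realized counts", {
  out <- generate_community(synth_config(), seed = 11)
  rel <- to_relative_abundance(out$counts)
  truth <- out$truth
  hub <- rel[truth$hub_id, ]
  sat_cor <- vapply(truth$satellites, function(s)
    abs(cor(hub, rel[s, ], method = "spearman")), numeric(1))
  others <- setdiff(rownames(rel),
                    c(truth$hub_id, truth$satellites,
                      truth$indicator_map$feature_id))
  set.seed(1)
  bg <- vapply(sample(others, 50), function(s)
    abs(cor(hub, rel[s, ], method = "spearman")), numeric(1))
  expect_gt(mean(sat_cor), mean(bg) + 0.3)
})

test_that("rare-tier features stay below 0.1% relative abundance in >= 95% of samples", {
  out <- generate_community(synth_config(), seed = 13)
  rel <- to_relative_abundance(out$counts)
  rare_ids <- names(out$truth$tier_map)[out$truth$tier_map == "rare"]
  frac_below <- rowMeans(rel[rare_ids, , drop = FALSE] <= 0.001)
  expect_gte(mean(frac_below), 0.95)
  expect_gte(mean(frac_below >= 0.95), 0.9)
})

test_that("null expression (no DE, no coupling) centers group log-CPM differences on zero", {
  cfg <- small_config(n_de_genes = 0L, n_coupled_genes = 0L, n_genes = 300L)
  comm <- generate_community(cfg, seed = 21)
  expr <- generate_expression(comm$truth, cfg, seed = 22)
  cpm <- normalized_cpm(expr$counts, tmm_factors(expr$counts))
  grp <- comm$metadata$group
  dif <- rowMeans(log2(cpm[, grp == "HA"])) - rowMeans(log2(cpm[, grp == "Control"]))
  expect_lt(abs(mean(dif)), 0.1)
  expect_equal(nrow(expr$truth$de_genes), 0L)
})

test_that("coupled genes track their taxon and planted DE genes shift group means", {
  cfg <- small_config()
  comm <- generate_community(cfg, seed = 31)
  expr <- generate_expression(comm$truth, cfg, seed = 32)
  truth <- expr$truth
  rel <- to_relative_abundance(comm$counts)
  cpm <- normalized_cpm(expr$counts, tmm_factors(expr$counts))
  for (i in seq_len(nrow(truth$coupling_map))) {
    r <- cor(cpm[truth$coupling_map$gene[i], ],
             rel[truth$coupling_map$taxon[i], ], method = "spearman")
    expect_gt(r, 0.6)
  }
  grp <- comm$metadata$group
  lfc <- log2(rowMeans(cpm[truth$de_genes$gene, grp == "HA"]) /
                rowMeans(cpm[truth$de_genes$gene, grp == "Control"]))
  expect_lt(mean(abs(lfc - truth$de_genes$log2fc)), 0.6)
  # coupling to an unknown taxon is rejected
  bad <- comm$truth; bad$hub_id <- "ASV-not-there"
  expect_error(generate_expression(bad, cfg, seed = 1), "unknown taxon")
})

test_that("trait generator honors weights, noise and validation", {
  cfg <- small_config()
  comm <- generate_community(cfg, seed = 41)
  expr <- generate_expression(comm$truth, cfg, seed = 42)
  trt <- generate_traits(expr$truth, cfg, seed = 43)
  truth <- trt$truth
  rel <- to_relative_abundance(comm$counts)
  # hub-weighted trait tracks the hub's realized abundance
  r_hub <- cor(trt$traits$exploration_ratio, rel[truth$hub_id, ],
               method = "spearman")
  expect_gt(r_hub, 0.7)
  # null traits are uncorrelated with the community (empirical null bound)
  n <- ncol(rel)
  r_null <- abs(apply(rel, 1, cor, y = trt$traits$sod))
  expect_lt(mean(r_null), 3 * 2 / sqrt(n))
  # constant-trait misconfiguration is rejected
  cfg_bad <- small_config(traits = list(dead = list(weights = numeric(0),
                                                    noise_sd = 0)))
  expect_error(generate_traits(expr$truth, cfg_bad, seed = 1), "constant")
})

test_that("truth JSON export keeps planted structure and drops latent matrices", {
  cfg <- small_config()
  comm <- generate_community(cfg, seed = 51)
  expr <- generate_expression(comm$truth, cfg, seed = 52)
  trt <- generate_traits(expr$truth, cfg, seed = 53)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth(trt$truth, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$hub_id, trt$truth$hub_id)
  expect_null(back$latent)
  expect_equal(length(back$satellites), length(trt$truth$satellites))
})
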