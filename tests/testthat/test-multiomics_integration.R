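test_that("Procrustes m2 vanishes under rotation plus scaling and p hits the floor", {
  set.seed(71)
  X <- matrix(rnorm(20 * 2), 20, 2, dimnames = list(paste0("s", 1:20), NULL))
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  Y <- 3.2 * X %*% R + 5  # rigid rotation, uniform scaling, translation
  rownames(Y) <- rownames(X)
  res <- procrustes_test(X, Y, n_axes = 2, n_permutations = 999, seed = 71)
  expect_lt(res$m2, 1e-10)
  expect_equal(res$p, 1 / 1000)
  expect_equal(res$t_stat, 1, tolerance = 1e-6)

  # reflection also recovered (reflections allowed)
  Yr <- Y %*% diag(c(-1, 1))
  rownames(Yr) <- rownames(X)
  expect_lt(procrustes_test(X, Yr, n_permutations = 49, seed = 1)$m2, 1e-10)
})

test_that("Procrustes m2 matches an independent step-by-step superimposition oracle", {
  X <- matrix(c(0, 1, 1, 0, 0, 0, 1, 1), 4, 2,
              dimnames = list(paste0("s", 1:4), NULL))
  Y <- matrix(c(0.1, 1.3, 0.9, -0.2, 0.2, -0.1, 1.2, 0.8), 4, 2,
              dimnames = list(paste0("s", 1:4), NULL))
  res <- procrustes_test(X, Y, n_axes = 2, n_permutations = 9, seed = 1)
  # oracle: explicit centering, unit-trace scaling, optimal rotation residual
  Xc <- scale(X, scale = FALSE); Xc <- Xc / sqrt(sum(Xc^2))
  Yc <- scale(Y, scale = FALSE); Yc <- Yc / sqrt(sum(Yc^2))
  sv <- svd(t(Xc) %*% Yc)
  rot <- sv$v %*% t(sv$u)
  resid <- sum((Xc - Yc %*% rot * sum(sv$d))^2)
  expect_equal(res$m2, resid, tolerance = 1e-10)
  expect_equal(res$m2, 1 - sum(sv$d)^2, tolerance = 1e-10)
})

test_that("Procrustes agrees with the vegan protest oracle on ordinations", {
  skip_if_not_installed("vegan")
  set.seed(72)
  m <- rand_counts(40, 12, lambda = 30, seed = 72)
  d <- bray_curtis(to_relative_abundance(m))
  ordA <- pcoa(d)
  expr <- matrix(rnorm(30 * 12, 5), 30, 12,
                 dimnames = list(paste0("g", 1:30), colnames(m)))
  expr[1:5, ] <- expr[1:5, ] + 2 * ordA$coordinates[, 1]
  ordB <- pca_ordination(expr)
  res <- procrustes_test(ordA, ordB, n_axes = 2, n_permutations = 999, seed = 72)
  pro <- vegan::protest(ordA$coordinates[, 1:2], ordB$coordinates[, 1:2],
                        permutations = 999)
  expect_equal(res$m2, pro$ss, tolerance = 1e-10)
  # both are permutation tests of the same statistic; p-values agree closely
  expect_lt(abs(res$p - pro$signif), 0.05)
})

test_that("Procrustes errors name mismatched samples", {
  X <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("s", 1:5), NULL))
  Y <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("t", 1:5), NULL))
  expect_error(procrustes_test(X, Y), "only in A.*s1")
})

test_that("omics network applies strict thresholds and recovers a hard coupling", {
  set.seed(73)
  n <- 40
  ids <- paste0("s", 1:n)
  z <- rnorm(n)
  taxa <- rbind(hub = exp(z), other = rexp(n))
  colnames(taxa) <- ids
  genes <- rbind(coupled = z + rnorm(n, 0, 0.1), free = rnorm(n))
  colnames(genes) <- ids
  traits <- data.frame(sample_id = ids, behav = z + rnorm(n, 0, 0.2),
                       null_trait = rnorm(n))
  net <- omics_network(taxa, genes, traits)
  eg <- net$edges
  expect_true(any(eg$type == "taxon-gene" & eg$from == "hub" & eg$to == "coupled"))
  expect_false(any(eg$from == "other" & eg$to == "free"))
  expect_true(any(eg$type == "taxon-trait" & eg$from == "hub" & eg$to == "behav"))
  expect_true(all(eg$rho[eg$type == "taxon-gene"] > 0.8))
  expect_true(all(eg$p[eg$type == "taxon-gene"] < 0.01))

  # sample-order invariance
  perm <- sample(n)
  net2 <- omics_network(taxa[, perm], genes[, perm], traits)
  expect_equal(sort(paste(net2$edges$from, net2$edges$to)),
               sort(paste(eg$from, eg$to)))

  expect_error(omics_network(taxa[, 1:4], genes[, 1:4], NULL), "fewer than 5")
})

test_that("taxon-gene edges at rho exactly 0.8 are excluded (strict rule)", {
  ids <- paste0("s", 1:5)
  # ranks (1..5) against (2,1,3,5,4): sum d^2 = 4, so Spearman rho is
  # exactly 1 - 6*4/(5*24) = 0.8
  taxa <- rbind(t1 = 1:5)
  colnames(taxa) <- ids
  genes <- rbind(g1 = c(2, 1, 3, 5, 4), g2 = c(1, 2, 3, 4, 5))
  colnames(genes) <- ids
  expect_equal(cor(taxa[1, ], genes["g1", ], method = "spearman"), 0.8)
  net <- omics_network(taxa, genes, NULL, r_min = 0.8, alpha = 1)
  expect_false(any(net$edges$to == "g1"))   # rho == r_min: excluded
  expect_true(any(net$edges$to == "g2"))    # rho = 1 > r_min: retained
})

test_that("trait-feature screen matches a correlation oracle and its strict boundary", {
  set.seed(74)
  n <- 30
  ids <- paste0("s", 1:n)
  feats <- matrix(rnorm(5 * n), 5, n, dimnames = list(paste0("f", 1:5), ids))
  traits <- data.frame(sample_id = ids,
                       t1 = feats[1, ] ,          # exact copy: r = 1
                       t2 = rnorm(n),
                       t3 = replace(rnorm(n), 1:3, NA))  # missing values
  res <- trait_feature_correlation(feats, traits)
  r11 <- res[res$feature_id == "f1" & res$trait == "t1", ]
  expect_equal(r11$r_pearson, 1, tolerance = 1e-12)
  expect_true(r11$pass)
  # oracle on random pairs, including pairwise-complete handling
  for (f in rownames(feats)) for (tr in c("t2", "t3")) {
    row <- res[res$feature_id == f & res$trait == tr, ]
    ct <- cor.test(feats[f, ], traits[[tr]])
    expect_equal(row$r_pearson, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(row$p_pearson, ct$p.value, tolerance = 1e-9)
    sp <- suppressWarnings(cor.test(feats[f, ], traits[[tr]], method = "spearman"))
    expect_equal(row$r_spearman, unname(sp$estimate), tolerance = 1e-12)
  }
  # every pass satisfies the strict |r| > cor_min and p < alpha rules
  expect_true(all(!res$pass | (abs(res$r_pearson) > 0.05 & res$p_pearson < 0.05)))
  # raising cor_min to 1 can never pass (strict inequality at the boundary)
  res_hi <- trait_feature_correlation(feats, traits, cor_min = 1)
  expect_false(any(res_hi$pass))
})
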