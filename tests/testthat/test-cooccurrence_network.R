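test_that("Spearman matrix handles monotone data, ties and constants", {
  x <- 1:8
  rel <- rbind(up = x, curve = x^3, down = -x, const = rep(2, 8),
               noise = c(3, 1, 4, 1, 5, 9, 2, 6))
  colnames(rel) <- paste0("s", 1:8)
  sm <- spearman_matrix(rel)
  expect_equal(diag(sm$rho), rep(1, 5), ignore_attr = TRUE)
  expect_equal(sm$rho["up", "curve"], 1)
  expect_equal(sm$rho["up", "down"], -1)
  expect_true(all(is.na(sm$rho["const", c("up", "noise")])))
  expect_equal(sm$rho, t(sm$rho))

  # tied data: must equal rank-then-Pearson with mid-ranks
  set.seed(51)
  tied <- matrix(sample(1:4, 40, replace = TRUE), 4, 10,
                 dimnames = list(paste0("f", 1:4), paste0("s", 1:10)))
  smt <- spearman_matrix(tied)
  oracle <- cor(apply(tied, 1, rank))  # mid-rank then Pearson
  expect_equal(unname(smt$rho), unname(oracle), tolerance = 1e-12)
  tt <- smt$rho[1, 2] * sqrt(8 / (1 - smt$rho[1, 2]^2))
  expect_equal(smt$p[1, 2], 2 * pt(-abs(tt), 8), tolerance = 1e-12)
})

test_that("network construction matches a brute-force recount of passing pairs", {
  set.seed(52)
  rel <- matrix(rexp(20 * 12), 20, 12,
                dimnames = list(paste0("f", 1:20), paste0("s", 1:12)))
  rel[2, ] <- rel[1, ] + rnorm(12, 0, 0.01)
  rel[3, ] <- rel[1, ] + rnorm(12, 0, 0.01)
  sm <- spearman_matrix(rel)
  net <- build_network(sm$rho, sm$p, rho_min = 0.6, alpha = 0.05, correction = "bh")
  # brute force: recompute the edge rule pair by pair
  ut <- which(upper.tri(sm$rho), arr.ind = TRUE)
  q <- p.adjust(sm$p[ut], method = "BH")
  n_expected <- sum(abs(sm$rho[ut]) >= 0.6 & q < 0.05, na.rm = TRUE)
  expect_equal(nrow(net$edges), n_expected)
  expect_equal(nrow(net$nodes), 20L)  # isolated nodes retained

  # perfectly correlated triple forms a triangle
  tri_edges <- net$edges[net$edges$from %in% c("f1", "f2", "f3") &
                           net$edges$to %in% c("f1", "f2", "f3"), ]
  expect_equal(nrow(tri_edges), 3L)

  expect_error(build_network(sm$rho, sm$p, rho_min = 1.5), "rho_min")
})

test_that("network construction is invariant to feature ordering", {
  set.seed(53)
  rel <- matrix(rexp(15 * 10), 15, 10,
                dimnames = list(paste0("f", 1:15), paste0("s", 1:10)))
  rel[5, ] <- rel[9, ] * 2
  sm <- spearman_matrix(rel)
  net1 <- build_network(sm$rho, sm$p, rho_min = 0.5)
  perm <- sample(15)
  smp <- spearman_matrix(rel[perm, ])
  net2 <- build_network(smp$rho, smp$p, rho_min = 0.5)
  key1 <- sort(with(net1$edges, paste(pmin(from, to), pmax(from, to))))
  key2 <- sort(with(net2$edges, paste(pmin(from, to), pmax(from, to))))
  expect_identical(key1, key2)
})

test_that("centralities are exact on star, cycle and path graphs", {
  star <- net_from_edges(data.frame(from = "hub", to = paste0("leaf", 1:5)))
  star <- node_centralities(star)
  h <- star$nodes[star$nodes$id == "hub", ]
  expect_equal(h$degree, 5)
  expect_equal(h$betweenness, 10)  # all C(5,2) leaf pairs
  expect_equal(h$stress, 10)
  expect_equal(h$eigenvector, 1)
  leaves <- star$nodes[star$nodes$id != "hub", ]
  expect_true(all(leaves$betweenness == 0))
  ks <- keystone_nodes(star)
  expect_true(all(vapply(ks$per_metric, identical, logical(1), "hub")))

  cyc <- net_from_edges(data.frame(from = paste0("n", 1:6),
                                   to = paste0("n", c(2:6, 1))))
  cyc <- node_centralities(cyc)
  expect_equal(var(cyc$nodes$eigenvector), 0)
  expect_equal(var(cyc$nodes$degree), 0)

  path <- net_from_edges(data.frame(from = c("a", "b", "c"),
                                    to = c("b", "c", "d")))
  path <- node_centralities(path)
  expect_equal(path$nodes$betweenness[path$nodes$id == "b"], 2)
  expect_equal(path$nodes$betweenness[path$nodes$id == "c"], 2)
  expect_equal(path$nodes$stress[path$nodes$id == "b"], 2)
})

test_that("betweenness and stress match exhaustive enumeration on small random graphs", {
  set.seed(54)
  for (trial in 1:12) {
    V <- sample(4:8, 1)
    A <- matrix(0, V, V)
    A[upper.tri(A)] <- rbinom(V * (V - 1) / 2, 1, 0.45)
    A <- A + t(A)
    ids <- paste0("v", seq_len(V))
    dimnames(A) <- list(ids, ids)
    ij <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
    if (!nrow(ij)) next
    net <- net_from_edges(data.frame(from = ids[ij[, 1]], to = ids[ij[, 2]],
                                     stringsAsFactors = FALSE),
                          nodes = ids)
    net <- node_centralities(net)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_equal(net$nodes$betweenness,
                 unname(igraph::betweenness(g, directed = FALSE)),
                 tolerance = 1e-10)
    # stress oracle: enumerate all shortest paths between every pair
    stress_oracle <- numeric(V)
    for (s in 1:(V - 1)) for (t in (s + 1):V) {
      sp <- igraph::all_shortest_paths(g, from = s, to = t)$res
      for (pth in sp) {
        inner <- setdiff(as.integer(pth), c(s, t))
        stress_oracle[inner] <- stress_oracle[inner] + 1
      }
    }
    expect_equal(net$nodes$stress, stress_oracle)
    # eigenvector centrality against a power-iteration oracle (connected case)
    if (igraph::is_connected(g)) {
      # power iteration on A + I (same eigenvectors, avoids bipartite cycling)
      B <- A + diag(V)
      v <- rep(1, V)
      for (it in 1:2000) v <- B %*% v / sqrt(sum((B %*% v)^2))
      v <- abs(as.numeric(v)) / max(abs(v))
      expect_equal(net$nodes$eigenvector, v, tolerance = 1e-6)
    }
  }
})

test_that("degree identities hold and modules split disjoint cliques", {
  tri2 <- net_from_edges(data.frame(
    from = c("a", "a", "b", "x", "x", "y"),
    to = c("b", "c", "c", "y", "z", "z")))
  tri2 <- node_centralities(tri2)
  expect_equal(sum(tri2$nodes$degree), 2 * nrow(tri2$edges))
  tri2 <- detect_modules(tri2)
  expect_equal(length(unique(tri2$nodes$module)), 2L)
  expect_equal(length(unique(tri2$nodes$module[tri2$nodes$id %in% c("a", "b", "c")])), 1L)

  # fully connected graph collapses to one module
  full <- net_from_edges(expand.grid(from = paste0("k", 1:4),
                                     to = paste0("k", 1:4),
                                     stringsAsFactors = FALSE) |>
                           subset(from < to))
  full <- detect_modules(full)
  expect_equal(length(unique(full$nodes$module)), 1L)
})

test_that("keystone report lists ties and empty networks yield zero metrics", {
  twin <- net_from_edges(data.frame(from = c("h1", "h1", "h2", "h2"),
                                    to = c("l1", "l2", "l3", "l4")))
  twin <- node_centralities(twin)
  ks <- keystone_nodes(twin)
  expect_setequal(ks$per_metric$degree, c("h1", "h2"))

  rho0 <- diag(3); p0 <- 1 - diag(3)
  ids <- c("a", "b", "c")
  dimnames(rho0) <- dimnames(p0) <- list(ids, ids)
  empty <- node_centralities(build_network(rho0, p0))
  expect_true(all(empty$nodes$degree == 0))
  expect_true(all(empty$nodes$eigenvector == 0))
  expect_equal(keystone_nodes(empty)$per_metric$degree, character(0))
})
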