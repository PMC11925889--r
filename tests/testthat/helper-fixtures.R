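# Small in-code fixtures shared across test files.

# random count matrix with named dims
rand_counts <- function(n_feat = 6, n_samp = 4, lambda = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(n_feat * n_samp, lambda), n_feat, n_samp,
              dimnames = list(paste0("f", seq_len(n_feat)),
                              paste0("s", seq_len(n_samp))))
  m
}

two_group_meta <- function(n_per_group = 3, groups = c("A", "B")) {
  data.frame(sample_id = paste0("s", seq_len(n_per_group * length(groups))),
             group = rep(groups, each = n_per_group),
             stringsAsFactors = FALSE)
}

# tiny configuration for fast synthetic runs
small_config <- function(...) {
  synth_config(n_per_group = 10L, n_features = 120L, n_genes = 200L,
               n_de_genes = 8L, n_coupled_genes = 3L,
               n_satellites = 6L, ...)
}

# build a cooccurrence_network directly from an edge list (testing helper)
net_from_edges <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  rho <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  p <- matrix(1, length(nodes), length(nodes), dimnames = dimnames(rho))
  for (i in seq_len(nrow(edges))) {
    rho[edges$from[i], edges$to[i]] <- rho[edges$to[i], edges$from[i]] <- 0.9
    p[edges$from[i], edges$to[i]] <- p[edges$to[i], edges$from[i]] <- 1e-9
  }
  diag(p) <- 0
  build_network(rho, p, rho_min = 0.6, alpha = 0.05, correction = "none")
}
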