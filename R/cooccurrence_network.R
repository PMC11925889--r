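#' Pairwise Spearman correlation matrix with t-approximation p-values
#'
#' Spearman rho with mid-ranks for ties; two-sided p from the t
#' approximation t = rho * sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom.
#' Pairs involving a constant feature are returned as NA.
#'
#' @param rel Feature x sample matrix (>= 5 samples).
#' @return List with symmetric matrices \code{rho} and \code{p}
#'   (features x features; unit diagonal, zero-diagonal p).
#' @export
spearman_matrix <- function(rel) {
  n <- ncol(rel)
  if (n < 5L) stop("need at least 5 samples for correlation networks")
  x <- t(rel)
  sds <- apply(x, 2L, stats::sd)
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  rho[sds == 0, ] <- NA_real_
  rho[, sds == 0] <- NA_real_
  r <- pmin(pmax(rho, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) >= 1] <- 0
  diag(rho) <- 1
  diag(p) <- 0
  list(rho = rho, p = p)
}

#' Build a co-occurrence network from correlation matrices
#'
#' An undirected edge joins features i and j when |rho_ij| >= rho_min and
#' the (optionally BH-adjusted) p-value is below \code{alpha}. Isolated
#' nodes are retained. Adjustment is applied over the upper-triangle tests.
#'
#' @param rho,p Symmetric, aligned correlation and p-value matrices (as from
#'   \code{\link{spearman_matrix}}).
#' @param rho_min Minimum absolute correlation in [0,1] (default 0.6).
#' @param alpha Significance level (default 0.05).
#' @param correction \code{"bh"} (Benjamini-Hochberg, default) or
#'   \code{"none"}.
#' @param node_attributes Optional data.frame keyed by \code{feature_id}
#'   (e.g. abundance classes) merged onto the node table.
#' @return List of class \code{cooccurrence_network} with \code{nodes}
#'   (data.frame: id plus attributes), \code{edges} (from, to, rho, p, q) and
#'   \code{params}.
#' @export
build_network <- function(rho, p, rho_min = 0.6, alpha = 0.05,
                          correction = c("bh", "none"),
                          node_attributes = NULL) {
  correction <- match.arg(correction)
  if (rho_min < 0 || rho_min > 1) stop("rho_min must be in [0,1]")
  if (!identical(dim(rho), dim(p))) stop("rho and p matrices are not aligned")
  if (max(abs(rho - t(rho)), na.rm = TRUE) > 1e-12) stop("rho matrix not symmetric")
  ids <- rownames(rho)
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[ut]
  pv <- p[ut]
  ok <- !is.na(r)
  q <- rep(NA_real_, length(pv))
  q[ok] <- if (correction == "bh") stats::p.adjust(pv[ok], method = "BH") else pv[ok]
  sel <- ok & abs(r) >= rho_min & q < alpha
  edges <- data.frame(from = ids[ut[sel, 1L]], to = ids[ut[sel, 2L]],
                      rho = r[sel], p = pv[sel], q = q[sel],
                      stringsAsFactors = FALSE, row.names = NULL)
  nodes <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (!is.null(node_attributes)) {
    nodes <- merge(nodes, node_attributes, by.x = "id", by.y = "feature_id",
                   all.x = TRUE, sort = FALSE)
    nodes <- nodes[match(ids, nodes$id), , drop = FALSE]
    rownames(nodes) <- NULL
  }
  structure(list(nodes = nodes, edges = edges,
                 params = list(rho_min = rho_min, alpha = alpha,
                               correction = correction)),
            class = "cooccurrence_network")
}

adjacency_matrix <- function(net) {
  ids <- net$nodes$id
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(net$edges)) {
    i <- match(net$edges$from, ids)
    j <- match(net$edges$to, ids)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  A
}

# Breadth-first shortest-path distances and path counts from every source.
# Returns list(D = distances, S = number of shortest paths), both V x V.
shortest_path_counts <- function(A) {
  V <- nrow(A)
  D <- matrix(Inf, V, V)
  S <- matrix(0, V, V)
  for (s in seq_len(V)) {
    dist <- rep(Inf, V); sigma <- rep(0, V)
    dist[s] <- 0; sigma[s] <- 1
    frontier <- s
    while (length(frontier)) {
      reach <- if (length(frontier) == 1L) A[frontier, ] * sigma[frontier]
               else as.vector(sigma[frontier] %*% A[frontier, , drop = FALSE])
      nxt <- which(reach > 0 & !is.finite(dist))
      if (!length(nxt)) break
      dist[nxt] <- dist[frontier[1L]] + 1
      sigma[nxt] <- reach[nxt]
      frontier <- nxt
    }
    D[s, ] <- dist
    S[s, ] <- sigma
  }
  list(D = D, S = S)
}

#' Compute node centralities for a co-occurrence network
#'
#' Adds degree, betweenness, stress and eigenvector centrality to the node
#' table, computed on the unweighted skeleton. Betweenness sums, over
#' unordered pairs (s, t), the fraction of shortest s-t paths passing through
#' the node; stress sums the raw number of such paths. Eigenvector centrality
#' is the principal eigenvector of the adjacency matrix, computed per
#' connected component and max-normalised to 1 across the network; isolated
#' nodes score 0.
#'
#' @param net A \code{cooccurrence_network}.
#' @return The network with columns \code{degree}, \code{betweenness},
#'   \code{stress}, \code{eigenvector} added to \code{nodes}.
#' @export
node_centralities <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  A <- adjacency_matrix(net)
  V <- nrow(A)
  degree <- rowSums(A)
  betweenness <- numeric(V)
  stress <- numeric(V)
  if (nrow(net$edges)) {
    sp <- shortest_path_counts(A)
    D <- sp$D; S <- sp$S
    for (v in seq_len(V)) {
      if (degree[v] < 2) next
      Dsum <- outer(D[, v], D[v, ], "+")
      on_path <- is.finite(Dsum) & Dsum == D & S > 0
      on_path[v, ] <- FALSE
      on_path[, v] <- FALSE
      diag(on_path) <- FALSE
      if (!any(on_path)) next
      paths_through <- outer(S[, v], S[v, ])
      betweenness[v] <- sum((paths_through / S)[on_path]) / 2
      stress[v] <- sum(paths_through[on_path]) / 2
    }
  }
  eigenv <- numeric(V)
  if (nrow(net$edges)) {
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    comp <- igraph::components(g)$membership
    for (cc in unique(comp)) {
      idx <- which(comp == cc)
      if (length(idx) < 2L) next
      e <- eigen(A[idx, idx], symmetric = TRUE)
      v1 <- abs(e$vectors[, 1L])
      eigenv[idx] <- v1
    }
    if (max(eigenv) > 0) eigenv <- eigenv / max(eigenv)
  }
  net$nodes$degree <- as.numeric(degree)
  net$nodes$betweenness <- betweenness
  net$nodes$stress <- stress
  net$nodes$eigenvector <- eigenv
  net
}

#' Detect network modules by greedy modularity maximisation
#'
#' Fast-greedy community detection on the unweighted skeleton; singleton
#' components form their own modules. The algorithm is deterministic, so
#' module ids are stable across runs.
#'
#' @param net A \code{cooccurrence_network}.
#' @param seed Optional seed (kept for interface stability; the greedy
#'   algorithm itself is deterministic).
#' @return The network with a \code{module} column added to \code{nodes}.
#' @export
detect_modules <- function(net, seed = NULL) {
  stopifnot(inherits(net, "cooccurrence_network"))
  if (!is.null(seed)) set.seed(seed)
  if (!nrow(net$edges)) {
    net$nodes$module <- seq_len(nrow(net$nodes))
    return(net)
  }
  g <- igraph::graph_from_adjacency_matrix(adjacency_matrix(net),
                                           mode = "undirected")
  cl <- igraph::cluster_fast_greedy(g)
  if (igraph::modularity(cl) > 0) {
    net$nodes$module <- as.integer(igraph::membership(cl))
  } else {
    # the greedy cut is no better than the trivial partition; fall back to
    # connected components (complete graphs, single cliques)
    net$nodes$module <- as.integer(igraph::components(g)$membership)
  }
  net
}

#' Report keystone nodes (per-metric argmax with ties)
#'
#' For each centrality metric, reports the node(s) attaining the maximum;
#' nodes maximising degree or mediation (betweenness/stress) are the
#' candidate keystones of the community.
#'
#' @param net A network that has been through \code{\link{node_centralities}}.
#' @return List with \code{per_metric} (named list of character vectors of
#'   argmax node ids, ties included) and \code{table} (data.frame: metric,
#'   node, value).
#' @export
keystone_nodes <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  metrics <- c("degree", "betweenness", "stress", "eigenvector")
  if (!all(metrics %in% colnames(net$nodes)))
    stop("run node_centralities() before keystone_nodes()")
  per_metric <- lapply(metrics, function(m) {
    v <- net$nodes[[m]]
    if (!length(v) || max(v) == 0) return(character(0))
    net$nodes$id[v == max(v)]
  })
  names(per_metric) <- metrics
  tab <- do.call(rbind, lapply(metrics, function(m) {
    ids <- per_metric[[m]]
    if (!length(ids)) return(NULL)
    data.frame(metric = m, node = ids, value = max(net$nodes[[m]]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(tab))
    tab <- data.frame(metric = character(0), node = character(0),
                      value = numeric(0), stringsAsFactors = FALSE)
  list(per_metric = per_metric, table = tab)
}
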