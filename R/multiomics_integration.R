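#' Procrustes concordance test between two ordinations (PROTEST)
#'
#' Both configurations are centred and scaled to unit sum of squares, the
#' optimal rotation (reflections allowed) is obtained from the singular value
#' decomposition of the cross-product, and the residual m2 = 1 - (sum of
#' singular values)^2 measures discordance. Significance is assessed by
#' permuting the sample rows of the second configuration and counting
#' permuted m2 values at or below the observed one (add-one convention).
#'
#' @param ordA,ordB Ordinations (\code{pcoa_ordination}, or any matrix of
#'   sample coordinates with sample rownames) over the same samples.
#' @param n_axes Number of leading axes compared (default 2).
#' @param n_permutations Permutations (default 999).
#' @param seed Optional integer seed.
#' @return List of class \code{procrustes_result}: \code{m2},
#'   \code{t_stat} = sqrt(1 - m2), \code{p}, \code{n_permutations},
#'   \code{n_axes}.
#' @export
procrustes_test <- function(ordA, ordB, n_axes = 2, n_permutations = 999,
                            seed = NULL) {
  X <- ordination_coords(ordA)
  Y <- ordination_coords(ordB)
  if (is.null(rownames(X)) || is.null(rownames(Y)))
    stop("ordination coordinates must carry sample rownames")
  if (!setequal(rownames(X), rownames(Y))) {
    onlyA <- setdiff(rownames(X), rownames(Y))
    onlyB <- setdiff(rownames(Y), rownames(X))
    stop("sample sets differ between ordinations; only in A: ",
         paste(onlyA, collapse = ", "), "; only in B: ",
         paste(onlyB, collapse = ", "))
  }
  Y <- Y[rownames(X), , drop = FALSE]
  if (n_axes > ncol(X) || n_axes > ncol(Y))
    stop("n_axes exceeds available axes")
  X <- X[, seq_len(n_axes), drop = FALSE]
  Y <- Y[, seq_len(n_axes), drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  Xs <- procrustes_prescale(X)
  Ys <- procrustes_prescale(Y)
  m2_obs <- procrustes_m2(Xs, Ys)
  n <- nrow(Xs)
  hits <- 0L
  for (b in seq_len(n_permutations)) {
    if (procrustes_m2(Xs, Ys[sample.int(n), , drop = FALSE]) <= m2_obs)
      hits <- hits + 1L
  }
  structure(list(m2 = m2_obs, t_stat = sqrt(max(0, 1 - m2_obs)),
                 p = (1 + hits) / (n_permutations + 1),
                 n_permutations = n_permutations, n_axes = n_axes),
            class = "procrustes_result")
}

ordination_coords <- function(ord) {
  if (inherits(ord, "pcoa_ordination")) return(ord$coordinates)
  if (is.matrix(ord)) return(ord)
  stop("cannot extract coordinates from object of class ",
       paste(class(ord), collapse = "/"))
}

procrustes_prescale <- function(X) {
  X <- scale(X, center = TRUE, scale = FALSE)
  ss <- sum(X^2)
  if (ss == 0) stop("degenerate (constant) configuration")
  X / sqrt(ss)
}

# m2 between two centred unit-sum-of-squares configurations
procrustes_m2 <- function(Xs, Ys) {
  sv <- svd(crossprod(Xs, Ys))$d
  max(0, 1 - sum(sv)^2)
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("Procrustes: m2 = %.4f, t = %.4f, p = %.4g (%d permutations, %d axes)\n",
              x$m2, x$t_stat, x$p, x$n_permutations, x$n_axes))
  invisible(x)
}

# Spearman rho and p between the columns of two matrices (samples in rows),
# pairwise-complete over missing values.
cross_spearman <- function(A, B) {
  rho <- suppressWarnings(stats::cor(A, B, method = "spearman",
                                     use = "pairwise.complete.obs"))
  nmat <- crossprod(!is.na(A), !is.na(B))
  r <- pmin(pmax(rho, -1), 1)
  tstat <- r * sqrt((nmat - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = pmax(nmat - 2, 1))
  p[!is.na(r) & abs(r) >= 1] <- 0
  list(rho = rho, p = p, n = nmat)
}

#' Taxon-gene-trait correlation network
#'
#' Builds the typed multi-omics association network: Spearman correlations
#' are computed for every taxon-gene, taxon-trait and gene-trait pair over
#' the shared samples. Taxon-gene edges are kept when rho > \code{r_min} and
#' p < \code{alpha} (strict, positive association); edges involving a trait
#' are kept when |rho| > \code{trait_r_min} and p < \code{trait_alpha}.
#'
#' @param taxa Relative-abundance matrix restricted to the selected key taxa
#'   (features x samples).
#' @param genes Normalised expression matrix restricted to the selected genes
#'   (features x samples).
#' @param traits Trait data.frame (\code{sample_id} plus numeric columns);
#'   may be \code{NULL} to skip trait edges. Missing trait values are handled
#'   pairwise-complete.
#' @param r_min,alpha Thresholds for taxon-gene edges (defaults 0.8, 0.01).
#' @param trait_r_min,trait_alpha Thresholds for trait edges (defaults 0.05,
#'   0.05 on |rho|).
#' @return List of class \code{omics_link_network}: \code{nodes} (id, type)
#'   and \code{edges} (from, to, type, rho, p).
#' @export
omics_network <- function(taxa, genes, traits = NULL,
                          r_min = 0.8, alpha = 0.01,
                          trait_r_min = 0.05, trait_alpha = 0.05) {
  shared <- intersect(colnames(taxa), colnames(genes))
  if (!is.null(traits)) shared <- intersect(shared, traits$sample_id)
  if (length(shared) < 5L) stop("fewer than 5 shared samples across matrices")
  Tm <- t(taxa[, shared, drop = FALSE])
  Gm <- t(genes[, shared, drop = FALSE])
  edges <- list()
  tg <- cross_spearman(Tm, Gm)
  sel <- which(!is.na(tg$rho) & tg$rho > r_min & tg$p < alpha, arr.ind = TRUE)
  if (nrow(sel))
    edges$tg <- data.frame(from = rownames(tg$rho)[sel[, 1]],
                           to = colnames(tg$rho)[sel[, 2]],
                           type = "taxon-gene",
                           rho = tg$rho[sel], p = tg$p[sel],
                           stringsAsFactors = FALSE)
  trait_names <- character(0)
  if (!is.null(traits)) {
    W <- as.matrix(traits[match(shared, traits$sample_id), -1, drop = FALSE])
    rownames(W) <- shared
    trait_names <- colnames(W)
    for (blk in list(list(Tm, "taxon-trait"), list(Gm, "gene-trait"))) {
      cs <- cross_spearman(blk[[1]], W)
      sel <- which(!is.na(cs$rho) & abs(cs$rho) > trait_r_min &
                     cs$p < trait_alpha, arr.ind = TRUE)
      if (nrow(sel))
        edges[[blk[[2]]]] <- data.frame(from = rownames(cs$rho)[sel[, 1]],
                                        to = colnames(cs$rho)[sel[, 2]],
                                        type = blk[[2]],
                                        rho = cs$rho[sel], p = cs$p[sel],
                                        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, unname(edges)) else
    data.frame(from = character(0), to = character(0), type = character(0),
               rho = numeric(0), p = numeric(0), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  nodes <- data.frame(
    id = c(rownames(taxa), rownames(genes), trait_names),
    type = c(rep("taxon", nrow(taxa)), rep("gene", nrow(genes)),
             rep("trait", length(trait_names))),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 params = list(r_min = r_min, alpha = alpha,
                               trait_r_min = trait_r_min,
                               trait_alpha = trait_alpha)),
            class = "omics_link_network")
}

#' Trait-feature correlation screen
#'
#' Pearson and Spearman correlation of every feature against every trait,
#' with the pass rule p < \code{alpha} and |r| > \code{cor_min} (strict, on
#' the Pearson coefficient). Missing trait values are dropped pairwise.
#'
#' @param features Matrix, features x samples.
#' @param traits Trait data.frame (\code{sample_id} + numeric columns).
#' @param cor_min Minimum absolute correlation (default 0.05, strict).
#' @param alpha Significance level (default 0.05).
#' @return data.frame: \code{feature_id}, \code{trait}, \code{r_pearson},
#'   \code{p_pearson}, \code{r_spearman}, \code{p_spearman}, \code{pass},
#'   \code{constant} (TRUE when the pair had no variance).
#' @export
trait_feature_correlation <- function(features, traits, cor_min = 0.05,
                                      alpha = 0.05) {
  shared <- intersect(colnames(features), traits$sample_id)
  if (length(shared) < 5L) stop("fewer than 5 shared samples")
  Fm <- t(features[, shared, drop = FALSE])
  W <- as.matrix(traits[match(shared, traits$sample_id), -1, drop = FALSE])
  out <- expand.grid(feature_id = colnames(Fm), trait = colnames(W),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rp <- suppressWarnings(stats::cor(Fm, W, use = "pairwise.complete.obs"))
  nmat <- crossprod(!is.na(Fm), !is.na(W))
  tstat <- rp * sqrt((nmat - 2) / pmax(1 - pmin(rp^2, 1), 1e-300))
  pp <- 2 * stats::pt(-abs(tstat), df = pmax(nmat - 2, 1))
  cs <- cross_spearman(Fm, W)
  out$r_pearson <- as.vector(rp)
  out$p_pearson <- as.vector(pp)
  out$r_spearman <- as.vector(cs$rho)
  out$p_spearman <- as.vector(cs$p)
  out$constant <- is.na(out$r_pearson)
  out$pass <- !out$constant & out$p_pearson < alpha &
    abs(out$r_pearson) > cor_min
  out
}
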