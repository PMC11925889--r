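#' Alpha diversity: observed features and Shannon index
#'
#' @param counts Count matrix (features x samples); per-sample totals must be
#'   positive.
#' @param log_base Logarithm base for the Shannon index; \code{exp(1)}
#'   (default) or \code{2}.
#' @return data.frame with columns \code{sample_id}, \code{observed},
#'   \code{shannon}; the base is recorded as attribute \code{"log_base"}.
#' @export
alpha_diversity <- function(counts, log_base = exp(1)) {
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  observed <- colSums(counts > 0)
  shannon <- vegan::diversity(t(counts), index = "shannon", base = log_base)
  out <- data.frame(sample_id = colnames(counts),
                    observed = as.integer(observed),
                    shannon = as.numeric(shannon),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "log_base") <- log_base
  out
}

#' Bray-Curtis dissimilarity between samples
#'
#' d(x, y) = sum |x_i - y_i| / sum (x_i + y_i) over features, for each pair
#' of sample columns. Values lie in [0, 1] and the result is symmetric with a
#' zero diagonal.
#'
#' @param x Count or relative-abundance matrix (features x samples).
#' @return Symmetric numeric matrix (samples x samples) with dimnames.
#' @export
bray_curtis <- function(x) {
  if (ncol(x) < 2L) stop("need at least 2 samples")
  zero <- colSums(x) == 0
  if (sum(zero) >= 2L)
    stop("Bray-Curtis undefined between all-zero samples: ",
         paste(colnames(x)[zero], collapse = ", "))
  d <- as.matrix(vegan::vegdist(t(x), method = "bray"))
  dimnames(d) <- list(colnames(x), colnames(x))
  d
}

#' Principal coordinate analysis (classical metric MDS)
#'
#' Gower double-centering of the squared distance matrix followed by
#' eigendecomposition. Coordinates are returned for axes with positive
#' eigenvalues (eigenvector scaled by the square root of its eigenvalue);
#' negative eigenvalues are reported, not corrected.
#'
#' @param d Symmetric distance matrix (samples x samples).
#' @param tol Symmetry tolerance.
#' @return List of class \code{pcoa_ordination}: \code{coordinates} (samples
#'   x positive axes), \code{eigenvalues} (all, descending),
#'   \code{proportion_explained} (over positive eigenvalues),
#'   \code{negative_eigenvalues} (count and total magnitude).
#' @export
pcoa <- function(d, tol = 1e-8) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > tol) stop("distance matrix is asymmetric beyond tolerance")
  n <- nrow(d)
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  d2 <- d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% d2 %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  ev <- e$values
  pos <- ev > max(ev, 0) * 1e-12 & ev > 0
  prop <- rep(0, length(ev))
  if (any(pos)) prop[pos] <- ev[pos] / sum(ev[pos])
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(ev[pos]), sum(pos))
  rownames(coords) <- ids
  if (ncol(coords)) colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(coordinates = coords,
                 eigenvalues = ev,
                 proportion_explained = prop[pos],
                 negative_eigenvalues = list(count = sum(ev < -tol),
                                             total_magnitude = -sum(ev[ev < -tol]))),
            class = "pcoa_ordination")
}

#' Principal component analysis as an ordination
#'
#' Thin wrapper over \code{\link[stats]{prcomp}} on samples-in-rows data,
#' returning the same structure as \code{\link{pcoa}} so either can feed the
#' Procrustes test.
#'
#' @param x Matrix with features as rows and samples as columns (e.g. log
#'   expression); transposed internally.
#' @param center,scale. Passed to \code{prcomp}.
#' @return A \code{pcoa_ordination} with PCA scores as coordinates.
#' @export
pca_ordination <- function(x, center = TRUE, scale. = FALSE) {
  pr <- stats::prcomp(t(x), center = center, scale. = scale.)
  ev <- pr$sdev^2
  structure(list(coordinates = pr$x,
                 eigenvalues = ev,
                 proportion_explained = ev / sum(ev),
                 negative_eigenvalues = list(count = 0L, total_magnitude = 0)),
            class = "pcoa_ordination")
}

#' One-way PERMANOVA (adonis-style permutation test)
#'
#' Partitions the total sum of squared inter-sample distances into between-
#' and within-group components and tests the pseudo-F statistic by permuting
#' group labels. SS_total = (1/n) sum_{i<j} d_ij^2; SS_within = sum over
#' groups g of (1/n_g) sum_{i<j in g} d_ij^2; pseudo-F =
#' (SS_between/(g-1)) / (SS_within/(n-g)). The permutation p-value uses the
#' add-one convention and so never returns 0.
#'
#' @param d Distance matrix (samples x samples).
#' @param meta Sample metadata; every sample of \code{d} must have a group
#'   and every group at least 2 samples.
#' @param n_permutations Number of label permutations (default 999).
#' @param seed Optional integer seed for the permutations.
#' @return List of class \code{permanova_result}: \code{pseudo_F}, \code{R2},
#'   \code{p}, \code{n_permutations}, \code{seed}, \code{df}.
#' @export
permanova <- function(d, meta, n_permutations = 999, seed = NULL) {
  d <- as.matrix(d)
  meta <- join_metadata(d, meta)
  g <- meta$group
  sizes <- table(g)
  if (length(sizes) < 2L) stop("PERMANOVA needs at least 2 groups")
  if (any(sizes < 2L))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(d)
  k <- length(sizes)
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  gi <- as.integer(g)
  ng <- as.numeric(sizes)
  ss_within <- function(idx) {
    # W: n x k 0/1 membership; within-group squared distances via quadratic form
    W <- matrix(0, n, k)
    W[cbind(seq_len(n), idx)] <- 1
    sum(colSums((d2 %*% W) * W) / (2 * ng))
  }
  f_of_ssw <- function(ssw) ((ss_total - ssw) / (k - 1)) / (ssw / (n - k))
  ssw_obs <- ss_within(gi)
  f_obs <- f_of_ssw(ssw_obs)
  r2 <- (ss_total - ssw_obs) / ss_total
  hits <- 0L
  for (b in seq_len(n_permutations)) {
    if (f_of_ssw(ss_within(gi[sample.int(n)])) >= f_obs) hits <- hits + 1L
  }
  p <- (1 + hits) / (n_permutations + 1)
  structure(list(pseudo_F = f_obs, R2 = r2, p = p,
                 n_permutations = n_permutations, seed = seed,
                 df = c(between = k - 1L, within = n - k)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4f (df %d, %d), R2 = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$df[1], x$df[2], x$R2, x$p, x$n_permutations))
  invisible(x)
}
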