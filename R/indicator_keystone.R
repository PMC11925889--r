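#' Point-biserial indicator-species analysis
#'
#' For every feature, computes the point-biserial correlation (Pearson
#' correlation against a 0/1 membership vector) with every non-empty
#' combination of groups up to \code{max_combination_size}, and reports the
#' combination maximising the correlation. Significance is assessed by
#' permuting sample labels and recomputing the maximised statistic
#' (a max-statistic null, which accounts for the selection of the best
#' combination). A feature is an indicator when its best correlation is
#' positive and the permutation p-value falls below \code{alpha}.
#'
#' @param rel Relative-abundance (or count) matrix, features x samples.
#' @param meta Sample metadata.
#' @param max_combination_size Largest group-combination searched; default
#'   \code{nlevels(group) - 1} (a feature "indicating" every group carries no
#'   information).
#' @param n_permutations Label permutations for the max-statistic null.
#' @param alpha Significance level.
#' @param seed Optional integer seed.
#' @return data.frame with one row per feature: \code{feature_id},
#'   \code{group_combination} (group names joined by \code{+}), \code{r_pb},
#'   \code{p}, \code{significant}, \code{zero_variance}.
#' @export
indicator_analysis <- function(rel, meta, max_combination_size = NULL,
                               n_permutations = 999, alpha = 0.05,
                               seed = NULL) {
  meta <- join_metadata(rel, meta)
  g <- meta$group
  if (nlevels(g) < 2L) stop("indicator analysis needs at least 2 groups")
  if (is.null(max_combination_size)) max_combination_size <- nlevels(g) - 1L
  max_combination_size <- min(max_combination_size, nlevels(g) - 1L)
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(rel)
  X <- t(rel)                                   # n x F
  sds <- apply(X, 2L, stats::sd)
  zero_var <- sds == 0 | !is.finite(sds)
  Xs <- scale(X)                                # zero-variance cols become NaN
  Xs[, zero_var] <- 0
  combos <- group_combinations(levels(g), max_combination_size)
  D <- vapply(combos, function(set) as.numeric(g %in% set), numeric(n))
  Ds <- scale(D)
  r_obs <- crossprod(Xs, Ds) / (n - 1)          # F x K
  best_k <- max.col(r_obs, ties.method = "first")
  best_r <- r_obs[cbind(seq_len(nrow(r_obs)), best_k)]
  # max-statistic permutation null: permute sample labels, track per-feature max
  hits <- integer(nrow(r_obs))
  chunk <- 200L
  done <- 0L
  while (done < n_permutations) {
    b <- min(chunk, n_permutations - done)
    Dall <- matrix(0, n, ncol(Ds) * b)
    for (j in seq_len(b)) {
      Dall[, (j - 1L) * ncol(Ds) + seq_len(ncol(Ds))] <- Ds[sample.int(n), ]
    }
    R <- crossprod(Xs, Dall) / (n - 1)
    perm_max <- matrix(-Inf, nrow(r_obs), b)
    for (kk in seq_len(ncol(Ds))) {
      perm_max <- pmax(perm_max, R[, (seq_len(b) - 1L) * ncol(Ds) + kk, drop = FALSE])
    }
    hits <- hits + rowSums(perm_max >= matrix(best_r, nrow(r_obs), b))
    done <- done + b
  }
  p <- (1 + hits) / (n_permutations + 1)
  p[zero_var] <- 1
  out <- data.frame(
    feature_id = rownames(rel),
    group_combination = vapply(combos[best_k], paste, character(1), collapse = "+"),
    r_pb = best_r,
    p = p,
    significant = !zero_var & p < alpha & best_r > 0,
    zero_variance = zero_var,
    stringsAsFactors = FALSE, row.names = NULL)
  out$group_combination[zero_var] <- NA_character_
  out$r_pb[zero_var] <- NA_real_
  attr(out, "n_permutations") <- n_permutations
  attr(out, "alpha") <- alpha
  attr(out, "max_combination_size") <- max_combination_size
  out
}

group_combinations <- function(groups, max_size) {
  combos <- list()
  for (size in seq_len(max_size)) {
    cc <- utils::combn(groups, size, simplify = FALSE)
    combos <- c(combos, cc)
  }
  combos
}

#' Specificity-occupancy key-species calling
#'
#' For each feature and group, specificity is the feature's mean relative
#' abundance in that group divided by the sum of its group means (rows sum to
#' 1 over groups), and occupancy is the fraction of the group's samples in
#' which the feature is present. A feature is a key species for a group when
#' both exceed \code{tau} (strictly).
#'
#' @param rel Relative-abundance matrix, features x samples.
#' @param meta Sample metadata (>= 2 groups).
#' @param tau Threshold applied to both specificity and occupancy
#'   (default 0.7, strict inequality).
#' @param presence_threshold Abundance above which a feature counts as
#'   present (default 0).
#' @return data.frame with columns \code{feature_id}, \code{group},
#'   \code{specificity}, \code{occupancy}, \code{key}. Features absent from
#'   every sample are excluded; their ids are attached as attribute
#'   \code{"excluded_features"}.
#' @export
specificity_occupancy <- function(rel, meta, tau = 0.7, presence_threshold = 0) {
  meta <- join_metadata(rel, meta)
  g <- meta$group
  if (nlevels(g) < 2L) stop("specificity-occupancy needs at least 2 groups")
  groups <- levels(g)
  gm <- vapply(groups, function(lev) rowMeans(rel[, g == lev, drop = FALSE]),
               numeric(nrow(rel)))                       # F x G group means
  occ <- vapply(groups, function(lev)
    rowMeans(rel[, g == lev, drop = FALSE] > presence_threshold),
    numeric(nrow(rel)))
  if (!is.matrix(gm)) {   # single-feature table: vapply drops to a vector
    gm <- matrix(gm, nrow = 1L, dimnames = list(rownames(rel), groups))
    occ <- matrix(occ, nrow = 1L, dimnames = list(rownames(rel), groups))
  }
  tot <- rowSums(gm)
  absent <- tot == 0
  spec <- gm / ifelse(tot == 0, NA_real_, tot)
  keep <- !absent
  out <- data.frame(
    feature_id = rep(rownames(rel)[keep], times = length(groups)),
    group = rep(groups, each = sum(keep)),
    specificity = as.vector(spec[keep, , drop = FALSE]),
    occupancy = as.vector(occ[keep, , drop = FALSE]),
    stringsAsFactors = FALSE, row.names = NULL)
  out$key <- out$specificity > tau & out$occupancy > tau
  attr(out, "tau") <- tau
  attr(out, "excluded_features") <- rownames(rel)[absent]
  out
}
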