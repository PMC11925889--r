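#' TMM-normalised counts per million
#'
#' cpm = 1e6 * (count + pseudocount) / (library_size * factor + 1). The
#' pseudocount keeps zero counts finite on the log scale; the +1 in the
#' denominator keeps the transform defined for empty libraries.
#'
#' @param counts Count matrix (features x samples).
#' @param factors TMM factors from \code{\link{tmm_factors}}; factors of 1
#'   are used when \code{NULL}.
#' @param pseudocount Added to every count (default 0.5).
#' @return Numeric matrix of CPM values, same shape as \code{counts}.
#' @export
normalized_cpm <- function(counts, factors = NULL, pseudocount = 0.5) {
  if (is.null(factors)) {
    factors <- rep(1, ncol(counts))
    names(factors) <- colnames(counts)
  }
  if (!all(colnames(counts) %in% names(factors)))
    stop("TMM factors missing for sample(s): ",
         paste(setdiff(colnames(counts), names(factors)), collapse = ", "))
  f <- factors[colnames(counts)]
  eff <- colSums(counts) * f
  sweep(counts + pseudocount, 2L, eff + 1, "/") * 1e6
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: q_(i) = min_{j >= i} (m/j) p_(j), clipped at 1 and
#' mapped back to the input order.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Vector of adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

# Method-of-moments common dispersion on library-size-equalised counts.
# For each feature, pooled within-group moments give
# phi = (s^2 - mu) / mu^2 under NB(mu, phi); the common value is the
# median over features with positive estimates (floored at 1e-4).
estimate_common_dispersion <- function(z, groups) {
  phis <- apply(z, 1L, function(y) {
    num <- 0; den <- 0
    for (lev in levels(groups)) {
      yi <- y[groups == lev]
      m <- mean(yi)
      if (m <= 0) next
      num <- num + (stats::var(yi) - m) * (length(yi) - 1)
      den <- den + m^2 * (length(yi) - 1)
    }
    if (den <= 0) return(NA_real_)
    num / den
  })
  phi <- stats::median(phis[is.finite(phis)], na.rm = TRUE)
  max(phi, 1e-4)
}

# Exact conditional NB test for one feature: given group sums sA (nA samples)
# and sB (nB samples) of equalised counts and common dispersion phi, the
# conditional distribution of the group-A sum given the total is evaluated
# over all splits; two-sided p sums the probabilities of outcomes no more
# likely than the observed one.
nb_exact_pvalue <- function(sA, sB, nA, nB, phi) {
  s <- sA + sB
  if (s == 0) return(NA_real_)
  mu <- s / (nA + nB)
  a <- 0:s
  logp <- stats::dnbinom(a, size = nA / phi, mu = nA * mu, log = TRUE) +
    stats::dnbinom(s - a, size = nB / phi, mu = nB * mu, log = TRUE)
  logp <- logp - max(logp)
  pr <- exp(logp)
  pr <- pr / sum(pr)
  obs <- pr[sA + 1]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]))
}

#' Two-group differential feature test
#'
#' Tests each feature for a difference between two groups on TMM-normalised
#' counts. Two methods are provided and tagged in the output: an exact
#' conditional negative-binomial test with a common method-of-moments
#' dispersion (\code{"nb_exact"}), and a distribution-free label-permutation
#' test on the difference of group mean log2-CPM (\code{"permutation"}).
#' log2 fold changes are computed from mean CPMs (pseudocount included).
#'
#' Significance follows the mode: \code{"gene"} calls a feature when
#' |log2FC| > \code{lfc_min} and p < \code{alpha}; \code{"microbiome"} calls
#' it when the BH-adjusted q < \code{fdr_alpha}.
#'
#' @param counts Count matrix (features x samples).
#' @param meta Sample metadata.
#' @param pair Character vector of two group names \code{c(A, B)}; fold
#'   changes are B over A.
#' @param method \code{"nb_exact"} (default) or \code{"permutation"}.
#' @param lfc_min,alpha Gene-mode thresholds (strict inequalities).
#' @param fdr_alpha Microbiome-mode FDR threshold.
#' @param mode \code{"gene"} or \code{"microbiome"}.
#' @param n_permutations Permutations for the permutation method.
#' @param pseudocount CPM pseudocount.
#' @param seed Optional seed (permutation method).
#' @return data.frame: \code{feature_id}, \code{log2FC}, \code{p}, \code{q},
#'   \code{significant}, \code{method}. Features that are all-zero in both
#'   groups are excluded; their ids are in attribute
#'   \code{"excluded_features"}.
#' @export
differential_test <- function(counts, meta, pair,
                              method = c("nb_exact", "permutation"),
                              lfc_min = 1, alpha = 0.05, fdr_alpha = 0.05,
                              mode = c("gene", "microbiome"),
                              n_permutations = 999, pseudocount = 0.5,
                              seed = NULL) {
  method <- match.arg(method)
  mode <- match.arg(mode)
  if (length(pair) != 2L) stop("pair must name exactly two groups")
  meta <- join_metadata(counts, meta)
  keep_s <- meta$group %in% pair
  if (sum(meta$group == pair[1]) < 2L || sum(meta$group == pair[2]) < 2L)
    stop("both groups need at least 2 samples")
  counts <- counts[, keep_s, drop = FALSE]
  grp <- factor(as.character(meta$group[keep_s]), levels = pair)
  if (!is.null(seed)) set.seed(seed)

  nonzero <- rowSums(counts) > 0
  excluded <- rownames(counts)[!nonzero]
  counts <- counts[nonzero, , drop = FALSE]

  fac <- tmm_factors(counts)
  cpm <- normalized_cpm(counts, fac, pseudocount = pseudocount)
  idxA <- grp == pair[1]; idxB <- grp == pair[2]
  log2fc <- log2(rowMeans(cpm[, idxB, drop = FALSE]) /
                 rowMeans(cpm[, idxA, drop = FALSE]))

  if (method == "nb_exact") {
    eff <- colSums(counts) * fac[colnames(counts)]
    z <- round(sweep(counts, 2L, mean(eff) / eff, "*"))
    phi <- estimate_common_dispersion(z, grp)
    sA <- rowSums(z[, idxA, drop = FALSE])
    sB <- rowSums(z[, idxB, drop = FALSE])
    p <- vapply(seq_len(nrow(z)), function(i)
      nb_exact_pvalue(sA[i], sB[i], sum(idxA), sum(idxB), phi), numeric(1))
  } else {
    lcpm <- log2(cpm)
    stat_obs <- rowMeans(lcpm[, idxB, drop = FALSE]) -
      rowMeans(lcpm[, idxA, drop = FALSE])
    nB <- sum(idxB); nS <- ncol(lcpm)
    hits <- integer(nrow(lcpm))
    for (b in seq_len(n_permutations)) {
      pb <- sample.int(nS, nB)
      stat_p <- rowMeans(lcpm[, pb, drop = FALSE]) -
        rowMeans(lcpm[, -pb, drop = FALSE])
      hits <- hits + (abs(stat_p) >= abs(stat_obs))
    }
    p <- (1 + hits) / (n_permutations + 1)
  }
  q <- bh_adjust(p)
  significant <- if (mode == "gene") {
    !is.na(p) & abs(log2fc) > lfc_min & p < alpha
  } else {
    !is.na(q) & q < fdr_alpha
  }
  out <- data.frame(feature_id = rownames(counts), log2FC = log2fc,
                    p = p, q = q, significant = significant,
                    method = method, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "excluded_features") <- excluded
  attr(out, "mode") <- mode
  attr(out, "pair") <- pair
  out
}
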