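#' Convert counts to per-sample relative abundances
#'
#' @param counts Count matrix (features x samples).
#' @return Matrix of the same shape whose columns each sum to 1.
#' @export
to_relative_abundance <- function(counts) {
  totals <- colSums(counts)
  zero <- colnames(counts)[totals == 0]
  if (length(zero))
    stop("sample(s) with zero total count: ", paste(zero, collapse = ", "))
  sweep(counts, 2L, totals, "/")
}

#' Prevalence and total-abundance feature filter
#'
#' Retains features that are present (relative abundance > 0) in at least
#' \code{min_group_prevalence} of the samples of at least one group, and whose
#' relative abundance summed over all samples exceeds
#' \code{min_total_relabund}. Feature order is preserved; applying the filter
#' twice is a no-op.
#'
#' @param rel Relative-abundance matrix (features x samples).
#' @param meta Sample metadata (see \code{\link{sample_metadata}}).
#' @param min_group_prevalence Within-group prevalence threshold in [0,1];
#'   default 0.20.
#' @param min_total_relabund Threshold on the sum of a feature's relative
#'   abundances over all samples; default 0.025 (i.e. 2.5%).
#' @return The row-subset of \code{rel} passing both rules.
#' @export
prevalence_filter <- function(rel, meta,
                              min_group_prevalence = 0.20,
                              min_total_relabund = 0.025) {
  if (min_group_prevalence < 0 || min_group_prevalence > 1)
    stop("min_group_prevalence must be in [0,1]")
  if (min_total_relabund < 0 || min_total_relabund > 1)
    stop("min_total_relabund must be in [0,1]")
  meta <- join_metadata(rel, meta)
  groups <- levels(meta$group)
  prev_ok <- rep(FALSE, nrow(rel))
  for (g in groups) {
    idx <- meta$group == g
    prev <- rowMeans(rel[, idx, drop = FALSE] > 0)
    prev_ok <- prev_ok | (prev >= min_group_prevalence)
  }
  total_ok <- rowSums(rel) > min_total_relabund
  rel[prev_ok & total_ok, , drop = FALSE]
}

#' TMM scaling factors (trimmed mean of M-values)
#'
#' Computes between-sample scaling factors by the weighted trimmed mean of
#' log-fold-changes (M-values) against a reference sample, the standard
#' library-composition normalization for count libraries. Features that are
#' zero in either the sample or the reference are excluded pairwise; M- and
#' A-values are double-trimmed and the surviving M-values averaged with
#' inverse-asymptotic-variance weights. Factors are rescaled to geometric
#' mean 1.
#'
#' @param counts Count matrix (features x samples), at least 2 samples.
#' @param m_trim Fraction of M-values trimmed from each tail (default 0.30).
#' @param a_trim Fraction of A-values trimmed from each tail (default 0.05).
#' @param ref_sample Optional reference sample id; by default the sample whose
#'   upper-quartile/library-size ratio is closest to the mean of that ratio.
#' @return Named numeric vector of positive factors (one per sample), with
#'   attributes \code{"ref_sample"}, \code{"m_trim"}, \code{"a_trim"}.
#' @export
tmm_factors <- function(counts, m_trim = 0.30, a_trim = 0.05, ref_sample = NULL) {
  if (ncol(counts) < 2L) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample(s) with zero library size")
  f75 <- apply(counts, 2L, function(y) stats::quantile(y, 0.75)) / lib
  if (is.null(ref_sample)) {
    ref <- which.min(abs(f75 - mean(f75)))
  } else {
    ref <- match(ref_sample, colnames(counts))
    if (is.na(ref)) stop("reference sample not found: ", ref_sample)
  }
  yr <- counts[, ref]
  nr <- lib[ref]
  fac <- vapply(seq_len(ncol(counts)), function(k) {
    yk <- counts[, k]
    nk <- lib[k]
    keep0 <- yk > 0 & yr > 0
    if (!any(keep0)) {
      warning("sample '", colnames(counts)[k],
              "' shares no nonzero features with the reference; factor set to 1")
      return(1)
    }
    M <- log2((yk[keep0] / nk) / (yr[keep0] / nr))
    A <- 0.5 * log2((yk[keep0] / nk) * (yr[keep0] / nr))
    v <- (nk - yk[keep0]) / (nk * yk[keep0]) + (nr - yr[keep0]) / (nr * yr[keep0])
    fin <- is.finite(M) & is.finite(A) & A > -1e10
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * m_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * a_trim) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f <- sum(M[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
    if (!is.finite(f)) f <- 0
    2^f
  }, numeric(1))
  fac <- fac / exp(mean(log(fac)))
  names(fac) <- colnames(counts)
  attr(fac, "ref_sample") <- colnames(counts)[ref]
  attr(fac, "m_trim") <- m_trim
  attr(fac, "a_trim") <- a_trim
  fac
}

#' Six-way abundance-class partition (RT/AT/MT/CRT/CAT/CRAT)
#'
#' Classifies every feature from the minimum (m) and maximum (M) of its
#' per-sample relative abundance, using closed bounds at the rare and
#' abundant cutoffs:
#' \itemize{
#'   \item RT (rare): M <= rare_cut in all samples;
#'   \item AT (abundant): m >= abundant_cut in all samples;
#'   \item MT (moderate): rare_cut < m and M < abundant_cut;
#'   \item CRT (conditionally rare): m <= rare_cut, rare_cut < M < abundant_cut;
#'   \item CAT (conditionally abundant): rare_cut < m < abundant_cut, M >= abundant_cut;
#'   \item CRAT (conditionally rare or abundant): m <= rare_cut and M >= abundant_cut.
#' }
#' These six predicates partition the (m, M) plane: every feature receives
#' exactly one label.
#'
#' @param rel Relative-abundance matrix (features x samples).
#' @param rare_cut Rare threshold as a proportion (default 0.001, i.e. 0.1%).
#' @param abundant_cut Abundant threshold as a proportion (default 0.01, i.e. 1%).
#' @return data.frame with columns \code{feature_id}, \code{class},
#'   \code{min_ra}, \code{max_ra}, \code{mean_ra}; thresholds attached as
#'   attributes \code{"rare_cut"} and \code{"abundant_cut"}.
#' @export
classify_abundance <- function(rel, rare_cut = 0.001, abundant_cut = 0.01) {
  if (rare_cut >= abundant_cut) stop("rare_cut must be below abundant_cut")
  m <- apply(rel, 1L, min)
  M <- apply(rel, 1L, max)
  cls <- abundance_class(m, M, rare_cut, abundant_cut)
  out <- data.frame(feature_id = rownames(rel), class = cls,
                    min_ra = m, max_ra = M, mean_ra = rowMeans(rel),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "rare_cut") <- rare_cut
  attr(out, "abundant_cut") <- abundant_cut
  out
}

#' Abundance class from per-feature min/max relative abundance
#'
#' Vectorised classification rule underlying \code{\link{classify_abundance}};
#' exposed so the partition property can be checked on an (m, M) grid.
#'
#' @param m,M Numeric vectors of per-feature minimum and maximum relative
#'   abundance (m <= M).
#' @param rare_cut,abundant_cut Class thresholds as proportions.
#' @return Character vector in \{RT, AT, MT, CRT, CAT, CRAT\}.
#' @export
abundance_class <- function(m, M, rare_cut = 0.001, abundant_cut = 0.01) {
  if (any(m > M)) stop("min abundance exceeds max abundance")
  cls <- character(length(m))
  cls[M <= rare_cut] <- "RT"
  cls[m >= abundant_cut] <- "AT"
  cls[m > rare_cut & M < abundant_cut] <- "MT"
  cls[m <= rare_cut & M > rare_cut & M < abundant_cut] <- "CRT"
  cls[m > rare_cut & m < abundant_cut & M >= abundant_cut] <- "CAT"
  cls[m <= rare_cut & M >= abundant_cut] <- "CRAT"
  stopifnot(all(nzchar(cls)))
  cls
}
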