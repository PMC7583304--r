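# Histogram machinery shared by entropy, mutual information and the merit
# function. Bins are equal-width over the observed [min, max] of each
# feature; the maximum value is assigned to the last bin; a constant
# feature occupies a single bin (entropy 0). Logarithms are base 2
# throughout, so all information quantities are in bits.

#' Assign values to equal-width histogram bins
#'
#' @param values finite numeric vector.
#' @param n_b number of bins (>= 1).
#' @return Integer bin indices in `1..n_b`.
#' @export
bin_indices <- function(values, n_b) {
  n_b <- as.integer(n_b)
  if (is.na(n_b) || n_b < 1L) stop("n_b must be >= 1")
  if (length(values) == 0L) stop("empty vector")
  if (!all(is.finite(values))) stop("non-finite values")
  lo <- min(values); hi <- max(values)
  if (hi == lo) return(rep(1L, length(values)))
  idx <- floor((values - lo) / (hi - lo) * n_b) + 1L
  pmin(as.integer(idx), n_b)
}

#' Shannon entropy of a binned feature
#'
#' `H = -sum p_i log2 p_i` over occupied bins of the equal-width histogram
#' (0 log 0 := 0). Bounded by `log2(n_b)`, attained when every bin is
#' equally populated; 0 for a constant feature.
#'
#' @param values finite numeric vector.
#' @param n_b number of equal-width bins.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(values, n_b) {
  idx <- bin_indices(values, n_b)
  p <- tabulate(idx, nbins = as.integer(n_b)) / length(idx)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information between two binned features
#'
#' Joint equal-width histogram using each feature's own bin edges;
#' `I = sum p(i,l) log2( p(i,l) / (p_j(i) p_k(l)) )` with marginals taken
#' from the joint margins, so `I >= 0` and `I(f, f) = H(f)` hold exactly.
#'
#' @param f_j,f_k finite numeric vectors of equal length.
#' @param n_b number of bins per feature.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(f_j, f_k, n_b) {
  if (length(f_j) != length(f_k)) stop("length mismatch")
  bi <- bin_indices(f_j, n_b)
  bl <- bin_indices(f_k, n_b)
  mi_from_bins(bi, bl, as.integer(n_b))
}

mi_from_bins <- function(bi, bl, n_b) {
  joint <- tabulate((bl - 1L) * n_b + bi, nbins = n_b * n_b) / length(bi)
  dim(joint) <- c(n_b, n_b)
  pi_ <- rowSums(joint)
  pl_ <- colSums(joint)
  nz <- which(joint > 0, arr.ind = TRUE)
  p <- joint[nz]
  sum(p * log2(p / (pi_[nz[, 1L]] * pl_[nz[, 2L]])))
}

#' Absolute Pearson / Spearman correlation between two features
#'
#' Redundancy criteria: the absolute value of the coefficient, so perfectly
#' anti-correlated features are as redundant as perfectly correlated ones.
#' Spearman computes Pearson on average ranks (ties averaged). A constant
#' feature has undefined correlation; by documented contract it returns 0
#' with a warning (a constant feature carries no redundancy signal).
#'
#' @param f_j,f_k numeric vectors of equal length >= 2.
#' @return Scalar in \[0, 1\].
#' @export
pearson_abs <- function(f_j, f_k) {
  abs_cor(f_j, f_k, method = "pearson")
}

#' @rdname pearson_abs
#' @export
spearman_abs <- function(f_j, f_k) {
  abs_cor(f_j, f_k, method = "spearman")
}

abs_cor <- function(f_j, f_k, method) {
  if (length(f_j) != length(f_k)) stop("length mismatch")
  if (length(f_j) < 2L) stop("need at least 2 observations")
  if (sd(f_j) == 0 || sd(f_k) == 0) {
    warning("constant feature: correlation undefined, returning 0")
    return(0)
  }
  abs(cor(f_j, f_k, method = method))
}

#' Bin-count rules
#'
#' Resolves the per-stage histogram resolution: an explicit integer, `"n"`
#' (one bin per instance, the entropy-ranking default) or `"sqrt"`
#' (`floor(sqrt(n))`, the square-root choice used during subset
#' optimization).
#'
#' @param rule integer, `"n"`, or `"sqrt"`.
#' @param n number of instances.
#' @return Integer bin count.
#' @export
n_bins_rule <- function(rule, n) {
  if (is.numeric(rule)) {
    nb <- as.integer(rule)
    if (is.na(nb) || nb < 1L) stop("explicit n_bins must be >= 1")
    return(nb)
  }
  switch(match.arg(rule, c("n", "sqrt")),
         n = as.integer(n),
         sqrt = max(1L, as.integer(floor(sqrt(n)))))
}
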