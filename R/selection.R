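#' Configuration of the entropy/correlation feature filter
#'
#' Stage-1 defaults follow the tuned workflow: one histogram bin per
#' instance (`n_bins = "n"`), entropy cutoff at 10% of the maximum
#' (`theta1 = 0.1 * log2(n_bins)`), Spearman correlation with redundancy
#' cutoff `theta2 = 0.8`.
#'
#' @param theta1 entropy cutoff in bits (>= 0), or `NULL` for
#'   `0.1 * log2(n_bins)` resolved at run time.
#' @param theta2 correlation cutoff in \[0, 1\].
#' @param method correlation method, `"spearman"` or `"pearson"`.
#' @param n_bins bin rule: explicit integer, `"n"`, or `"sqrt"`.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(theta1 = NULL, theta2 = 0.8,
                          method = c("spearman", "pearson"),
                          n_bins = "n") {
  method <- match.arg(method)
  if (!is.null(theta1) && (!is.numeric(theta1) || theta1 < 0))
    stop("theta1 must be >= 0")
  if (!is.numeric(theta2) || theta2 < 0 || theta2 > 1)
    stop("theta2 must lie in [0, 1]")
  structure(list(theta1 = theta1, theta2 = theta2, method = method,
                 n_bins = n_bins),
            class = "filter_config")
}

#' Stage 1: entropy ranking and correlation redundancy filtering
#'
#' Removes features with entropy below `theta1`, ranks the survivors by
#' descending entropy (stable: ties keep original column order), then scans
#' greedily keeping a feature iff its absolute correlation with every
#' already-kept feature is below `theta2`. The candidate subset preserves
#' the entropy-sorted order.
#'
#' @param matrix descriptor matrix (numeric, named columns).
#' @param cfg a [filter_config].
#' @return Object of class `feature_subset`: list with `indices` (into the
#'   matrix columns), `names`, `entropy` (per kept feature), `provenance =
#'   "candidate"` and the resolved `config`.
#' @export
rank_and_filter <- function(matrix, cfg = filter_config()) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  n <- nrow(matrix); m <- ncol(matrix)
  nb <- n_bins_rule(cfg$n_bins, n)
  theta1 <- if (is.null(cfg$theta1)) 0.1 * log2(nb) else cfg$theta1
  H <- apply(matrix, 2L, shannon_entropy, n_b = nb)
  keep <- which(H >= theta1)
  if (length(keep) == 0L)
    stop("all ", m, " features fall below the entropy cutoff ",
         signif(theta1, 4), " bits (max observed ", signif(max(H), 4), ")")
  ord <- keep[order(-H[keep])]  # stable: order() keeps original order on ties
  # correlations on rank-transformed copies cached once for Spearman
  X <- matrix[, ord, drop = FALSE]
  if (cfg$method == "spearman") X <- apply(X, 2L, rank)
  selected <- integer(0)
  for (i in seq_along(ord)) {
    if (length(selected) == 0L) { selected <- i; next }
    # a constant column has undefined correlation; contract: treat as 0
    r <- abs(suppressWarnings(cor(X[, i], X[, selected, drop = FALSE])))
    r[is.na(r)] <- 0
    if (all(r < cfg$theta2)) selected <- c(selected, i)
  }
  idx <- unname(ord[selected])
  structure(list(indices = idx,
                 names = colnames(matrix)[idx],
                 entropy = unname(H[idx]),
                 merit = NA_real_,
                 provenance = "candidate",
                 config = list(theta1 = theta1, theta2 = cfg$theta2,
                               method = cfg$method, n_bins = nb)),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat(sprintf("<feature_subset> %d features (%s)", length(x$indices),
              x$provenance))
  if (!is.na(x$merit)) cat(sprintf(", merit %.4f", x$merit))
  cat("\n")
  invisible(x)
}

# Entropy vector and full pairwise mutual-information matrix for a set of
# columns; the cache that makes backward elimination O(passes * |F|^2)
# merit lookups instead of repeated histogramming.
information_cache <- function(matrix, indices, n_b) {
  n_b <- as.integer(n_b)
  bins <- lapply(indices, function(j) bin_indices(matrix[, j], n_b))
  p <- length(indices)
  H <- vapply(bins, function(bi) {
    pr <- tabulate(bi, nbins = n_b) / length(bi)
    pr <- pr[pr > 0]
    -sum(pr * log2(pr))
  }, numeric(1L))
  I <- diag(H, p)
  if (p > 1L) {
    for (a in seq_len(p - 1L)) {
      for (b in seq.int(a + 1L, p)) {
        I[a, b] <- I[b, a] <- mi_from_bins(bins[[a]], bins[[b]], n_b)
      }
    }
  }
  list(H = H, I = I)
}

merit_from_cache <- function(cache, pos, exclude_diagonal = FALSE) {
  p <- length(pos)
  s <- sum(cache$I[pos, pos])
  if (exclude_diagonal) s <- s - sum(diag(cache$I)[pos])
  mean(cache$H[pos]) - s / p^2
}

#' Merit of a feature subset
#'
#' `Phi(F) = mean entropy of F - (1/|F|^2) * sum of pairwise mutual
#' information over all ordered pairs in F`. The literal double sum includes
#' the diagonal `I(f, f) = H(f)` (so a singleton subset has merit 0);
#' `exclude_diagonal = TRUE` gives the off-diagonal-only alternative.
#'
#' @param matrix descriptor matrix.
#' @param indices column indices of the subset (non-empty).
#' @param n_b histogram bins (default square-root choice).
#' @param exclude_diagonal drop the `j = k` terms from the penalty.
#' @return Scalar merit in bits.
#' @export
merit <- function(matrix, indices, n_b = n_bins_rule("sqrt", nrow(matrix)),
                  exclude_diagonal = FALSE) {
  if (length(indices) == 0L) stop("empty feature subset")
  if (any(indices < 1L | indices > ncol(matrix))) stop("indices out of bounds")
  if (anyDuplicated(indices)) stop("duplicate indices")
  cache <- information_cache(matrix, indices, n_b)
  merit_from_cache(cache, seq_along(indices), exclude_diagonal)
}

#' Stage 2: greedy backward elimination maximizing the merit
#'
#' Starting from the full candidate subset, evaluates every single-feature
#' deletion, applies the one with the highest merit if it strictly improves
#' the current merit, and stops otherwise. Entropies and the pairwise
#' mutual-information matrix are computed once and cached, so each deletion
#' evaluation is an O(|F|^2) arithmetic lookup. Ties in deletion gain are
#' broken toward the lowest column index; the procedure is deterministic.
#'
#' @param matrix descriptor matrix.
#' @param candidate a [feature_subset][rank_and_filter] (or an integer
#'   vector of column indices).
#' @param n_b histogram bins (default `floor(sqrt(n))`).
#' @param exclude_diagonal see [merit()].
#' @return A `feature_subset` with `provenance = "optimized"` and its
#'   `merit` filled; the returned merit always equals [merit()] of the
#'   returned indices and is never below the candidate's.
#' @export
optimize_subset <- function(matrix, candidate,
                            n_b = n_bins_rule("sqrt", nrow(matrix)),
                            exclude_diagonal = FALSE) {
  idx <- if (inherits(candidate, "feature_subset")) candidate$indices
         else as.integer(candidate)
  if (length(idx) == 0L) stop("empty candidate subset")
  cache <- information_cache(matrix, idx, n_b)
  pos <- seq_along(idx)  # positions into idx still alive
  current <- merit_from_cache(cache, pos, exclude_diagonal)
  while (length(pos) > 1L) {
    gains <- vapply(seq_along(pos), function(d)
      merit_from_cache(cache, pos[-d], exclude_diagonal), numeric(1L))
    best <- which.max(gains)  # first max: lowest column index wins ties
    if (gains[best] > current) {
      pos <- pos[-best]
      current <- gains[best]
    } else break
  }
  structure(list(indices = unname(idx[pos]),
                 names = colnames(matrix)[idx[pos]],
                 entropy = unname(cache$H[pos]),
                 merit = current,
                 provenance = "optimized",
                 config = list(n_bins = as.integer(n_b),
                               exclude_diagonal = exclude_diagonal)),
            class = "feature_subset")
}

#' Procrustes goodness-of-fit between two descriptor spaces
#'
#' Both matrices (same peptides, same row order) are column-standardized,
#' projected onto their leading principal components, and compared by
#' symmetric Procrustes superimposition (optimal translation, scaling,
#' rotation and reflection). The statistic is the normalized residual sum
#' of squares in \[0, 1\]: 0 means the configurations coincide, 1 that they
#' are maximally dissimilar.
#'
#' @param original,reduced numeric matrices with identical rows.
#' @param n_components principal components to retain (default 50; reduced
#'   with a warning when either matrix has lower rank).
#' @param scale_columns unit-scale columns before PCA (default `TRUE`,
#'   appropriate for descriptor columns on incommensurable scales; use
#'   `FALSE` when both matrices are coordinate configurations in a common
#'   unit, which makes the fit exactly invariant to rotation and uniform
#'   scaling of either configuration).
#' @return List of class `procrustes_result` with `goodness_of_fit` and
#'   `n_components`.
#' @export
procrustes_fit <- function(original, reduced, n_components = 50L,
                           scale_columns = TRUE) {
  if (nrow(original) != nrow(reduced))
    stop("matrices must describe the same peptides (row mismatch)")
  pcs <- function(m) {
    m <- m[, apply(m, 2L, sd) > 0, drop = FALSE]
    prcomp(m, center = TRUE, scale. = scale_columns)$x
  }
  a <- pcs(original); b <- pcs(reduced)
  nc <- min(n_components, ncol(a), ncol(b), nrow(original) - 1L)
  if (nc < n_components)
    warning("rank limits components to ", nc, " (requested ", n_components, ")")
  fit <- vegan::procrustes(a[, seq_len(nc), drop = FALSE],
                           b[, seq_len(nc), drop = FALSE],
                           symmetric = TRUE)
  structure(list(goodness_of_fit = max(0, min(1, fit$ss)),
                 n_components = nc),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("Procrustes goodness-of-fit: %.4f (%d PCs)\n",
              x$goodness_of_fit, x$n_components))
  invisible(x)
}

#' Two-stage unsupervised feature selection
#'
#' Convenience wrapper chaining [rank_and_filter()] (entropy ranking +
#' correlation redundancy filter) and [optimize_subset()] (backward
#' elimination on the merit function with square-root binning).
#'
#' @param matrix descriptor matrix.
#' @param cfg stage-1 [filter_config].
#' @param n_b stage-2 bin count (default `floor(sqrt(n))`).
#' @param exclude_diagonal see [merit()].
#' @return List with `candidate` and `optimized` feature subsets.
#' @export
select_features <- function(matrix, cfg = filter_config(),
                            n_b = n_bins_rule("sqrt", nrow(matrix)),
                            exclude_diagonal = FALSE) {
  cand <- rank_and_filter(matrix, cfg)
  opt <- optimize_subset(matrix, cand, n_b = n_b,
                         exclude_diagonal = exclude_diagonal)
  list(candidate = cand, optimized = opt)
}
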