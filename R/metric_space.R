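#' Build a metric space over selected descriptors
#'
#' Restricts the descriptor matrix to the selected columns and (by default)
#' z-score standardizes them, storing the centering/scaling parameters so
#' that new points can later be embedded in the identical coordinate frame.
#' Distances are Euclidean; `max_distance`, the diameter of the point set,
#' normalizes the similarity transform. The full pairwise distance matrix
#' is never materialized: distances are computed per point on demand, and
#' the diameter in row blocks, so the model scales to tens of thousands of
#' peptides.
#'
#' @param matrix descriptor matrix (rows = peptides).
#' @param subset a [feature_subset][rank_and_filter], integer indices, or
#'   column names; default all columns.
#' @param standardize center and unit-scale columns (default `TRUE`);
#'   zero-variance columns are dropped with a warning.
#' @return Object of class `metric_space`: `points` (n x m'), `center`,
#'   `scale`, `max_distance`, `ids`.
#' @export
build_metric_space <- function(matrix, subset = NULL, standardize = TRUE) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  idx <- if (is.null(subset)) seq_len(ncol(matrix))
         else if (inherits(subset, "feature_subset")) subset$indices
         else if (is.character(subset)) match(subset, colnames(matrix))
         else as.integer(subset)
  if (length(idx) == 0L || anyNA(idx)) stop("invalid or empty feature subset")
  P <- matrix[, idx, drop = FALSE]
  center <- rep(0, ncol(P)); scale <- rep(1, ncol(P))
  if (standardize) {
    center <- colMeans(P)
    scale <- apply(P, 2L, sd)
    zero <- scale == 0
    if (any(zero)) {
      warning("dropping ", sum(zero), " zero-variance column(s): ",
              paste(colnames(P)[zero], collapse = ", "))
      P <- P[, !zero, drop = FALSE]
      center <- center[!zero]; scale <- scale[!zero]
    }
    if (ncol(P) == 0L) stop("no columns left after dropping zero variance")
    P <- sweep(sweep(P, 2L, center), 2L, scale, "/")
  }
  ids <- rownames(matrix)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(P)))
  rownames(P) <- ids
  space <- structure(list(points = P, center = center, scale = scale,
                          feature_names = colnames(P), ids = ids,
                          standardize = standardize,
                          max_distance = NA_real_),
                     class = "metric_space")
  space$max_distance <- space_diameter(space)
  space
}

#' @export
print.metric_space <- function(x, ...) {
  cat(sprintf("<metric_space> %d points in %d dimensions%s, diameter %.4f\n",
              nrow(x$points), ncol(x$points),
              if (x$standardize) " (standardized)" else "",
              x$max_distance))
  invisible(x)
}

# Euclidean distances from point u (index or coordinate vector) to all rows.
space_distances <- function(space, u) {
  P <- space$points
  p <- if (length(u) == 1L && is.numeric(u) && u == round(u) &&
           is.null(dim(u))) P[u, ] else u
  sqrt(pmax(0, rowSums(P * P) - 2 * drop(P %*% p) + sum(p * p)))
}

# Diameter max d(p,q) computed in row blocks (no n x n allocation).
space_diameter <- function(space) {
  P <- space$points
  n <- nrow(P)
  if (n < 2L) return(0)
  sq <- rowSums(P * P)
  blk <- max(1L, min(n, floor(2e6 / n)))
  best <- 0
  for (start in seq(1L, n, by = blk)) {
    rows <- start:min(n, start + blk - 1L)
    d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(P[rows, , drop = FALSE], P)
    best <- max(best, d2)
  }
  sqrt(max(0, best))
}

#' Pairwise similarity in a metric space
#'
#' `sim(u, v) = 1 - d(u, v) / max_distance`: 1 for coincident points, 0 for
#' the farthest pair.
#'
#' @param space a [metric_space][build_metric_space] with >= 2 points.
#' @param u,v point indices (or coordinate vectors on the space's scale).
#' @return Scalar in \[0, 1\].
#' @export
similarity <- function(space, u, v) {
  if (nrow(space$points) < 2L) stop("similarity needs >= 2 points")
  pu <- if (length(u) == 1L) space$points[u, ] else u
  pv <- if (length(v) == 1L) space$points[v, ] else v
  1 - sqrt(sum((pu - pv)^2)) / space$max_distance
}

# Map new descriptor rows into the space's coordinate frame.
space_transform <- function(space, newdata) {
  miss <- setdiff(space$feature_names, colnames(newdata))
  if (length(miss))
    stop("new points lack selected descriptors: ",
         paste(head(miss, 5L), collapse = ", "))
  Q <- newdata[, space$feature_names, drop = FALSE]
  if (space$standardize)
    Q <- sweep(sweep(Q, 2L, space$center), 2L, space$scale, "/")
  Q
}
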