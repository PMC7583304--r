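#' Build a thresholded chemical space network (CSN)
#'
#' Nodes are peptides; an undirected edge joins every pair with pairwise
#' similarity `sim(u, v) >= t`, weighted by that similarity. At `t = 0` the
#' graph is complete (density 1); raising the threshold can only remove
#' edges. Edges are generated in row blocks so no full n x n similarity
#' matrix is held.
#'
#' @param space a [metric_space][build_metric_space].
#' @param t similarity threshold in \[0, 1\].
#' @return An [igraph][igraph::igraph-package] graph with `weight` edge
#'   attribute and graph attributes `kind = "CSN"` and `threshold`.
#' @export
build_csn <- function(space, t) {
  stopifnot(t >= 0, t <= 1)
  n <- nrow(space$points)
  maxd <- space$max_distance
  edges <- vector("list", n)
  for (u in seq_len(n)) {
    if (u == n) break
    d <- space_distances(space, u)[(u + 1L):n]
    s <- 1 - d / maxd
    hit <- which(s >= t)
    if (length(hit))
      edges[[u]] <- cbind(u, u + hit, s[hit])
  }
  el <- do.call(rbind, edges)
  graph_from_weighted_edges(el, space$ids, kind = "CSN", threshold = t)
}

#' Half-space proximal neighbors of one point
#'
#' The HSP test for point `u`: among the remaining candidates, take the
#' nearest point `v`, emit the edge `u -> v`, then discard every candidate
#' `w` lying in the forbidden half-space of `v`, i.e. with
#' `d(w, v) < d(w, u)` (ties survive, so tied points are never silently
#' disconnected); repeat until no candidates remain. Distance ties when
#' picking the nearest candidate are broken toward the lowest point index.
#'
#' @param space a [metric_space][build_metric_space] with >= 2 points.
#' @param u point index.
#' @return Integer vector of neighbor indices, in order of emission.
#' @export
hsp_neighbors <- function(space, u) {
  n <- nrow(space$points)
  if (n < 2L) stop("HSP needs >= 2 points")
  P <- space$points
  du <- space_distances(space, u)
  cand <- setdiff(seq_len(n), u)
  out <- integer(0)
  while (length(cand)) {
    v <- cand[which.min(du[cand])]  # which.min: lowest index wins ties
    out <- c(out, v)
    cand <- cand[cand != v]
    if (length(cand)) {
      dv <- sqrt(rowSums(sweep(P[cand, , drop = FALSE], 2L, P[v, ])^2))
      cand <- cand[dv >= du[cand]]
    }
  }
  out
}

#' Build a half-space proximal network (HSPN)
#'
#' Applies the HSP test independently to every point (the per-node
#' computations share nothing, so any evaluation order -- including a
#' parallel one -- yields the same graph), takes the undirected union of
#' the emitted edges, weights each by the similarity transform, and prunes
#' edges with weight below `t`. The HSPN edge set is a subset of the CSN
#' edge set at the same threshold; at `t = 0` the HSPN is a connected,
#' low-density subnetwork of the complete graph.
#'
#' @inheritParams build_csn
#' @return An igraph graph with `kind = "HSPN"`.
#' @export
build_hspn <- function(space, t = 0) {
  stopifnot(t >= 0, t <= 1)
  n <- nrow(space$points)
  maxd <- space$max_distance
  edges <- vector("list", n)
  for (u in seq_len(n)) {
    nb <- hsp_neighbors(space, u)
    edges[[u]] <- cbind(pmin(u, nb), pmax(u, nb))
  }
  el <- unique(do.call(rbind, edges))
  d <- sqrt(rowSums((space$points[el[, 1L], , drop = FALSE] -
                     space$points[el[, 2L], , drop = FALSE])^2))
  w <- 1 - d / maxd
  keep <- w >= t
  graph_from_weighted_edges(cbind(el[keep, , drop = FALSE], w[keep]),
                            space$ids, kind = "HSPN", threshold = t)
}

#' Embed new points as a k-nearest-neighbor graph
#'
#' Projects new descriptor rows into the reference coordinate frame (the
#' stored standardization is reused verbatim) and connects each new node to
#' its `k` nearest reference-or-new nodes by Euclidean distance, ties
#' broken by node id order. Edge weights use the similarity transform with
#' the *reference* diameter; a pair farther apart than the reference
#' diameter clamps to similarity 0 with a warning. Reference topology is
#' not recomputed: only the new nodes gain edges.
#'
#' @param space the reference [metric_space][build_metric_space].
#' @param new_points matrix of new descriptor rows (raw scale, named
#'   columns covering the selected descriptors; rownames become node ids).
#' @param k neighbors per new node (default 3).
#' @return An igraph graph over reference + new nodes with `kind = "KNNG"`
#'   and a logical vertex attribute `new`.
#' @export
embed_knng <- function(space, new_points, k = 3L) {
  if (is.null(dim(new_points))) new_points <- t(as.matrix(new_points))
  Q <- space_transform(space, new_points)
  n_ref <- nrow(space$points)
  n_new <- nrow(Q)
  k <- as.integer(k)
  if (k < 1L || k > n_ref + n_new - 1L)
    stop("k must be in 1 .. number of other nodes")
  new_ids <- rownames(Q)
  if (is.null(new_ids)) new_ids <- sprintf("new_%03d", seq_len(n_new))
  ids <- make.unique(c(space$ids, new_ids))  # embedded duplicates get a suffix
  all_pts <- rbind(space$points, Q)
  edges <- vector("list", n_new)
  clamped <- FALSE
  for (i in seq_len(n_new)) {
    self <- n_ref + i
    d <- sqrt(rowSums(sweep(all_pts, 2L, Q[i, ])^2))
    d[self] <- Inf
    ord <- order(d, seq_along(d))  # secondary key: node id order breaks ties
    nb <- ord[seq_len(k)]
    w <- 1 - d[nb] / space$max_distance
    if (any(w < 0)) { clamped <- TRUE; w <- pmax(0, w) }
    edges[[i]] <- cbind(self, nb, w)
  }
  if (clamped)
    warning("embedded pair(s) farther than the reference diameter; ",
            "similarity clamped at 0")
  el <- do.call(rbind, edges)
  # mutual selections produce one undirected edge, not two
  key <- paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  el <- el[!duplicated(key), , drop = FALSE]
  g <- graph_from_weighted_edges(el, ids, kind = "KNNG", threshold = 0)
  igraph::V(g)$new <- seq_along(ids) > n_ref
  g
}

graph_from_weighted_edges <- function(el, ids, kind, threshold) {
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  if (!is.null(el) && nrow(el) > 0) {
    g <- igraph::add_edges(g, t(el[, 1:2, drop = FALSE]),
                           weight = el[, 3L])
  }
  g <- igraph::set_graph_attr(g, "kind", kind)
  igraph::set_graph_attr(g, "threshold", threshold)
}

#' Network density
#'
#' The ratio of realized to possible edges, `2m / (n (n - 1))`; 1 for a
#' complete graph. `density_from_counts()` applies the same formula to
#' plain node/edge counts.
#'
#' @param graph an igraph graph.
#' @return Scalar in \[0, 1\].
#' @export
network_density <- function(graph) {
  density_from_counts(igraph::vcount(graph), igraph::ecount(graph))
}

#' @rdname network_density
#' @param n,m node and edge counts.
#' @export
density_from_counts <- function(n, m) {
  if (n < 2) stop("density undefined for fewer than 2 nodes")
  2 * m / (n * (n - 1))
}

#' Export a similarity graph for external viewers
#'
#' GraphML (canonical: carries all node/edge attributes, suitable for
#' Gephi), GML, or a lightweight `source,target,weight` edge-list CSV.
#'
#' @param graph an igraph graph.
#' @param path output file.
#' @param format `"graphml"`, `"gml"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "gml", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    el <- igraph::as_data_frame(graph, what = "edges")
    names(el)[1:2] <- c("source", "target")
    write.csv(el, path, row.names = FALSE)
  } else {
    igraph::write_graph(graph, path, format = format)
  }
  invisible(path)
}
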