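#' Weighted modularity of a partition
#'
#' `Q = (1/2m) sum_ij (a_ij - k_i k_j / 2m) delta(c_i, c_j)` with weighted
#' adjacency `a_ij`, node strengths `k_i` and total weight `m`. Q can be
#' negative; its maximum is 1. Undefined (an error) on an edgeless graph.
#'
#' @param graph a weighted igraph graph.
#' @param membership community labels, one per node (integer vector or a
#'   [community_partition][louvain]).
#' @return Scalar Q.
#' @export
modularity_q <- function(graph, membership) {
  if (inherits(membership, "community_partition"))
    membership <- membership$membership
  if (igraph::ecount(graph) == 0L)
    stop("modularity undefined on an edgeless graph (m = 0)")
  if (length(membership) != igraph::vcount(graph))
    stop("partition must cover all nodes")
  igraph::modularity(graph, membership, weights = edge_weights(graph))
}

edge_weights <- function(graph) {
  w <- igraph::E(graph)$weight
  if (is.null(w)) rep(1, igraph::ecount(graph)) else w
}

#' Louvain community detection
#'
#' Greedy weighted-modularity maximization (two phases: local node moves,
#' then aggregation of communities into super-nodes, iterated). The node
#' visiting order is randomized, so an explicit seed makes runs
#' reproducible; isolated nodes become singleton communities.
#'
#' @param graph a weighted igraph graph.
#' @param seed integer seed for the node visiting order.
#' @param resolution modularity resolution (default 1).
#' @return Object of class `community_partition`: `membership` (integer
#'   labels, one per node), `Q` (modularity, recomputed from the final
#'   partition), `n_communities`, `sizes`.
#' @export
louvain <- function(graph, seed = 42L, resolution = 1.0) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  if (igraph::ecount(graph) == 0L) {
    memb <- seq_len(igraph::vcount(graph))
    return(structure(list(membership = memb, Q = NA_real_,
                          n_communities = length(memb), sizes = rep(1L, length(memb))),
                     class = "community_partition"))
  }
  cl <- igraph::cluster_louvain(graph, weights = edge_weights(graph),
                                resolution = resolution)
  memb <- as.integer(igraph::membership(cl))
  structure(list(membership = memb,
                 Q = modularity_q(graph, memb),
                 n_communities = length(unique(memb)),
                 sizes = as.integer(table(memb))),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d communities, Q = %s\n",
              x$n_communities,
              if (is.na(x$Q)) "NA (edgeless)" else sprintf("%.4f", x$Q)))
  invisible(x)
}

#' Harmonic centrality
#'
#' `C_H(i) = sum_{j != i} 1 / d_g(i, j)` with the convention that
#' unreachable pairs contribute 0. `mode = "hops"` uses unit edge lengths;
#' `mode = "weighted"` converts similarity weights to lengths as
#' `1 - similarity`, so strongly similar peptides are close.
#'
#' @param graph an igraph graph (edge attribute `weight` = similarity).
#' @param mode `"weighted"` or `"hops"`.
#' @return Named numeric vector of centralities.
#' @export
harmonic_centrality <- function(graph, mode = c("weighted", "hops")) {
  mode <- match.arg(mode)
  w <- if (mode == "weighted") 1 - edge_weights(graph) else NA
  res <- igraph::harmonic_centrality(graph, mode = "all", weights = w,
                                     normalized = FALSE)
  setNames(as.numeric(res), igraph::V(graph)$name)
}

#' Internal and external node strengths
#'
#' For node i in community `c_i`: `k_int` sums the weights of edges to
#' same-community neighbors, `k_ext` those to other communities; their sum
#' is the weighted degree. On an unweighted graph these are neighbor
#' counts.
#'
#' @param graph a weighted igraph graph.
#' @param membership community labels (or a [community_partition][louvain]).
#' @return Data frame with columns `k_int`, `k_ext` (rownames = node ids).
#' @export
node_strengths <- function(graph, membership) {
  if (inherits(membership, "community_partition"))
    membership <- membership$membership
  n <- igraph::vcount(graph)
  if (length(membership) != n) stop("partition must cover all nodes")
  el <- igraph::as_edgelist(graph, names = FALSE)
  w <- edge_weights(graph)
  k_int <- k_ext <- numeric(n)
  if (nrow(el)) {
    same <- membership[el[, 1L]] == membership[el[, 2L]]
    for (side in 1:2) {
      v <- el[, side]
      k_int <- k_int + unname(tapply2(w * same, v, n))
      k_ext <- k_ext + unname(tapply2(w * !same, v, n))
    }
  }
  out <- data.frame(k_int = k_int, k_ext = k_ext)
  rownames(out) <- igraph::V(graph)$name
  out
}

# sum `vals` by integer index, dense over 1..n
tapply2 <- function(vals, idx, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Community hub-bridge centrality
#'
#' `C_HB(i) = k_int(i) * card(c_i) + k_ext(i) * nnc(i)` where `card(c_i)`
#' is the size of i's community and `nnc(i)` the number of distinct
#' foreign communities among i's neighbors. The measure favors hubs of
#' large communities and bridges reaching many communities.
#'
#' @inheritParams node_strengths
#' @return Data frame with `k_int`, `k_ext`, `card`, `nnc`, `C_HB`
#'   (rownames = node ids).
#' @export
community_hub_bridge <- function(graph, membership) {
  if (inherits(membership, "community_partition"))
    membership <- membership$membership
  n <- igraph::vcount(graph)
  st <- node_strengths(graph, membership)
  card <- as.integer(table(factor(membership, levels = sort(unique(membership)))))
  names(card) <- sort(unique(membership))
  st$card <- card[as.character(membership)]
  el <- igraph::as_edgelist(graph, names = FALSE)
  nnc <- integer(n)
  if (nrow(el)) {
    pairs <- rbind(cbind(el[, 1L], membership[el[, 2L]]),
                   cbind(el[, 2L], membership[el[, 1L]]))
    pairs <- pairs[pairs[, 2L] != membership[pairs[, 1L]], , drop = FALSE]
    pairs <- unique(pairs)
    if (nrow(pairs)) {
      cnt <- table(pairs[, 1L])
      nnc[as.integer(names(cnt))] <- as.integer(cnt)
    }
  }
  st$nnc <- nnc
  st$C_HB <- st$k_int * st$card + st$k_ext * st$nnc
  st
}

#' Induced subgraph of the top-k central nodes
#'
#' Ranks nodes by decreasing score (ties broken by node id ascending) and
#' induces the subgraph on the best `k`.
#'
#' @param graph an igraph graph.
#' @param scores numeric vector of per-node scores (graph vertex order).
#' @param k number of nodes to keep.
#' @return The induced igraph subgraph.
#' @export
top_k_subnetwork <- function(graph, scores, k) {
  n <- igraph::vcount(graph)
  if (length(scores) != n) stop("scores must cover all nodes")
  k <- min(as.integer(k), n)
  ord <- order(-scores, igraph::V(graph)$name)
  igraph::induced_subgraph(graph, ord[seq_len(k)])
}

#' Central but non-redundant peptide selection
#'
#' Scans records in decreasing centrality order and keeps a record iff its
#' local-alignment identity ([local_identity()]) to every already-kept
#' record is below `identity_threshold`. Optionally re-ranks the survivors
#' by another score (e.g. harmonic centrality). The output is
#' prefix-stable: truncating the input ranking can shorten but never
#' reorder it.
#'
#' @param records a [peptide_records] data frame.
#' @param scores named numeric vector of centralities covering all record
#'   ids (ties broken by id ascending).
#' @param identity_threshold percent identity in (0, 100] above or at
#'   which two sequences count as redundant (default 70).
#' @param rerank_by optional named numeric vector; survivors are reordered
#'   by decreasing value of this score.
#' @param ... passed to [local_identity()].
#' @return The kept records, in scan (or re-ranked) order.
#' @export
nonredundant_central <- function(records, scores, identity_threshold = 70,
                                 rerank_by = NULL, ...) {
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 ||
      identity_threshold > 100)
    stop("identity_threshold must lie in (0, 100]")
  if (!all(records$id %in% names(scores)))
    stop("scores must cover all records")
  ord <- order(-scores[records$id], records$id)
  recs <- records[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(recs))) {
    redundant <- FALSE
    for (j in kept) {
      idp <- local_identity(recs$sequence[i], recs$sequence[j], ...)$identity_percent
      if (idp >= identity_threshold) { redundant <- TRUE; break }
    }
    if (!redundant) kept <- c(kept, i)
  }
  out <- recs[kept, , drop = FALSE]
  if (!is.null(rerank_by)) {
    if (!all(out$id %in% names(rerank_by)))
      stop("rerank_by must cover all surviving records")
    out <- out[order(-rerank_by[out$id], out$id), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
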