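#' Fit a chemical-space network model to peptide sequences
#'
#' The central estimator of the package. From raw sequences (or a
#' precomputed descriptor matrix) it:
#'
#' 1. computes molecular descriptors ([compute_descriptor_matrix()]);
#' 2. selects an optimized descriptor subset by the two-stage unsupervised
#'    procedure (entropy ranking + correlation filter, then backward
#'    elimination on the merit function; [select_features()]);
#' 3. builds the metric space over the selected descriptors and a weighted
#'    similarity network -- a thresholded CSN, or the sparse HSPN for large
#'    datasets ([build_csn()], [build_hspn()]);
#' 4. mines the network: Louvain communities, modularity, harmonic and
#'    community hub-bridge centralities ([louvain()],
#'    [community_hub_bridge()]).
#'
#' New sequences are embedded into the fitted space with
#' [predict.chemspace()].
#'
#' @param x a [peptide_records] data frame, a character vector of
#'   sequences, a FASTA path, or a numeric descriptor matrix (rownames =
#'   ids).
#' @param config a [chemspace_config()].
#' @param table amino-acid property table for descriptor computation.
#' @param specs descriptor specs (default [default_descriptor_specs()]).
#' @return Object of class `chemspace` with components `records` (may be
#'   `NULL` when fitted from a matrix), `descriptors`, `selection`
#'   (candidate + optimized feature subsets), `space`, `graph`,
#'   `communities`, `centralities` (data frame: `community`, `k_int`,
#'   `k_ext`, `card`, `nnc`, `C_HB`, `C_H`), and `config`.
#' @export
chemspace <- function(x, config = chemspace_config(),
                      table = default_property_table(),
                      specs = default_descriptor_specs(table)) {
  records <- NULL
  if (is.matrix(x) && is.numeric(x)) {
    D <- x
    if (is.null(rownames(D))) rownames(D) <- sprintf("pep_%05d", seq_len(nrow(D)))
  } else {
    records <- if (inherits(x, "peptide_records")) x
      else if (is.character(x) && length(x) == 1L && file.exists(x)) read_fasta(x)
      else peptide_records(x)
    D <- compute_descriptor_matrix(records, specs = specs, table = table)
  }
  sel <- select_features(D, cfg = config$filter,
                         n_b = n_bins_rule(config$stage2_bins, nrow(D)))
  space <- build_metric_space(D, sel$optimized,
                              standardize = config$standardize)
  kind <- config$network
  if (identical(kind, "auto"))
    kind <- if (nrow(D) > config$hspn_above) "HSPN" else "CSN"
  graph <- if (kind == "HSPN") build_hspn(space, config$threshold)
           else build_csn(space, config$threshold)
  communities <- louvain(graph, seed = config$seed)
  hb <- community_hub_bridge(graph, communities)
  hb$community <- communities$membership
  hb$C_H <- unname(harmonic_centrality(graph, mode = config$harmonic_mode))
  structure(list(records = records, descriptors = D, selection = sel,
                 table = table, specs = specs,
                 space = space, graph = graph, communities = communities,
                 centralities = hb[, c("community", "k_int", "k_ext",
                                       "card", "nnc", "C_HB", "C_H")],
                 config = config),
            class = "chemspace")
}

#' Configuration for [chemspace()]
#'
#' Defaults mirror the tuned workflow: Spearman redundancy filter at
#' `theta2 = 0.8` with entropy cutoff 10% of maximum, square-root binning
#' for the optimization stage, z-score standardized Euclidean space, CSN
#' for datasets up to `hspn_above` peptides and the sparse HSPN beyond,
#' k = 3 embedding, 70% identity for redundancy removal.
#'
#' @param filter stage-1 [filter_config()].
#' @param stage2_bins bin rule for the optimization stage
#'   (see [n_bins_rule()]).
#' @param standardize z-score the selected descriptors before distances.
#' @param network `"CSN"`, `"HSPN"`, or `"auto"`.
#' @param threshold similarity threshold t in \[0, 1\].
#' @param hspn_above dataset size above which `"auto"` switches to HSPN.
#' @param harmonic_mode edge-length convention for harmonic centrality.
#' @param k embedding neighbors.
#' @param identity_threshold redundancy identity percent.
#' @param top_k default top-k sizes for subnetwork extraction.
#' @param seed global seed (community detection, simulation fan-out).
#' @return A list of class `chemspace_config`.
#' @export
chemspace_config <- function(filter = filter_config(),
                             stage2_bins = "sqrt",
                             standardize = TRUE,
                             network = "auto",
                             threshold = 0,
                             hspn_above = 10000L,
                             harmonic_mode = "weighted",
                             k = 3L,
                             identity_threshold = 70,
                             top_k = c(500L, 1000L),
                             seed = 42L) {
  stopifnot(threshold >= 0, threshold <= 1,
            network %in% c("auto", "CSN", "HSPN"))
  structure(list(filter = filter, stage2_bins = stage2_bins,
                 standardize = standardize, network = network,
                 threshold = threshold, hspn_above = hspn_above,
                 harmonic_mode = harmonic_mode, k = as.integer(k),
                 identity_threshold = identity_threshold,
                 top_k = as.integer(top_k), seed = as.integer(seed)),
            class = "chemspace_config")
}

#' @export
print.chemspace <- function(x, ...) {
  g <- x$graph
  cat("Chemical-space network model\n")
  cat(sprintf("  peptides:    %d\n", nrow(x$descriptors)))
  cat(sprintf("  descriptors: %d computed -> %d candidate -> %d optimized (merit %.4f)\n",
              ncol(x$descriptors), length(x$selection$candidate$indices),
              length(x$selection$optimized$indices),
              x$selection$optimized$merit))
  cat(sprintf("  network:     %s at t = %g, %d edges, density %.4g\n",
              igraph::graph_attr(g, "kind"), igraph::graph_attr(g, "threshold"),
              igraph::ecount(g), network_density(g)))
  cat(sprintf("  communities: %d (Q = %.4f)\n",
              x$communities$n_communities, x$communities$Q))
  invisible(x)
}

#' @export
summary.chemspace <- function(object, ...) {
  top <- rownames(object$centralities)[
    order(-object$centralities$C_HB, rownames(object$centralities))]
  out <- list(model = object,
              density = network_density(object$graph),
              max_distance = object$space$max_distance,
              top_hub_bridge = head(top, 10L))
  class(out) <- "summary.chemspace"
  out
}

#' @export
print.summary.chemspace <- function(x, ...) {
  print(x$model)
  cat(sprintf("  diameter:    %.4f\n", x$max_distance))
  cat("  top hub-bridge nodes:", paste(head(x$top_hub_bridge, 5L),
                                       collapse = ", "), "\n")
  invisible(x)
}

#' Coefficients of a chemical-space model
#'
#' The optimized descriptor subset with per-feature entropies -- the
#' parameters that define the reduced chemical space.
#'
#' @param object a [chemspace] fit.
#' @param ... unused.
#' @return Named numeric vector: entropy (bits) per selected descriptor.
#' @export
coef.chemspace <- function(object, ...) {
  setNames(object$selection$optimized$entropy,
           object$selection$optimized$names)
}

#' Embed new peptides into a fitted chemical space
#'
#' Computes the selected descriptors for the new sequences, reuses the
#' stored standardization, and links each new node to its k nearest
#' reference-or-new nodes ([embed_knng()]).
#'
#' @param object a [chemspace] fit (fitted from sequences, or from a
#'   matrix if `newdata` is already a descriptor matrix).
#' @param newdata new sequences ([peptide_records], character vector, or
#'   FASTA path) or a descriptor matrix covering the selected columns.
#' @param k neighbors per new node (default from the fit config).
#' @param ... unused.
#' @return A KNNG igraph over reference + new nodes; new nodes carry
#'   vertex attribute `new = TRUE`.
#' @export
predict.chemspace <- function(object, newdata, k = object$config$k, ...) {
  if (is.matrix(newdata) && is.numeric(newdata)) {
    M <- newdata
  } else {
    recs <- if (inherits(newdata, "peptide_records")) newdata
      else if (is.character(newdata) && length(newdata) == 1L &&
               file.exists(newdata)) read_fasta(newdata)
      else peptide_records(newdata, ids = names(newdata))
    if (is.null(object$records))
      stop("model was fitted from a matrix; supply newdata as a descriptor matrix")
    M <- compute_descriptor_matrix(recs, specs = object$specs,
                                   table = object$table)
  }
  embed_knng(object$space, M, k = k)
}

#' Residual-style diagnostics: similarity to nearest selected neighbor
#'
#' For each fitted peptide, one minus the similarity to its nearest other
#' peptide -- small values indicate well-embedded points, large ones
#' outliers of the chemical space.
#'
#' @param object a [chemspace] fit.
#' @param ... unused.
#' @return Named numeric vector.
#' @export
residuals.chemspace <- function(object, ...) {
  sp <- object$space
  n <- nrow(sp$points)
  out <- numeric(n)
  for (u in seq_len(n)) {
    d <- space_distances(sp, u)
    d[u] <- Inf
    out[u] <- min(d) / sp$max_distance
  }
  setNames(out, sp$ids)
}

#' Density profile plot of a chemical-space model
#'
#' Plots network density against the similarity threshold (the edge-count
#' decay as t rises), marking the fitted threshold.
#'
#' @param x a [chemspace] fit.
#' @param thresholds grid of thresholds to profile.
#' @param ... passed to [plot()].
#' @export
plot.chemspace <- function(x, thresholds = seq(0, 1, by = 0.05), ...) {
  sp <- x$space
  n <- nrow(sp$points)
  sims <- numeric(0)
  for (u in seq_len(n - 1L)) {
    d <- space_distances(sp, u)[(u + 1L):n]
    sims <- c(sims, 1 - d / sp$max_distance)
  }
  dens <- vapply(thresholds, function(t) mean(sims >= t), numeric(1L))
  plot(thresholds, dens, type = "b", pch = 16,
       xlab = "similarity threshold t", ylab = "CSN network density",
       main = "Density profile of the chemical space", ...)
  graphics::abline(v = igraph::graph_attr(x$graph, "threshold"), lty = 2)
  invisible(data.frame(threshold = thresholds, density = dens))
}
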