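#' Run the full workflow and write its artifacts
#'
#' Fits a [chemspace()] model and writes every stage's output to
#' `outdir`: the descriptor matrix, the selection report and summary, the
#' network (GraphML), community and centrality tables, the top-k central
#' subnetwork peptides and the central-but-non-redundant peptides (FASTA,
#' rank order preserved). Every table carries the configuration echo as
#' `#` comment lines and the full configuration is written as
#' `config.json`; reruns with identical inputs are bit-identical.
#'
#' @param x input for [chemspace()] (records, sequences, FASTA path, or
#'   descriptor matrix).
#' @param config a [chemspace_config()].
#' @param outdir output directory (created if needed).
#' @param ... passed to [chemspace()].
#' @return The fitted `chemspace` model, invisibly; artifact paths in
#'   attribute `"artifacts"`.
#' @export
run_pipeline <- function(x, config = chemspace_config(), outdir, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fit <- chemspace(x, config = config, ...)
  echo <- config_json(config)
  paths <- list()
  p <- function(f) file.path(outdir, f)

  jsonlite::write_json(config_list(config), p("config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  paths$config <- p("config.json")

  paths$descriptors <- write_descriptor_csv(fit$descriptors,
                                            p("descriptors.csv"),
                                            comment = echo)

  sel <- fit$selection
  rep_df <- data.frame(
    descriptor = c(sel$candidate$names),
    entropy = sel$candidate$entropy,
    stage = ifelse(sel$candidate$names %in% sel$optimized$names,
                   "optimized", "candidate"))
  con <- file(p("selection_report.csv"), "w")
  writeLines(paste0("# ", echo), con)
  write.csv(rep_df, con, row.names = FALSE)
  close(con)
  paths$selection_report <- p("selection_report.csv")

  jsonlite::write_json(
    list(n_candidate = length(sel$candidate$indices),
         n_optimized = length(sel$optimized$indices),
         merit = sel$optimized$merit,
         config = config_list(config)),
    p("selection_summary.json"), auto_unbox = TRUE, digits = NA)
  paths$selection_summary <- p("selection_summary.json")

  g <- fit$graph
  igraph::V(g)$community <- fit$centralities$community
  igraph::V(g)$C_HB <- fit$centralities$C_HB
  igraph::V(g)$C_H <- fit$centralities$C_H
  g <- igraph::set_graph_attr(g, "config", echo)
  paths$graph <- export_graph(g, p("network.graphml"), "graphml")

  cent <- data.frame(id = rownames(fit$centralities), fit$centralities)
  con <- file(p("communities.csv"), "w")
  writeLines(paste0("# ", echo), con)
  write.csv(cent[, c("id", "community")], con, row.names = FALSE)
  close(con)
  con <- file(p("centralities.csv"), "w")
  writeLines(paste0("# ", echo), con)
  write.csv(cent[, c("id", "community", "k_int", "k_ext", "C_H", "C_HB")],
            con, row.names = FALSE)
  close(con)
  paths$communities <- p("communities.csv")
  paths$centralities <- p("centralities.csv")

  if (!is.null(fit$records)) {
    k_top <- min(config$top_k[1L], nrow(fit$records))
    chb <- setNames(fit$centralities$C_HB, rownames(fit$centralities))
    topg <- top_k_subnetwork(fit$graph, fit$centralities$C_HB, k_top)
    top_ids <- igraph::V(topg)$name
    ord <- order(-chb[top_ids], top_ids)
    top_recs <- fit$records[match(top_ids[ord], fit$records$id), , drop = FALSE]
    paths$top_k <- write_fasta(top_recs, p(sprintf("top_%d.fasta", k_top)))

    ch <- setNames(fit$centralities$C_H, rownames(fit$centralities))
    nr <- nonredundant_central(top_recs, chb,
                               identity_threshold = config$identity_threshold,
                               rerank_by = ch)
    paths$nonredundant <- write_fasta(nr, p("nonredundant.fasta"))
  }
  attr(fit, "artifacts") <- paths
  invisible(fit)
}

config_list <- function(config) {
  list(filter = list(theta1 = config$filter$theta1,
                     theta2 = config$filter$theta2,
                     method = config$filter$method,
                     n_bins = config$filter$n_bins),
       stage2_bins = config$stage2_bins,
       standardize = config$standardize,
       network = config$network,
       threshold = config$threshold,
       hspn_above = config$hspn_above,
       harmonic_mode = config$harmonic_mode,
       k = config$k,
       identity_threshold = config$identity_threshold,
       top_k = config$top_k,
       seed = config$seed)
}

config_json <- function(config) {
  as.character(jsonlite::toJSON(config_list(config), auto_unbox = TRUE,
                                digits = NA))
}

#' Read a workflow configuration from JSON
#'
#' Inverse of the `config.json` echo written by [run_pipeline()].
#'
#' @param path JSON file.
#' @return A [chemspace_config()].
#' @export
read_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  f <- j$filter
  if (!length(f$theta1)) f$theta1 <- NULL  # JSON null round-trips as empty
  chemspace_config(
    filter = filter_config(theta1 = f$theta1, theta2 = f$theta2,
                           method = f$method, n_bins = f$n_bins),
    stage2_bins = j$stage2_bins, standardize = j$standardize,
    network = j$network, threshold = j$threshold,
    hspn_above = j$hspn_above, harmonic_mode = j$harmonic_mode,
    k = j$k, identity_threshold = j$identity_threshold,
    top_k = j$top_k, seed = j$seed)
}
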