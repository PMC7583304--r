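make_seeded_graph <- function(n, p = 0.25, seed = 1) {
  set.seed(seed)
  el <- NULL
  for (u in 1:(n - 1)) for (v in (u + 1):n)
    if (runif(1) < p) el <- rbind(el, c(u, v, runif(1, 0.1, 1)))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- paste0("n", sprintf("%02d", 1:n))
  if (!is.null(el))
    g <- igraph::add_edges(g, t(el[, 1:2]), weight = el[, 3])
  g
}

test_that("modularity: trivial partitions, the two-node value, the double-loop oracle", {
  g <- make_seeded_graph(12, 0.4, seed = 401)
  expect_equal(modularity_q(g, rep(1L, 12)), 0, tolerance = 1e-12)
  g2 <- igraph::make_graph(c(1, 2), directed = FALSE)
  igraph::E(g2)$weight <- 1
  expect_equal(modularity_q(g2, c(1L, 2L)), -0.5)
  set.seed(402)
  memb <- sample(1:3, 12, replace = TRUE)
  expect_equal(modularity_q(g, memb), oracle_modularity(g, memb),
               tolerance = 1e-10)
  g0 <- igraph::make_empty_graph(3, directed = FALSE)
  expect_error(modularity_q(g0, 1:3), "edgeless")
  expect_error(modularity_q(g, memb[-1]), "cover all nodes")
})

test_that("louvain separates planted communities and reports a consistent Q", {
  # two K5 cliques joined by one edge
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(5))
  g <- igraph::add_edges(g, c(1, 6))
  igraph::E(g)$weight <- 1
  igraph::V(g)$name <- paste0("v", 1:10)
  part <- louvain(g, seed = 7)
  expect_equal(part$n_communities, 2L)
  expect_equal(length(unique(part$membership[1:5])), 1L)
  expect_equal(length(unique(part$membership[6:10])), 1L)
  # the clique split maximizes Q over all 2-block partitions (exhaustive)
  qs <- sapply(0:(2^9 - 1), function(code) {
    bits <- as.integer(intToBits(code))[1:9]
    modularity_q(g, c(1L, bits + 1L))
  })
  expect_gte(part$Q + 1e-12, max(qs))
  expect_equal(part$Q, modularity_q(g, part$membership), tolerance = 1e-10)

  # complete graph: a single community, Q = 0
  k <- igraph::make_full_graph(8)
  igraph::E(k)$weight <- 1
  igraph::V(k)$name <- paste0("k", 1:8)
  pk <- louvain(k, seed = 3)
  expect_equal(pk$n_communities, 1L)
  expect_equal(pk$Q, 0)

  # planted partition with high in/out contrast is recovered up to relabeling
  set.seed(411)
  blocks <- rep(1:3, each = 10)
  el <- NULL
  for (u in 1:29) for (v in (u + 1):30) {
    w <- if (blocks[u] == blocks[v]) 1 else 0.02
    if (runif(1) < (if (blocks[u] == blocks[v]) 0.9 else 0.15))
      el <- rbind(el, c(u, v, w))
  }
  gp <- igraph::make_empty_graph(30, directed = FALSE)
  igraph::V(gp)$name <- paste0("p", 1:30)
  gp <- igraph::add_edges(gp, t(el[, 1:2]), weight = el[, 3])
  pp <- louvain(gp, seed = 5)
  expect_equal(pp$n_communities, 3L)
  tab <- table(blocks, pp$membership)
  expect_equal(sum(apply(tab, 1, max)), 30)
  # Q never below the singleton partition's
  expect_gte(pp$Q, modularity_q(gp, 1:30))
  # seeded: reproducible run-to-run
  expect_identical(pp$membership, louvain(gp, seed = 5)$membership)
})

test_that("harmonic centrality: star, isolates, and the all-pairs oracle", {
  star <- igraph::make_star(7, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("s", 1:7)
  ch <- harmonic_centrality(star, mode = "hops")
  expect_equal(unname(ch["s1"]), 6)
  iso <- igraph::add_vertices(star, 1, name = "lonely")
  expect_equal(unname(harmonic_centrality(iso, mode = "hops")["lonely"]), 0)

  g <- make_seeded_graph(25, 0.2, seed = 421)
  for (mode in c("weighted", "hops")) {
    got <- unname(harmonic_centrality(g, mode = mode))
    expect_equal(got, oracle_harmonic(g, mode), tolerance = 1e-8,
                 label = mode)
  }
  # adding an edge never decreases hop-mode centrality
  before <- harmonic_centrality(g, mode = "hops")
  nb1 <- as.integer(igraph::neighbors(g, 1))
  v2 <- setdiff(2:25, nb1)[1]
  g_plus <- igraph::add_edges(g, c(1, v2), weight = 0.5)
  after <- harmonic_centrality(g_plus, mode = "hops")
  expect_true(all(after >= before - 1e-12))
})

test_that("node strengths split the weighted degree by community", {
  g <- make_seeded_graph(20, 0.3, seed = 431)
  set.seed(432)
  memb <- sample(1:3, 20, replace = TRUE)
  st <- node_strengths(g, memb)
  want <- oracle_strengths_chb(g, memb)
  expect_equal(st$k_int, want$k_int, tolerance = 1e-10)
  expect_equal(st$k_ext, want$k_ext, tolerance = 1e-10)
  expect_equal(st$k_int + st$k_ext,
               unname(igraph::strength(g)), tolerance = 1e-10)
  # all neighbors in own community -> k_ext = 0
  clique <- igraph::make_full_graph(4)
  igraph::E(clique)$weight <- 1
  igraph::V(clique)$name <- paste0("c", 1:4)
  st2 <- node_strengths(clique, rep(1L, 4))
  expect_equal(st2$k_ext, rep(0, 4))
  expect_equal(st2$k_int, rep(3, 4))  # unweighted: count of same-community neighbors
})

test_that("community hub-bridge centrality follows k_int*card + k_ext*nnc", {
  # hand-evaluated bridge: singleton community, unit edges to 3 foreign communities
  g <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::E(g)$weight <- 1
  igraph::V(g)$name <- paste0("b", 1:4)
  hb <- community_hub_bridge(g, c(1L, 2L, 3L, 4L))
  expect_equal(hb$C_HB[1], 0 * 1 + 3 * 3)
  # no external edges, community of size s: C_HB = k_int * s
  clique <- igraph::make_full_graph(5)
  igraph::E(clique)$weight <- 0.5
  igraph::V(clique)$name <- paste0("c", 1:5)
  hb2 <- community_hub_bridge(clique, rep(1L, 5))
  expect_equal(hb2$C_HB, hb2$k_int * 5)

  g3 <- make_seeded_graph(20, 0.3, seed = 441)
  set.seed(442)
  memb <- sample(1:4, 20, replace = TRUE)
  got <- community_hub_bridge(g3, memb)
  want <- oracle_strengths_chb(g3, memb)
  expect_equal(got$C_HB, want$chb, tolerance = 1e-10)
  expect_equal(got$nnc, want$nnc)
  expect_equal(got$card, want$card)
})

test_that("top-k subnetwork keeps the highest-scoring nodes deterministically", {
  g <- make_seeded_graph(15, 0.3, seed = 451)
  scores <- seq(15, 1)
  expect_equal(igraph::vcount(top_k_subnetwork(g, scores, 15)), 15L)
  g1 <- top_k_subnetwork(g, scores, 1)
  expect_equal(igraph::vcount(g1), 1L)
  expect_equal(igraph::ecount(g1), 0L)
  set.seed(452)
  s <- runif(15)
  want <- igraph::V(g)$name[order(-s, igraph::V(g)$name)][1:10]
  expect_setequal(igraph::V(top_k_subnetwork(g, s, 10))$name, want)
})

test_that("redundancy filtering keeps one of each sequence family", {
  # identical pair: only the higher-ranked survives
  recs <- peptide_records(c("GFKDLLKGAAKALVKTVLF", "GFKDLLKGAAKALVKTVLF"),
                          ids = c("hi", "lo"))
  out <- nonredundant_central(recs, c(hi = 2, lo = 1), 70)
  expect_identical(out$id, "hi")

  # sequences with no shared residues are all kept
  recs2 <- peptide_records(c("AAAAAAAA", "KKKKKKKK", "WWWWWWWW"),
                           ids = c("a", "k", "w"))
  out2 <- nonredundant_central(recs2, c(a = 3, k = 2, w = 1), 70)
  expect_equal(nrow(out2), 3L)

  expect_error(nonredundant_central(recs2, c(a = 1, k = 1, w = 1), 0),
               "identity_threshold")
  expect_error(nonredundant_central(recs2, c(a = 1, k = 1), 70),
               "cover all records")
})

test_that("redundancy filtering is prefix-stable and re-rankable", {
  set.seed(461)
  recs <- simulate_peptides(12, c(12, 20), seed = 462)
  scores <- setNames(seq(12, 1), recs$id)
  full <- nonredundant_central(recs, scores, 55)
  head6 <- nonredundant_central(recs[1:6, ], scores[1:6], 55)
  expect_identical(head6$id, full$id[full$id %in% recs$id[1:6]][seq_len(nrow(head6))])
  # re-rank survivors by a second score
  rr <- setNames(seq_len(12), recs$id)
  rer <- nonredundant_central(recs, scores, 55, rerank_by = rr)
  expect_setequal(rer$id, full$id)
  expect_identical(rer$id, full$id[order(-rr[full$id], full$id)])
})
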