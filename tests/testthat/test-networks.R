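test_that("metric space distances and similarity follow the definitions", {
  # duplicated points are at distance 0
  m <- rbind(a = c(1, 2), b = c(1, 2), c = c(4, 6))
  colnames(m) <- c("x", "y")
  sp <- build_metric_space(m, standardize = FALSE)
  expect_equal(similarity(sp, 1, 2), 1)
  # two 1-D points {0}, {3}
  m1 <- matrix(c(0, 3), 2, 1, dimnames = list(c("p", "q"), "x"))
  sp1 <- build_metric_space(m1, standardize = FALSE)
  expect_equal(sp1$max_distance, 3)
  expect_equal(similarity(sp1, 1, 2), 0)  # the farthest pair
  # seeded 100 x 10: all pairwise distances equal a double-loop oracle
  P <- simulate_points(100, 10, seed = 301)
  sp2 <- build_metric_space(P, standardize = FALSE)
  want_max <- 0
  for (u in c(1, 17, 58)) {
    want <- sapply(seq_len(100), function(v) sqrt(sum((P[u, ] - P[v, ])^2)))
    expect_equal(pepspace:::space_distances(sp2, u), want, tolerance = 1e-10)
  }
  for (u in 1:99) for (v in (u + 1):100)
    want_max <- max(want_max, sqrt(sum((P[u, ] - P[v, ])^2)))
  expect_equal(sp2$max_distance, want_max, tolerance = 1e-10)
})

test_that("zero-variance columns are dropped with a warning under standardization", {
  P <- cbind(simulate_points(20, 3, seed = 302), flat = rep(2, 20))
  expect_warning(sp <- build_metric_space(P), "zero-variance")
  expect_equal(ncol(sp$points), 3L)
})

test_that("CSN: complete at t = 0, edgeless at t = 1, threshold oracle at 0.7", {
  P <- simulate_points(10, 4, seed = 311)
  sp <- build_metric_space(P)
  g0 <- build_csn(sp, 0)
  expect_equal(network_density(g0), 1)
  g1 <- build_csn(sp, 1)
  expect_equal(igraph::ecount(g1), 0L)

  P2 <- simulate_points(50, 5, seed = 312)
  sp2 <- build_metric_space(P2)
  g <- build_csn(sp2, 0.7)
  got <- igraph::as_edgelist(g, names = FALSE)
  got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
  want <- NULL
  for (u in 1:49) for (v in (u + 1):50) {
    s <- similarity(sp2, u, v)
    if (s >= 0.7) want <- rbind(want, c(u, v))
  }
  expect_equal(got, want)
  expect_true(all(igraph::E(g)$weight >= 0.7))
})

test_that("CSN edges are nested and density non-increasing in t", {
  sp <- build_metric_space(simulate_points(40, 6, seed = 321))
  ts <- c(0, 0.3, 0.5, 0.7, 0.9)
  gs <- lapply(ts, function(t) build_csn(sp, t))
  dens <- sapply(gs, network_density)
  expect_true(all(diff(dens) <= 0))
  key <- function(g) {
    el <- igraph::as_edgelist(g, names = FALSE)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  }
  for (i in 2:length(gs))
    expect_true(all(key(gs[[i]]) %in% key(gs[[i - 1]])))
})

test_that("HSP neighbors: the line example, two points, and the brute-force oracle", {
  m <- matrix(c(0, 1, 2, 4), 4, 1,
              dimnames = list(paste0("p", 1:4), "x"))
  sp <- build_metric_space(m, standardize = FALSE)
  expect_identical(hsp_neighbors(sp, 1), 2L)  # 2 and 4 fall in 1's forbidden half-space
  m2 <- matrix(c(0, 1), 2, 1, dimnames = list(c("a", "b"), "x"))
  sp2 <- build_metric_space(m2, standardize = FALSE)
  expect_identical(hsp_neighbors(sp2, 1), 2L)
  expect_identical(hsp_neighbors(sp2, 2), 1L)

  P <- simulate_points(200, 5, seed = 331)
  sp3 <- build_metric_space(P, standardize = FALSE)
  for (u in seq(1, 200, by = 13)) {
    expect_identical(hsp_neighbors(sp3, u), oracle_hsp(P, u),
                     label = sprintf("node %d", u))
  }
})

test_that("HSPN is a connected low-density subgraph of the CSN", {
  sp <- build_metric_space(simulate_points(200, 8, seed = 341))
  h0 <- build_hspn(sp, 0)
  expect_true(igraph::is_connected(h0))
  c0 <- build_csn(sp, 0)
  expect_lt(network_density(h0), network_density(c0))
  key <- function(g) {
    el <- igraph::as_edgelist(g, names = FALSE)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  }
  # HSPN(t) subset of HSPN(0) subset of CSN(0); weights match similarity
  h5 <- build_hspn(sp, 0.5)
  expect_true(all(key(h5) %in% key(h0)))
  expect_true(all(key(h0) %in% key(c0)))
  el <- igraph::as_edgelist(h0, names = FALSE)
  for (e in sample(nrow(el), 20)) {
    expect_equal(unname(igraph::E(h0)$weight[e]),
                 similarity(sp, el[e, 1], el[e, 2]), tolerance = 1e-12)
  }
  # deterministic: rebuilding yields the identical edge set
  h0b <- build_hspn(sp, 0)
  expect_identical(key(h0), key(h0b))
  expect_true(all(igraph::E(h0)$weight >= 0 & igraph::E(h0)$weight <= 1))
})

test_that("k-NN embedding links new points to nearest nodes with reference scaling", {
  D <- simulate_points(100, 6, seed = 351)
  sp <- build_metric_space(D, standardize = FALSE)
  # a new point duplicating a reference point, k = 1 -> edge at similarity 1
  g <- embed_knng(sp, D[7, , drop = FALSE], k = 1)
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 1L)
  expect_true("pt_00007" %in% el)
  expect_equal(igraph::E(g)$weight, 1)
  expect_equal(sum(igraph::V(g)$new), 1L)

  # 4 new + 100 reference, k = 3: edge lists equal an exhaustive-sort oracle
  New <- simulate_points(4, 6, seed = 352)
  rownames(New) <- paste0("new_", 1:4)
  g3 <- embed_knng(sp, New, k = 3)
  all_pts <- rbind(D, New)
  for (i in 1:4) {
    self <- 100 + i
    d <- apply(all_pts, 1, function(p) sqrt(sum((p - New[i, ])^2)))
    d[self] <- Inf
    nb_want <- sort(rownames(all_pts)[order(d)[1:3]])
    nbrs <- igraph::neighbors(g3, paste0("new_", i))$name
    expect_true(all(nb_want %in% nbrs))
  }
  expect_error(embed_knng(sp, New, k = 104), "number of other nodes")
})

test_that("embedding clamps beyond-diameter pairs at similarity 0 with a warning", {
  D <- matrix(c(0, 1), 2, 1, dimnames = list(c("a", "b"), "x"))
  sp <- build_metric_space(D, standardize = FALSE)
  far <- matrix(10, 1, 1, dimnames = list("far", "x"))
  expect_warning(g <- embed_knng(sp, far, k = 1), "clamped")
  expect_equal(min(igraph::E(g)$weight), 0)
})

test_that("density formula and graph export round-trip", {
  expect_equal(density_from_counts(10, 45), 1)
  expect_error(density_from_counts(1, 0), "fewer than 2")
  sp <- build_metric_space(simulate_points(15, 3, seed = 361))
  g <- build_csn(sp, 0.5)
  tmp <- tempfile(fileext = ".graphml")
  export_graph(g, tmp, "graphml")
  g2 <- igraph::read_graph(tmp, format = "graphml")
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_equal(sort(igraph::E(g2)$weight), sort(igraph::E(g)$weight),
               tolerance = 1e-6)
  tmp2 <- tempfile(fileext = ".csv")
  export_graph(g, tmp2, "csv")
  el <- read.csv(tmp2)
  expect_named(el, c("source", "target", "weight"))
  expect_equal(nrow(el), igraph::ecount(g))
})
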