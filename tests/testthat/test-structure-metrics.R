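ref <- example_reference()
fixture <- example_network()

test_that("degree and degree centrality match the reference column", {
  deg <- degree_vector(fixture)
  expect_equal(deg, ref$degree)
  expect_equal(sum(deg), 2 * igraph::gsize(fixture))

  dc <- degree_centrality(fixture)
  expect_equal(unname(dc["v1"]), 0.4)
  expect_equal(dc, deg / 10)

  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("s", 1:5)
  expect_equal(unname(degree_centrality(star)["s1"]), 1)

  iso <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(iso)$name <- c("a", "b")
  expect_equal(unname(degree_centrality(iso)), c(0, 0))
  one <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(one)$name <- "a"
  expect_error(degree_centrality(one), "at least 2")
})

test_that("eigenvector centrality is the unit-L2 principal eigenvector", {
  ec <- eigenvector_centrality(fixture)
  expect_equal(ec, ref$ec, tolerance = 1e-4)
  expect_equal(sum(ec^2), 1, tolerance = 1e-10)
  expect_true(all(ec >= 0))

  # eigen-equation residual: A x = lambda x with lambda = x' A x
  A <- as.matrix(igraph::as_adjacency_matrix(fixture, sparse = FALSE))
  lambda <- as.numeric(t(ec) %*% A %*% ec)
  expect_lt(max(abs(A %*% ec - lambda * ec)), 1e-7)

  # independent route: igraph's ARPACK scores, rescaled to unit L2
  ig <- igraph::eigen_centrality(fixture)$vector
  ig <- ig / sqrt(sum(ig^2))
  expect_equal(unname(ec), unname(ig), tolerance = 1e-6)

  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("a", "b", "c")
  expect_equal(unname(eigenvector_centrality(k3)), rep(1 / sqrt(3), 3))

  # bipartite graphs converge too (power iteration on A alone would oscillate)
  p4 <- igraph::make_ring(4, circular = FALSE)
  igraph::V(p4)$name <- paste0("p", 1:4)
  expect_silent(eigenvector_centrality(p4))

  edgeless <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(edgeless)$name <- letters[1:3]
  expect_error(eigenvector_centrality(edgeless), "at least one edge")
  expect_error(eigenvector_centrality(fixture, max_iter = 1L),
               "did not converge")
})

test_that("BFS distances reproduce the full reference block and the FW oracle", {
  d <- all_pairs_distances(fixture)
  expect_equal(d, ref$dist, ignore_attr = FALSE)
  expect_equal(unname(d["v1", "v5"]), 3)
  expect_equal(unname(diag(d)), rep(0, 11))
  expect_equal(max(d), 5)

  # oracle equivalence on random graphs up to N = 50, connected or not
  for (case in list(c(10, 0.3), c(25, 0.12), c(50, 0.05), c(50, 0.02))) {
    g <- generate_er(case[1], case[2], seed = 100 + case[1])
    expect_equal(all_pairs_distances(g), oracle_floyd_warshall(g))
  }

  f <- withr::local_tempfile()
  writeLines(c("a b", "c d"), f)
  two_edges <- read_edge_list(f)
  expect_equal(unname(all_pairs_distances(two_edges)["a", "c"]), Inf)
})

test_that("closeness matches the reference and works per component", {
  cc <- closeness_centrality(fixture)
  expect_equal(cc, ref$cc, tolerance = 1e-4)
  expect_equal(unname(cc["v1"]), 10 / 18, tolerance = 1e-6)
  expect_equal(unname(cc["v5"]), 0.32258, tolerance = 1e-4)

  f <- withr::local_tempfile(); writeLines(c("a b", "b c"), f)
  path3 <- read_edge_list(f)
  expect_equal(unname(closeness_centrality(path3)["b"]), 1)

  # disconnected: each component uses its own size
  f2 <- withr::local_tempfile(); writeLines(c("a b", "b c", "x y"), f2)
  g2 <- read_edge_list(f2)
  cc2 <- closeness_centrality(g2)
  expect_equal(unname(cc2[c("x", "y")]), c(1, 1))
  expect_equal(unname(cc2["b"]), 1)
})

test_that("network density follows 2M/(N(N-1)) and its invariances", {
  expect_equal(network_density(fixture), 0.29091, tolerance = 1e-5)
  k3 <- igraph::make_full_graph(3); igraph::V(k3)$name <- letters[1:3]
  expect_equal(network_density(k3), 1)
  e <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(e)$name <- letters[1:4]
  expect_equal(network_density(e), 0)

  # relabelling invariance and edge-addition monotonicity
  g <- generate_er(15, 0.2, seed = 5)
  perm <- sample(15)
  gp <- igraph::permute(g, perm)
  expect_equal(network_density(gp), network_density(g))
  missing <- which(as.matrix(igraph::as_adjacency_matrix(g)) == 0 &
                     upper.tri(diag(15)), arr.ind = TRUE)[1, ]
  g_plus <- igraph::add_edges(g, as.integer(missing))
  expect_gt(network_density(g_plus), network_density(g))
})

test_that("degree density follows both area conventions and their monotonicities", {
  expect_equal(degree_density(4, 1, "quadratic"), 1.27324, tolerance = 1e-5)
  expect_equal(degree_density(4, 2, "quadratic"), 0.31831, tolerance = 1e-5)
  expect_equal(degree_density(0, 3, "quadratic"), 0)
  expect_equal(degree_density(3, 1, "exponential"), 3 / pi)
  # conventions agree at distance 1 only
  expect_equal(degree_density(5, 1, "quadratic"),
               degree_density(5, 1, "exponential"))
  for (mode in c("quadratic", "exponential")) {
    dd <- degree_density(4, 1:6, mode)
    expect_true(all(diff(dd) < 0))           # strictly decreasing in distance
    dd2 <- degree_density(1:6, 3, mode)
    expect_true(all(diff(dd2) > 0))          # strictly increasing in degree
  }
  expect_error(degree_density(4, 0, "quadratic"), "unreachable|>= 1")
  expect_error(degree_density(4, Inf, "quadratic"), "finite")
})

test_that("k-shell equals the recursive-pruning oracle and its bounds", {
  star <- igraph::make_star(6, mode = "undirected")
  igraph::V(star)$name <- paste0("s", 1:6)
  expect_equal(unname(k_shell(star)), rep(1, 6))
  k4 <- igraph::make_full_graph(4); igraph::V(k4)$name <- letters[1:4]
  expect_equal(unname(k_shell(k4)), rep(3, 4))

  for (g in list(fixture, generate_er(30, 0.15, seed = 9),
                 generate_ba(30, 2, seed = 9))) {
    ks <- k_shell(g)
    expect_equal(ks, oracle_kshell(g))
    expect_true(all(ks <= degree_vector(g)))
  }
})

test_that("betweenness matches brute-force path enumeration", {
  f <- withr::local_tempfile(); writeLines(c("a b", "b c"), f)
  path3 <- read_edge_list(f)
  expect_equal(unname(betweenness_centrality(path3)["b"]), 1)

  c4 <- igraph::make_ring(4); igraph::V(c4)$name <- paste0("r", 1:4)
  bc4 <- betweenness_centrality(c4)
  expect_true(all(abs(bc4 - bc4[1]) < 1e-12))

  bc <- betweenness_centrality(fixture)
  expect_equal(bc, oracle_betweenness(fixture), tolerance = 1e-12)
  expect_equal(rank_nodes(bc)[1], "v1")

  g <- generate_er(15, 0.25, seed = 11)
  expect_equal(betweenness_centrality(g), oracle_betweenness(g),
               tolerance = 1e-12)
})

test_that("score tables serialize with node, score, rank columns", {
  s <- c(a = 1, b = 3, c = 2)
  tab <- score_table(s)
  expect_equal(tab$rank, c(3, 1, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_scores(s, f)
  expect_equal(read_scores(f), s)
})
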