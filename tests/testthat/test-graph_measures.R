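named_w <- function(w, labels = letters[seq_len(nrow(w))]) {
  dimnames(w) <- list(labels, labels)
  w
}

unit_clique <- function(n) {
  w <- matrix(1, n, n)
  diag(w) <- 0
  named_w(w)
}

chain3 <- function() {
  named_w(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3))
}

test_that("distances follow inverse-weight Dijkstra with detours", {
  d <- shortest_paths_matrix(unit_clique(3))
  expect_true(all(d[upper.tri(d)] == 1))
  d2 <- shortest_paths_matrix(chain3())
  expect_equal(d2["a", "c"], 2)
  # indirect path via b (1 + 1) beats the weak direct edge (1 / 0.4 = 2.5)
  w <- named_w(matrix(c(0, 1, 0.4, 1, 0, 1, 0.4, 1, 0), 3))
  d3 <- shortest_paths_matrix(w)
  expect_equal(d3["a", "c"], 2)
  expect_equal(d3, oracle_distances(w), ignore_attr = TRUE)
})

test_that("clique closed forms hold for nodal and global measures", {
  net <- group_network(unit_clique(3))
  nm <- nodal_measures(net)
  expect_equal(unname(nm[, "Clustering nodes"]), rep(1, 3))
  expect_equal(unname(nm[, "Triangles"]), rep(1, 3))
  expect_equal(unname(nm[, "Degree"]), rep(2, 3))
  expect_equal(unname(nm[, "Strength"]), rep(2, 3))
  expect_equal(unname(nm[, "Closeness centrality"]), rep(1, 3))
  g22 <- global_measures(group_network(unit_clique(22)), sw_n_rand = 0)
  expect_equal(unname(g22["Characteristic path length"]), 1)
  expect_equal(unname(g22["Global efficiency"]), 1)
  expect_equal(unname(g22["Clustering"]), 1)
  expect_equal(unname(g22["Transitivity"]), 1)
  expect_equal(unname(g22["Radius"]), 1)
  expect_equal(unname(g22["Diameter"]), 1)
  expect_equal(unname(g22["Eccentricity"]), 1)
})

test_that("3-chain global measures match hand enumeration", {
  g <- global_measures(group_network(chain3()), sw_n_rand = 0)
  expect_equal(unname(g["Characteristic path length"]), 4 / 3)
  expect_equal(unname(g["Global efficiency"]), 5 / 6)
  expect_equal(unname(g["Average degree"]), 4 / 3)
  expect_equal(unname(g["Average strength"]), 4 / 3)
  # empty network
  g0 <- global_measures(group_network(named_w(matrix(0, 3, 3))),
                        sw_n_rand = 0)
  expect_equal(unname(g0["Average degree"]), 0)
  expect_equal(unname(g0["Average strength"]), 0)
})

test_that("star betweenness: center carries every pair", {
  w <- matrix(0, 4, 4)
  w[1, 2:4] <- 1
  w[2:4, 1] <- 1
  nm <- nodal_measures(group_network(named_w(w)))
  expect_equal(unname(nm[, "Betweenness centrality"]), c(0.5, 0, 0, 0))
  expect_equal(unname(nm[, "Betweenness centrality"]),
               oracle_betweenness(w))
})

test_that("participation is zero in a single module and modularity Q", {
  w <- unit_clique(4)
  part <- detect_modules(w, seed = 1)
  expect_true(all(part$membership == part$membership[1]))
  expect_equal(part$q, 0)
  nm <- nodal_measures(group_network(w), part = part)
  expect_equal(unname(nm[, "Participation"]), rep(0, 4))
})

test_that("two disjoint 3-cliques split into the cliques with Q = 0.5", {
  w <- matrix(0, 6, 6)
  w[1:3, 1:3] <- 1
  w[4:6, 4:6] <- 1
  diag(w) <- 0
  w <- named_w(w)
  part <- detect_modules(w, seed = 7)
  expect_equal(part$q, 0.5)
  expect_length(unique(part$membership[1:3]), 1)
  expect_length(unique(part$membership[4:6]), 1)
  expect_false(part$membership[1] == part$membership[4])
  # exhaustive search over all 203 partitions of 6 nodes agrees
  best <- oracle_best_modularity(w)
  expect_equal(best$q, 0.5)
  # and my Q formula matches igraph's weighted modularity
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  expect_equal(modularity_q(w, part$membership),
               igraph::modularity(g, part$membership,
                                  weights = igraph::E(g)$weight))
})

test_that("module detection is deterministic given the seed", {
  set.seed(42)
  w <- random_weighted_graph(12)
  p1 <- detect_modules(w, seed = 5)
  p2 <- detect_modules(w, seed = 5)
  expect_identical(p1, p2)
})

test_that("within-module z-scores standardize within communities", {
  w <- matrix(0, 6, 6)
  w[1, 2] <- w[2, 1] <- 1
  w[1, 3] <- w[3, 1] <- 1
  w[2, 3] <- w[3, 2] <- 0.5   # a is the strong hub of module 1
  w[4:6, 4:6] <- 0.5
  diag(w) <- 0
  w[1, 4] <- w[4, 1] <- 0.1   # between-module edge must not count
  nm <- nodal_measures(group_network(named_w(w)),
                       part = structure(list(
                         membership = setNames(rep(1:2, each = 3),
                                               letters[1:6]),
                         q = 0, seed = 1), class = "module_partition"))
  z <- nm[, "Within module degree z-score"]
  expect_equal(sum(z[1:3]), 0, tolerance = 1e-12)
  expect_equal(sum(z[4:6]), 0, tolerance = 1e-12)
  expect_equal(unname(z[2]), unname(z[3]))  # b, c symmetric
  expect_gt(z[1], 0)
  expect_equal(unname(z[4:6]), rep(0, 3))  # equal within-strengths, sd = 0
})

test_that("isolated nodes get missing path length with a warning", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  expect_warning(nm <- nodal_measures(group_network(named_w(w))),
                 "isolated")
  expect_true(is.na(nm["c", "Path length"]))
  expect_true(is.na(nm["c", "Eccentricity"]))
  expect_equal(unname(nm["c", "Global efficiency nodes"]), 0)
})

test_that("uniform weight scaling rescales distances, preserves topology", {
  set.seed(43)
  w <- random_weighted_graph(10)
  c_scale <- 0.5
  m1 <- nodal_measures(group_network(named_w(w)), modules_seed = 3)
  m2 <- nodal_measures(group_network(named_w(w * c_scale)),
                       modules_seed = 3)
  expect_equal(m2[, "Path length"], m1[, "Path length"] / c_scale)
  expect_equal(m2[, "Eccentricity"], m1[, "Eccentricity"] / c_scale)
  for (meas in c("Degree", "Clustering nodes", "Participation",
                 "Betweenness centrality")) {
    expect_equal(m2[, meas], m1[, meas], tolerance = 1e-12)
  }
  expect_equal(m2[, "Strength"], m1[, "Strength"] * c_scale)
})

test_that("randomized references preserve degrees and the weight multiset", {
  set.seed(44)
  w <- named_w(random_weighted_graph(12, density = 0.4))
  refs <- randomized_reference(w, n_rand = 20, seed = 9)
  for (r in refs) {
    expect_identical(rowSums(r > 0), rowSums(w > 0))
    expect_equal(sort(r[upper.tri(r) & r > 0]),
                 sort(w[upper.tri(w) & w > 0]))
  }
  expect_warning(randomized_reference(unit_clique(4), 2, 1), "complete")
  expect_error(randomized_reference(named_w(matrix(0, 3, 3)), 2, 1),
               "2 edges")
})

test_that("ring lattices lose clustering under rewiring (sigma > random)", {
  n <- 22
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in 1:2) {
      j <- ((i + k - 1) %% n) + 1
      w[i, j] <- w[j, i] <- 0.9
    }
  }
  set.seed(46)
  w[w > 0] <- w[w > 0] * runif(sum(w > 0), 0.9, 1.1)
  w <- pmin((w + t(w)) / 2, 1)
  refs <- randomized_reference(w, n_rand = 50, seed = 2)
  c_obs <- mean(thalnet:::.triangles(w) * 2 /
                  pmax(rowSums(w > 0) * (rowSums(w > 0) - 1), 1))
  c_rand <- mean(vapply(refs, function(r) {
    k <- rowSums(r > 0)
    mean(2 * thalnet:::.triangles(r) / pmax(k * (k - 1), 1))
  }, numeric(1)))
  expect_gt(c_obs, c_rand)
  sigma_lattice <- small_worldness(w, n_rand = 50, seed = 3)
  # density-matched random graph
  set.seed(47)
  ne <- sum(w[upper.tri(w)] > 0)
  wr <- matrix(0, n, n)
  slots <- sample(which(upper.tri(wr)), ne)
  wr[slots] <- w[upper.tri(w)][w[upper.tri(w)] > 0]
  wr[lower.tri(wr)] <- t(wr)[lower.tri(wr)]
  sigma_rand <- small_worldness(wr, n_rand = 50, seed = 4)
  expect_gt(sigma_lattice, sigma_rand)
})

test_that("closeness times path length is one wherever defined", {
  set.seed(48)
  w <- named_w(random_weighted_graph(9))
  nm <- suppressWarnings(nodal_measures(group_network(w)))
  ok <- is.finite(nm[, "Path length"])
  expect_equal(unname(nm[ok, "Closeness centrality"] *
                        nm[ok, "Path length"]),
               rep(1, sum(ok)))
})

test_that("measure tables write with the published row labels", {
  set.seed(49)
  w <- named_w(random_weighted_graph(6))
  ms <- graph_measures(group_network(w), sw_n_rand = 5)
  fg <- withr::local_tempfile(fileext = ".tsv")
  fn <- withr::local_tempfile(fileext = ".tsv")
  write_measures(ms, fg, fn)
  g <- utils::read.delim(fg)
  expect_identical(g$measure, global_measure_names())
  nl <- utils::read.delim(fn)
  expect_setequal(unique(nl$measure), nodal_measure_names())
  expect_identical(nrow(nl), 6L * 12L)
})
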