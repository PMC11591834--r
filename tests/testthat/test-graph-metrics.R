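# Graph metrics: closed-form toys and the exhaustive-enumeration oracle.

test_that("shortest paths: toys, weighted lengths, disconnection", {
  p3 <- toy_path3()
  dm <- shortest_paths(p3, "binary")
  expect_equal(unname(dm$d["A", "C"]), 2)
  expect_equal(unname(dm$counts["A", "C"]), 1)
  tri <- toy_triangle(0.9)
  dmw <- shortest_paths(tri, "one_minus_w")
  expect_equal(unname(dmw$d[1, 2]), 0.1, tolerance = 1e-12)  # direct < 2 hops
  dmi <- shortest_paths(tri, "inverse_w")
  expect_equal(unname(dmi$d[1, 2]), 1 / 0.9, tolerance = 1e-12)
  # two components
  adj <- matrix(0, 4, 4); adj[1, 2] <- adj[2, 1] <- adj[3, 4] <- adj[4, 3] <- 1
  dm2 <- shortest_paths(make_graph(adj), "binary")
  expect_true(is.infinite(dm2$d[1, 3]))
  expect_equal(unname(dm2$counts[1, 3]), 0)
})

test_that("betweenness: star hub 1, path middle 1, 4-cycle 1/6", {
  st <- toy_star(5)
  bc <- betweenness(st, shortest_paths(st, "binary"))
  expect_equal(unname(bc[1]), 1)
  expect_equal(unname(bc[-1]), rep(0, 5))
  p3 <- toy_path3()
  expect_equal(unname(betweenness(p3, shortest_paths(p3, "binary"))["B"]), 1)
  c4 <- toy_cycle4()
  expect_equal(unname(betweenness(c4, shortest_paths(c4, "binary"))),
               rep(1 / 6, 4), tolerance = 1e-12)
  # N < 3 warns and returns zeros
  two <- make_graph(matrix(c(0, 1, 1, 0), 2))
  expect_warning(bc2 <- betweenness(two, shortest_paths(two, "binary")),
                 "N < 3")
  expect_equal(unname(bc2), c(0, 0))
})

test_that("nodal efficiency: complete 1, isolated 0, path endpoint 0.75", {
  comp <- make_graph(1 - diag(5))
  expect_equal(unname(nodal_efficiency(shortest_paths(comp, "binary"))),
               rep(1, 5))
  adj <- matrix(0, 3, 3); adj[1, 2] <- adj[2, 1] <- 1
  dm <- shortest_paths(make_graph(adj), "binary")
  expect_equal(unname(nodal_efficiency(dm)[3]), 0)
  ne <- nodal_efficiency(shortest_paths(toy_path3(), "binary"))
  expect_equal(unname(ne["A"]), (1 + 1 / 2) / 2)
  # weighted distances below 1 may push NE above 1 (reported unclamped)
  newt <- nodal_efficiency(shortest_paths(toy_triangle(0.9), "one_minus_w"))
  expect_true(all(newt > 1))
})

test_that("clustering: triangle 1, star 0, paw graph by enumeration", {
  expect_equal(unname(clustering_local(toy_triangle())), rep(1, 3))
  expect_equal(unname(clustering_local(toy_star(4))), rep(0, 5))
  paw <- toy_paw()   # A-B, A-C, B-C, A-D
  cc <- clustering_local(paw)
  expect_equal(unname(cc), c(1 / 3, 1, 1, 0))
  expect_equal(clustering_global(cc), (1 / 3 + 1 + 1 + 0) / 4)
  expect_equal(clustering_global(numeric(0)), 0)
})

test_that("characteristic path length: complete 1, path 4/3, weighted 0.1", {
  comp <- make_graph(1 - diag(6))
  expect_equal(characteristic_path_length(shortest_paths(comp, "binary")), 1)
  expect_equal(characteristic_path_length(shortest_paths(toy_path3(),
                                                         "binary")), 4 / 3)
  expect_equal(characteristic_path_length(
    shortest_paths(toy_triangle(0.9), "one_minus_w")), 0.1,
    tolerance = 1e-12)
  # finite distances only; fully disconnected errors
  empty <- make_graph(matrix(0, 3, 3))
  expect_error(characteristic_path_length(shortest_paths(empty, "binary")),
               "no connected pair")
})

test_that("metrics_for_graph: empty graph degenerates cleanly", {
  mt <- metrics_for_graph(make_graph(matrix(0, 5, 5)), "binary")
  expect_equal(mt$nodes$bc, rep(0, 5))
  expect_equal(mt$nodes$ne, rep(0, 5))
  expect_equal(mt$nodes$cc_local, rep(0, 5))
  expect_equal(mt$cc_global, 0)
  expect_true(is.na(mt$cpl))
})

test_that("metrics are equivariant under node relabeling", {
  set.seed(12)
  g <- random_graph(7, 0.5)
  perm <- sample(7)
  gp <- make_graph(g$adjacency[perm, perm], g$weights[perm, perm])
  mt <- metrics_for_graph(g)
  mtp <- metrics_for_graph(gp)
  expect_equal(mtp$nodes$bc, mt$nodes$bc[perm], tolerance = 1e-12)
  expect_equal(mtp$nodes$ne, mt$nodes$ne[perm], tolerance = 1e-12)
  expect_equal(mtp$nodes$cc_local, mt$nodes$cc_local[perm],
               tolerance = 1e-12)
  expect_equal(mtp$cpl, mt$cpl, tolerance = 1e-12)
})

test_that("adding an edge never increases any shortest-path distance", {
  set.seed(13)
  for (rep in 1:10) {
    g <- random_graph(7, 0.4)
    d0 <- shortest_paths(g)$d
    miss <- which(g$adjacency == 0 & upper.tri(g$adjacency), arr.ind = TRUE)
    if (!nrow(miss)) next
    pick <- miss[sample(nrow(miss), 1), ]
    g$adjacency[pick[1], pick[2]] <- g$adjacency[pick[2], pick[1]] <- 1
    g$weights[pick[1], pick[2]] <- g$weights[pick[2], pick[1]] <- 0.8
    d1 <- shortest_paths(g)$d
    expect_true(all(d1 <= d0 + 1e-12))
  }
})

test_that("Floyd-Warshall metrics match the enumeration oracle (spot check)", {
  set.seed(14)
  for (i in 1:12) {
    n <- sample(5:7, 1)
    weighted <- i %% 2 == 0
    g <- random_graph(n, sample(c(0.3, 0.6), 1), weighted = weighted)
    mode <- if (weighted) "one_minus_w" else "binary"
    dm <- shortest_paths(g, mode)
    orc <- oracle_metrics(g, mode)
    expect_equal(dm$d, orc$d, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(dm$counts, orc$counts, ignore_attr = TRUE)
    mt <- metrics_for_graph(g, mode)
    expect_equal(mt$nodes$bc, orc$bc, tolerance = 1e-12)
    expect_equal(mt$nodes$ne, orc$ne, tolerance = 1e-12)
    expect_equal(mt$nodes$cc_local, orc$cc_local, tolerance = 1e-12)
    expect_equal(mt$cc_global, orc$cc_global, tolerance = 1e-12)
    if (!is.na(mt$cpl) || !is.na(orc$cpl)) {
      expect_equal(mt$cpl, orc$cpl, tolerance = 1e-12)
    }
  }
})

test_that("metrics_long emits node rows plus GLOBAL rows", {
  mt <- metrics_for_graph(toy_triangle(0.8))
  long <- metrics_long(mt)
  expect_equal(nrow(long), 3 * 3 + 2)
  expect_setequal(unique(long$metric),
                  c("bc", "ne", "cc_local", "cc_global", "cpl"))
})
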