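test_that("density thresholding retains the requested strongest edges", {
  set.seed(20)
  m <- matrix(rnorm(141 * 141), 141); m <- (m + t(m)) / 2; diag(m) <- 0
  g <- apply_density_threshold(m, 0.15)
  expect_equal(g$n_edges, 1481L)        # round(0.15 * 9870) half-away
  expect_true(all(g$weights >= 0))
  expect_true(all(diag(g$weights) == 0))
  # retained edges are the strongest positives
  kept <- g$weights[upper.tri(g$weights)]
  cutoff <- min(kept[kept > 0])
  pos <- m[upper.tri(m)]
  expect_equal(sum(pos >= cutoff), g$n_edges)

  allneg <- -abs(m)
  expect_error(apply_density_threshold(allneg, 0.2), "no positive")

  allpos <- abs(m); diag(allpos) <- 0
  g1 <- apply_density_threshold(allpos, 1)
  expect_equal(g1$weights, allpos)

  sparse <- matrix(0, 10, 10); sparse[1, 2] <- sparse[2, 1] <- 0.5
  expect_warning(gs <- apply_density_threshold(sparse, 0.5), "keeping all")
  expect_equal(gs$n_edges, 1L)
})

test_that("strength, clustering and closeness match hand values on canonical graphs", {
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  expect_equal(nodal_strength(K5), rep(4, 5))
  expect_equal(nodal_clustering(K5), rep(1, 5))
  expect_equal(nodal_closeness(K5), rep(1, 5))
  expect_equal(global_efficiency(K5), 1)
  expect_equal(as.numeric(characteristic_path_length(K5)), 1)

  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- 0.2
  path3[2, 3] <- path3[3, 2] <- 0.5
  expect_equal(nodal_strength(path3), c(0.2, 0.7, 0.5))

  unit3 <- (path3 > 0) * 1
  expect_equal(nodal_closeness(unit3), c(0.75, 1, 0.75))
  expect_equal(global_efficiency(unit3), 5 / 6)
  expect_equal(as.numeric(characteristic_path_length(unit3)), 4 / 3)

  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(nodal_clustering(star), rep(0, 5))

  tri <- matrix(0, 3, 3)
  tri[1, 2] <- tri[2, 1] <- 1; tri[1, 3] <- tri[3, 1] <- 1
  tri[2, 3] <- tri[3, 2] <- 0.125
  expect_equal(nodal_clustering(tri), rep(0.5, 3))

  iso <- matrix(0, 4, 4); iso[1, 2] <- iso[2, 1] <- 1
  expect_equal(nodal_strength(iso)[3], 0)
  expect_equal(nodal_closeness(iso)[3], 0)

  dyads <- matrix(0, 4, 4)
  dyads[1, 2] <- dyads[2, 1] <- 1; dyads[3, 4] <- dyads[4, 3] <- 1
  L <- characteristic_path_length(dyads)
  expect_equal(as.numeric(L), 1)
  expect_equal(attr(L, "unreachable_frac"), 2 / 3)
})

test_that("graph metrics agree with brute-force oracles on random weighted graphs", {
  set.seed(21)
  for (i in 1:20) {
    r <- sample(5:30, 1)
    w <- random_weighted_graph(r, p_edge = runif(1, 0.15, 0.6))
    if (sum(w > 0) < 2) next
    d <- shortest_path_lengths(w)
    expect_equal(d, oracle_distances(w), tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(unname(nodal_clustering(w)), oracle_clustering(w),
                 tolerance = 1e-10)
    expect_equal(unname(nodal_closeness(w, d)), oracle_closeness(d),
                 tolerance = 1e-10)
    expect_equal(global_efficiency(w, d), oracle_efficiency(d),
                 tolerance = 1e-10)
    if (any(is.finite(d[row(d) != col(d)])))
      expect_equal(as.numeric(characteristic_path_length(w, d)),
                   oracle_cpl(d), tolerance = 1e-10)
  }
})

test_that("weight rescaling moves strength and distances but not topology metrics", {
  set.seed(22)
  w <- random_weighted_graph(15, 0.4)
  c_mult <- 3.7
  expect_equal(nodal_degree(w * c_mult), nodal_degree(w))
  expect_equal(nodal_strength(w * c_mult), c_mult * nodal_strength(w))
  expect_equal(nodal_clustering(w * c_mult), nodal_clustering(w),
               tolerance = 1e-12)
  expect_equal(shortest_path_lengths(w * c_mult),
               shortest_path_lengths(w) / c_mult, tolerance = 1e-12)
})

test_that("node relabeling permutes nodal outputs identically", {
  set.seed(23)
  w <- random_weighted_graph(12, 0.4)
  perm <- sample(12)
  wp <- w[perm, perm]
  expect_equal(nodal_strength(wp), nodal_strength(w)[perm])
  expect_equal(nodal_clustering(wp), nodal_clustering(w)[perm],
               tolerance = 1e-12)
  expect_equal(nodal_closeness(wp), nodal_closeness(w)[perm],
               tolerance = 1e-12)
})

test_that("global efficiency is non-decreasing in density on the same matrix", {
  set.seed(24)
  m <- matrix(rnorm(40 * 40, mean = 0.2), 40); m <- (m + t(m)) / 2; diag(m) <- 0
  effs <- sapply(seq(0.15, 0.35, by = 0.05), function(d)
    global_efficiency(apply_density_threshold(m, d)))
  expect_true(all(diff(effs) >= -1e-12))
})

test_that("rewired nulls preserve the degree sequence and randomize clustering", {
  set.seed(25)
  w <- random_weighted_graph(30, 0.3)
  null <- rewire_null(w, n_swaps_per_edge = 10, seed = 5)
  expect_equal(sort(nodal_degree(null$weights)), sort(nodal_degree(w)))
  expect_equal(nodal_degree(null$weights), nodal_degree(w))  # per node
  expect_equal(sort(null$weights[upper.tri(null$weights)][null$weights[upper.tri(null$weights)] > 0]),
               sort(w[upper.tri(w)][w[upper.tri(w)] > 0]))

  # complete graph admits no legal swap
  K6 <- matrix(1, 6, 6); diag(K6) <- 0
  expect_equal(rewire_null(K6, seed = 2)$weights, K6)

  # ring lattice: randomization halves clustering at least
  ring <- matrix(0, 100, 100)
  for (k in 1:3) {
    idx <- cbind(1:100, ((1:100 + k - 1) %% 100) + 1)
    ring[idx] <- 1; ring[idx[, c(2, 1)]] <- 1
  }
  cnull <- mean(nodal_clustering(rewire_null(ring, 10, seed = 3)$weights))
  expect_lt(cnull, 0.5 * mean(nodal_clustering(ring)))
})

test_that("small-worldness separates lattice-like from random graphs", {
  K6 <- matrix(1, 6, 6); diag(K6) <- 0
  expect_equal(small_worldness(K6, n_nulls = 3, seed = 1)$sigma, 1)

  set.seed(26)
  ws <- as.matrix(igraph::as_adjacency_matrix(
    igraph::sample_smallworld(1, 100, 3, 0.05)))
  er <- as.matrix(igraph::as_adjacency_matrix(
    igraph::sample_gnp(100, 0.15)))
  s_ws <- small_worldness(ws, n_nulls = 20, seed = 2)$sigma
  s_er <- small_worldness(er, n_nulls = 20, seed = 3)$sigma
  expect_gt(s_ws, 1.5)
  expect_gt(s_er, 0.8); expect_lt(s_er, 1.2)
})

test_that("density integration is a range-normalized trapezoid", {
  dens <- seq(0.15, 0.35, by = 0.01)
  expect_length(dens, 21L)
  expect_equal(integrate_over_densities(rep(3.3, 21), dens), 3.3)
  lin <- seq(2, 8, length.out = 21)
  expect_equal(integrate_over_densities(lin, dens), 5)
  m <- cbind(rep(1, 21), lin)
  expect_equal(unname(integrate_over_densities(m, dens)), c(1, 5))
  expect_error(integrate_over_densities(1, densities = 0.2), "at least 2")
  expect_error(integrate_over_densities(1:3, densities = c(0.1, 0.3, 0.2)),
               "increasing")
})

test_that("the metric profile integrates its own per-density curves", {
  set.seed(27)
  m <- matrix(rnorm(20 * 20, 0.3), 20); m <- (m + t(m)) / 2; diag(m) <- 0
  dens <- seq(0.15, 0.35, by = 0.05)
  pr <- graph_metric_profile(m, densities = dens, n_nulls = 4, seed = 9)
  expect_equal(pr$integrated$global[["efficiency"]],
               integrate_over_densities(pr$global$efficiency, dens))
  expect_equal(unname(pr$integrated$nodal$strength),
               unname(integrate_over_densities(pr$nodal$strength, dens)))
  expect_true(all(is.finite(pr$global$sigma)))
  expect_true(all(pr$global$sigma > 0))
})
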