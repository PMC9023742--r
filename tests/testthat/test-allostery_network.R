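test_that("DCCM has unit diagonal and resolves rigid and mirrored motion", {
  top <- toy_topology(3)
  set.seed(17)
  a <- rnorm(200)
  base <- matrix(rep(c(0, 0, 0, 5, 0, 0, 0, 5, 0), each = 200), nrow = 200)
  xyz <- base
  xyz[, 1] <- xyz[, 1] + a      # bead 1 and bead 2 move in lock-step along x
  xyz[, 4] <- xyz[, 4] + a
  xyz[, 7] <- xyz[, 7] - a      # bead 3 mirrors them
  dc <- compute_dccm(ensemble(top, xyz), superpose = FALSE)
  expect_equal(diag(dc), rep(1, 3), ignore_attr = TRUE)
  expect_equal(dc[1, 2], 1, tolerance = 1e-12)
  expect_equal(dc[1, 3], -1, tolerance = 1e-12)
  expect_true(all(abs(dc) <= 1 + 1e-12))
  expect_equal(unclass(dc), t(unclass(dc)), ignore_attr = TRUE)
})

test_that("a zero-variance residue is reported by name", {
  top <- toy_topology(2)
  xyz <- rbind(c(0, 0, 0, 5, 0, 0), c(1, 0, 0, 5, 0, 0))
  expect_error(compute_dccm(ensemble(top, xyz), superpose = FALSE), "A:2")
})

test_that("DCCM is invariant under global rigid motion of the frames", {
  sys <- synthetic_system(synthetic_spec(residues_per_segment = c(4, 6, 4),
                                         n_frames = 120, seed = 37))
  dc1 <- compute_dccm(sys$ensemble)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  rot <- t(apply(sys$ensemble$xyz, 1, function(row)
    as.numeric(t(sweep(matrix(row, ncol = 3, byrow = TRUE) %*% R, 2, c(3, -2, 1), `+`)))))
  dc2 <- compute_dccm(ensemble(sys$ensemble$topology, rot))
  expect_equal(unclass(dc1), unclass(dc2), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("sampled DCCM converges to the closed-form planted correlations", {
  sys <- toy20_system()
  dc <- compute_dccm(sys$ensemble, superpose = FALSE)
  want <- dccm_from_covariance(sys$truth$covariance)
  expect_lt(max(abs(unclass(dc) - want)), 0.05)
})

test_that("sampled DCCM agrees with an independent implementation", {
  skip_if_not_installed("bio3d")
  sys <- synthetic_system(synthetic_spec(residues_per_segment = c(4, 6, 4),
                                         n_frames = 150, seed = 41))
  dc <- compute_dccm(sys$ensemble, superpose = FALSE)
  ref <- bio3d::dccm(sys$ensemble$xyz)
  expect_lt(max(abs(unclass(dc) - unclass(ref))), 1e-6)
})

test_that("graph edges respect occupancy threshold and the -log|C| weight", {
  # two beads in contact 8/10 frames, two others 7/10
  top <- toy_topology(4)
  base <- c(0, 0, 0,  3, 0, 0,  20, 0, 0,  23, 0, 0)
  xyz <- matrix(rep(base, 10), nrow = 10, byrow = TRUE)
  xyz[9:10, 4] <- 9      # pair (1,2) apart in 2 frames -> occupancy 0.8
  xyz[8:10, 10] <- 43    # pair (3,4) apart in 3 frames -> occupancy 0.7
  xyz <- xyz + matrix(rnorm(120, sd = 0.01), nrow = 10)   # break degeneracy
  ens <- ensemble(top, xyz)
  dc <- compute_dccm(ens, superpose = FALSE)
  g <- build_graph(ens, dc, contact_cutoff = 4.5, occupancy_min = 0.75)
  key <- paste(g$edges$i, g$edges$j)
  expect_true("1 2" %in% key)
  expect_false("3 4" %in% key)
  expect_equal(g$edges$dij, -log(abs(g$edges$cij)))
  expect_error(build_graph(ens, dc, occupancy_min = 0), "occupancy_min")
  expect_error(build_graph(ens, dc, occupancy_min = 1.2), "occupancy_min")

  # tightening the cutoff or the occupancy threshold never adds edges
  g_loose <- build_graph(ens, dc, contact_cutoff = 6, occupancy_min = 0.5)
  expect_true(all(key %in% paste(g_loose$edges$i, g_loose$edges$j)))
})

test_that("the -log weight convention maps |C| = 1 and e^-1 correctly", {
  g <- allostery_graph(data.frame(i = c(1, 2), j = c(2, 3),
                                  cij = c(1, exp(-1))), 3)
  expect_equal(g$edges$dij, c(0, 1))
})

test_that("Girvan-Newman splits two cliques at the bridge and equals brute force", {
  edges <- rbind(expand.grid(i = 1:3, j = 1:3), expand.grid(i = 4:6, j = 4:6))
  edges <- edges[edges$i < edges$j, ]
  edges$cij <- 0.5
  edges <- rbind(edges, data.frame(i = 3, j = 4, cij = 0.5))
  g <- allostery_graph(edges, 6)
  cm <- detect_communities(g)
  expect_equal(length(cm$sizes), 2)
  expect_equal(cm$membership, rep(1:2, each = 3))
  expect_equal(cm$modularity, brute_max_modularity(g$edges, 6), tolerance = 1e-12)
})

test_that("a complete graph stays one community; components never merge", {
  k5 <- expand.grid(i = 1:5, j = 1:5)
  k5 <- k5[k5$i < k5$j, ]
  k5$cij <- 0.5
  cm <- detect_communities(allostery_graph(k5, 5))
  expect_equal(length(cm$sizes), 1)

  two <- rbind(expand.grid(i = 1:3, j = 1:3), expand.grid(i = 4:6, j = 4:6))
  two <- two[two$i < two$j, ]
  two$cij <- 0.5
  cmd <- detect_communities(allostery_graph(two, 6))
  expect_gte(length(cmd$sizes), 2)
  expect_true(all(cmd$membership[1:3] != cmd$membership[4:6]))
})

test_that("Girvan-Newman reaches the brute-force optimum on clique chains", {
  set.seed(19)
  for (t in 1:20) {
    gg <- random_clique_chain()
    cm <- detect_communities(gg$graph)
    expect_equal(cm$modularity, brute_max_modularity(gg$edges, gg$graph$n_nodes),
                 tolerance = 1e-9)
    expect_equal(ari(cm$membership, gg$truth), 1)
  }
})

test_that("the planted 8-community structure is recovered", {
  sys <- complex64_system()
  dc <- compute_dccm(sys$ensemble, superpose = FALSE)
  g <- build_graph(sys$ensemble, dc)
  cm <- detect_communities(g)
  expect_equal(length(cm$sizes), 8)
  expect_gte(ari(cm$membership, sys$truth$partition), 0.9)
})

test_that("intercommunity strengths are symmetric and conservative", {
  edges <- rbind(expand.grid(i = 1:3, j = 1:3), expand.grid(i = 4:6, j = 4:6))
  edges <- edges[edges$i < edges$j, ]
  edges$cij <- 0.5
  bridged <- rbind(edges, data.frame(i = 3, j = 4, cij = 0.5))
  g <- allostery_graph(bridged, 6)
  mem <- rep(1:2, each = 3)
  s_count <- intercommunity_strength(g, mem, measure = "count")
  expect_equal(s_count[1, 2], 1)
  expect_equal(s_count, t(s_count))

  s_bet <- intercommunity_strength(g, mem, measure = "betweenness")
  gi <- igraph::graph_from_data_frame(bridged[, 1:2], directed = FALSE,
                                      vertices = data.frame(name = 1:6))
  eb <- igraph::edge_betweenness(gi, weights = -log(bridged$cij))
  expect_equal(s_bet[1, 2], eb[length(eb)])   # the bridge edge's betweenness

  g0 <- allostery_graph(edges, 6)
  expect_true(all(intercommunity_strength(g0, mem, "count") == 0))
  expect_error(intercommunity_strength(g, mem[-1]), "partition")
})

test_that("optimal paths follow Floyd-Warshall on simple and random graphs", {
  line <- allostery_graph(data.frame(i = c(1, 2), j = c(2, 3),
                                     dij = c(1, 1), cij = exp(-1)), 3)
  op <- optimal_path(line, 1, 3)
  expect_equal(op$path, c(1L, 2L, 3L))
  expect_equal(op$length, 2)
  expect_equal(op$n_residues, 3)

  disc <- allostery_graph(data.frame(i = 1, j = 2, cij = 0.5), 3)
  nores <- optimal_path(disc, 1, 3)
  expect_true(nores$no_path)
  expect_equal(nores$length, Inf)

  set.seed(23)
  for (t in 1:20) {
    gg <- random_weighted_graph(50, p = 0.08)
    dj <- dijkstra_dist(gg$graph)
    s <- sample(50, 1); k <- sample(setdiff(1:50, s), 1)
    op <- optimal_path(gg$graph, s, k)
    expect_equal(op$length, dj[s, k], tolerance = 1e-10)
    # path length consistency
    e <- gg$graph$edges
    key <- paste(pmin(e$i, e$j), pmax(e$i, e$j))
    wt <- setNames(e$dij, key)
    v <- op$path
    expect_equal(sum(wt[paste(pmin(v[-length(v)], v[-1]),
                              pmax(v[-length(v)], v[-1]))]),
                 op$length, ignore_attr = TRUE)
  }
})

test_that("suboptimal path sets match exhaustive enumeration", {
  sq <- allostery_graph(data.frame(i = c(1, 2, 1, 3), j = c(2, 4, 3, 4),
                                   dij = 1, cij = exp(-1)), 4)
  sp0 <- suboptimal_paths(sq, 1, 4, tolerance = 0)
  expect_equal(sp0$n_suboptimal, 2)   # both sides of the square
  expect_true(all(abs(sp0$path_lengths - sp0$length) < 1e-12))

  set.seed(27)
  for (t in 1:20) {
    n <- sample(6:10, 1)
    gg <- random_weighted_graph(n, p = 0.35)
    s <- 1; k <- n
    tol <- runif(1, 0, 2)
    sp <- suboptimal_paths(gg$graph, s, k, tolerance = tol)
    lens <- all_simple_path_lengths(gg$graph, s, k)
    expect_equal(sp$n_suboptimal, sum(lens <= min(lens) + tol + 1e-9))
    expect_false(sp$truncated)
    expect_gte(min(sp$path_lengths), sp$length - 1e-12)
  }
})

test_that("the search cap truncates gracefully with a lower bound", {
  set.seed(29)
  gg <- random_weighted_graph(12, p = 0.5)
  full <- suboptimal_paths(gg$graph, 1, 12, tolerance = 10)
  capped <- suboptimal_paths(gg$graph, 1, 12, tolerance = 10,
                             max_expansions = 20)
  expect_true(capped$truncated)
  expect_lte(capped$n_suboptimal, full$n_suboptimal)
})

test_that("pathway tables compose the path operations deterministically", {
  sys <- ternary64_system()
  dc <- compute_dccm(sys$ensemble, superpose = FALSE)
  g <- build_graph(sys$ensemble, dc)
  pt <- pathway_table(g, list(c(57, 8)), tolerance = 2)
  op <- optimal_path(g, 57, 8)
  sp <- suboptimal_paths(g, 57, 8, tolerance = 2)
  expect_equal(pt$length, op$length)
  expect_equal(pt$residues, op$n_residues)
  expect_equal(pt$subopt, sp$n_suboptimal)
  pt2 <- pathway_table(g, list(c(57, 8)), tolerance = 2)
  expect_identical(pt, pt2)
  # the recovered optimal pathway is the planted chain
  expect_identical(op$path, sys$truth$path)
})

test_that("graph exports are written in standard formats", {
  g <- allostery_graph(data.frame(i = c(1, 2), j = c(2, 3), cij = c(0.5, 0.8)), 3)
  f1 <- tempfile(fileext = ".graphml"); f2 <- tempfile(fileext = ".dot")
  write_graph_file(g, f1, "graphml")
  write_graph_file(g, f2, "dot")
  expect_true(any(grepl("graphml", readLines(f1))))
  expect_true(file.size(f2) > 0)
})
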