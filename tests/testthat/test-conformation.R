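rotz <- function(th) matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)

test_that("Kabsch superposition removes rigid motion exactly", {
  set.seed(1)
  ref <- matrix(rnorm(30), ncol = 3)
  expect_equal(kabsch_superpose(ref, ref)$rmsd, 0, tolerance = 1e-12)
  moved <- sweep(ref %*% rotz(pi / 2), 2, c(5, -3, 2), `+`)
  fit <- kabsch_superpose(moved, ref)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(fit$coords, ref, tolerance = 1e-9)
})

test_that("Kabsch RMSD matches a fine planar rotation-grid search", {
  # asymmetric planar 4-point sets: the optimal proper rotation is about z,
  # so an exhaustive 1-D angle grid is a complete oracle
  set.seed(7)
  P <- cbind(matrix(rnorm(8), ncol = 2), 0)
  Q <- cbind(matrix(rnorm(8), ncol = 2), 0)
  fit <- kabsch_superpose(P, Q, mask = 1:4)
  th <- seq(0, 2 * pi, length.out = 720001)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  best <- Inf
  for (chunk in split(th, ceiling(seq_along(th) / 20000))) {
    rmsds <- vapply(chunk, function(a)
      sqrt(mean(rowSums((Pc %*% rotz(a) - Qc)^2))), numeric(1))
    best <- min(best, min(rmsds))
  }
  expect_lt(abs(fit$rmsd - best), 1e-3)
  expect_lte(fit$rmsd, best + 1e-12)   # never worse than the grid
})

test_that("Kabsch agrees with an independent superposition implementation", {
  skip_if_not_installed("bio3d")
  set.seed(11)
  for (k in 1:5) {
    ref <- matrix(rnorm(45), ncol = 3)
    mob <- ref + 0.3 * matrix(rnorm(45), ncol = 3)
    ours <- kabsch_superpose(mob, ref)$rmsd
    theirs <- bio3d::rmsd(as.numeric(t(ref)), as.numeric(t(mob)), fit = TRUE)
    expect_lt(abs(ours - theirs), 6e-4)   # bio3d rounds to 3 decimals
  }
})

test_that("degenerate masks are rejected", {
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_superpose(line, line + 1), "collinear|degenerate")
  expect_error(kabsch_superpose(line[1:2, ], line[1:2, ]), "3 mask atoms")
})

test_that("RMSD series is zero for a constant ensemble and rigid-motion invariant", {
  sys <- synthetic_system(synthetic_spec(residues_per_segment = c(4, 6, 4),
                                         n_frames = 20, seed = 2))
  ens <- sys$ensemble
  const <- ensemble(ens$topology, ens$xyz[rep(1, 5), ])
  expect_equal(rmsd_series(const)$rmsd, rep(0, 5), tolerance = 1e-10)

  # re-inject random rigid motions frame by frame: series must not change
  set.seed(3)
  xyz2 <- t(apply(ens$xyz, 1, function(row) {
    m <- matrix(row, ncol = 3, byrow = TRUE)
    th <- runif(3, 0, 2 * pi)
    R <- rotz(th[1]) %*% matrix(c(1,0,0, 0,cos(th[2]),sin(th[2]), 0,-sin(th[2]),cos(th[2])), 3)
    as.numeric(t(sweep(m %*% R, 2, runif(3, -5, 5), `+`)))
  }))
  wobbled <- ensemble(ens$topology, xyz2)
  expect_equal(rmsd_series(wobbled)$rmsd, rmsd_series(ens)$rmsd,
               tolerance = 1e-7)
})

test_that("mean squared RMSD matches the planted covariance trace", {
  sys <- toy20_system()
  rs <- rmsd_series(sys$ensemble, reference = sys$reference)
  expected <- mean(diag(sys$truth$covariance)) * 3   # per-atom block trace
  expect_equal(mean(rs$rmsd^2), expected, tolerance = 0.05)
})

test_that("RMSF recovers isotropic displacement amplitudes", {
  n <- 100
  top <- toy_topology(n)
  ref <- 10 * matrix(rnorm(3 * n), ncol = 3)
  sigma <- 0.25
  set.seed(5)
  F <- 10000
  xyz <- matrix(rep(as.numeric(t(ref)), each = F), nrow = F) +
    matrix(rnorm(F * 3 * n, sd = sigma), nrow = F)
  rf <- rmsf_per_residue(ensemble(top, xyz))
  expect_equal(mean(rf$rmsf), sigma * sqrt(3), tolerance = 0.03)
  expect_error(rmsf_per_residue(ensemble(top, xyz[1, , drop = FALSE])),
               "2 frames")
})

test_that("stiffly coupled residues fluctuate less, as the planted covariance orders", {
  sys <- ternary64_system()
  rf <- rmsf_per_residue(sys$ensemble)
  chain <- sys$truth$path
  expect_lt(mean(rf$rmsf[chain]), mean(rf$rmsf[-chain]))
  # and the sampled RMSF ordering tracks the planted per-residue variance
  planted <- sqrt(vapply(seq_len(64), function(i)
    sum(diag(sys$truth$covariance[(3*i-2):(3*i), (3*i-2):(3*i)])), numeric(1)))
  expect_gt(cor(rf$rmsf, planted, method = "spearman"), 0.9)
})

test_that("pair distance distributions are normalized with correct moments", {
  top <- toy_topology(3)
  ens <- ensemble(top, matrix(rep(c(0, 0, 0, 3, 0, 0, 0, 5, 0), 4),
                              nrow = 4, byrow = TRUE))
  dd <- pair_distance_distribution(ens, c(1, 2))
  expect_equal(dd$mean, 3)
  expect_equal(dd$mode, 3, tolerance = 0.06)
  expect_equal(sum(dd$prob), 1)
  expect_error(pair_distance_distribution(ens, c(2, 2)), "distinct")

  set.seed(6)
  F <- 4000; d0 <- 6; s <- 0.2
  b1 <- matrix(rnorm(3 * F, sd = s), ncol = 3)
  b2 <- cbind(rnorm(F, d0, s), rnorm(F, 0, s), rnorm(F, 0, s))
  b3 <- matrix(rep(c(0, 5, 0), each = F), ncol = 3)
  ens2 <- ensemble(top, cbind(b1, b2, b3))
  dd2 <- pair_distance_distribution(ens2, c(1, 2))
  expect_lt(abs(dd2$mean - d0), 0.05)
  expect_equal(sum(dd2$prob), 1)
})
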