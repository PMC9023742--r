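# Independent oracles used across the suite.  These deliberately re-derive
# quantities with different code paths (plain double loops, exhaustive
# enumeration, igraph reference algorithms) from the implementations they
# check.

# ---- set partitions / modularity ------------------------------------------

.partition_memo <- new.env()

# n x Bell(n) matrix of canonical set-partition labelings
partition_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.partition_memo[[key]])) return(.partition_memo[[key]])
  parts <- matrix(1L, 1, 1)
  if (n > 1) for (pos in 2:n) {
    mx <- apply(parts, 2, max)
    reps <- mx + 1L
    idx <- rep(seq_len(ncol(parts)), reps)
    newrow <- unlist(lapply(seq_len(ncol(parts)), function(c) seq_len(reps[c])))
    parts <- rbind(parts[, idx, drop = FALSE], newrow)
  }
  dimnames(parts) <- NULL
  .partition_memo[[key]] <- parts
  parts
}

# weighted Newman modularity of one labeling (independent implementation)
modularity_oracle <- function(edges, n, mem, w = abs(edges$cij)) {
  m2 <- 2 * sum(w)
  deg <- numeric(n)
  for (r in seq_len(nrow(edges))) {
    deg[edges$i[r]] <- deg[edges$i[r]] + w[r]
    deg[edges$j[r]] <- deg[edges$j[r]] + w[r]
  }
  same <- mem[edges$i] == mem[edges$j]
  sum(2 * w[same]) / m2 - sum(tapply(deg, mem, sum)^2) / m2^2
}

# exhaustive max modularity over all set partitions (vectorized)
brute_max_modularity <- function(edges, n, w = abs(edges$cij)) {
  m2 <- 2 * sum(w)
  deg <- numeric(n)
  for (r in seq_len(nrow(edges))) {
    deg[edges$i[r]] <- deg[edges$i[r]] + w[r]
    deg[edges$j[r]] <- deg[edges$j[r]] + w[r]
  }
  P <- partition_matrix(n)
  same_e <- P[edges$i, , drop = FALSE] == P[edges$j, , drop = FALSE]
  t1 <- colSums(2 * w * same_e) / m2
  pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
  same_n <- P[pr[, 1], , drop = FALSE] == P[pr[, 2], , drop = FALSE]
  dd <- deg[pr[, 1]] * deg[pr[, 2]]
  t2 <- (colSums(2 * dd * same_n) + sum(deg^2)) / m2^2
  max(t1 - t2)
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expct <- si * sj / choose(n, 2)
  (sij - expct) / ((si + sj) / 2 - expct)
}

# ---- random graph generators ----------------------------------------------

# clique blocks (sizes >= 3) joined in a chain by single uniform-weight
# bridges, with permuted node labels: the class on which divisive GN
# provably reaches the max-modularity split
random_clique_chain <- function() {
  repeat {
    k <- sample(2:3, 1)
    sizes <- sample(3:4, k, replace = TRUE)
    if (sum(sizes) <= 10) break
  }
  n <- sum(sizes)
  perm <- sample(n)
  mem <- rep(seq_len(k), sizes)
  edges <- NULL
  for (b in seq_len(k)) {
    nodes <- perm[which(mem == b)]
    pr <- t(utils::combn(nodes, 2))
    edges <- rbind(edges, data.frame(i = pmin(pr[, 1], pr[, 2]),
                                     j = pmax(pr[, 1], pr[, 2]), cij = 0.5))
  }
  for (b in seq_len(k - 1)) {
    a <- sample(perm[which(mem == b)], 1)
    c <- sample(perm[which(mem == b + 1)], 1)
    edges <- rbind(edges, data.frame(i = min(a, c), j = max(a, c), cij = 0.5))
  }
  list(graph = allostery_graph(edges, n), edges = edges,
       truth = mem[order(perm)])
}

# connected Erdos-Renyi graph with random correlation weights
random_weighted_graph <- function(n, p = 0.25) {
  repeat {
    pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pr)) < p
    if (sum(keep) < 1) next
    edges <- data.frame(i = pr[keep, 1], j = pr[keep, 2],
                        cij = stats::runif(sum(keep), 0.05, 0.95))
    gi <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                        vertices = data.frame(name = seq_len(n)))
    if (igraph::is_connected(gi)) return(list(graph = allostery_graph(edges, n),
                                              edges = edges))
  }
}

# ---- reference path algorithms --------------------------------------------

# single-pair Dijkstra distance via igraph (reference implementation)
dijkstra_dist <- function(graph) {
  gi <- igraph::graph_from_data_frame(graph$edges[, c("i", "j")],
                                      directed = FALSE,
                                      vertices = data.frame(name = seq_len(graph$n_nodes)))
  igraph::distances(gi, weights = graph$edges$dij, algorithm = "dijkstra")
}

# lengths of ALL simple paths between two nodes (exhaustive, via igraph)
all_simple_path_lengths <- function(graph, s, t) {
  gi <- igraph::graph_from_data_frame(graph$edges[, c("i", "j")],
                                      directed = FALSE,
                                      vertices = data.frame(name = seq_len(graph$n_nodes)))
  key <- paste(pmin(graph$edges$i, graph$edges$j),
               pmax(graph$edges$i, graph$edges$j))
  wt <- stats::setNames(graph$edges$dij, key)
  ps <- igraph::all_simple_paths(gi, from = s, to = t)
  vapply(ps, function(p) {
    v <- as.integer(names(p))
    sum(wt[paste(pmin(v[-length(v)], v[-1]), pmax(v[-length(v)], v[-1]))])
  }, numeric(1))
}

# ---- energetics oracles ----------------------------------------------------

# plain double-loop MM cross energies, written from the formulas
brute_force_mm <- function(coords, gA, gB, top, eps_in = 1) {
  a <- top$atoms
  evdw <- 0; eele <- 0
  for (i in gA) for (j in gB) {
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    eele <- eele + 332.0637 * a$charge[i] * a$charge[j] / (eps_in * r)
    eij <- sqrt(a$eps[i] * a$eps[j])
    rmin <- a$rmin_half[i] + a$rmin_half[j]
    evdw <- evdw + eij * ((rmin / r)^12 - 2 * (rmin / r)^6)
  }
  list(E_vdW = evdw, E_ele = eele)
}

# hand-evaluated two-atom generalized-Born energy (HCT radii + f_GB)
gb_two_atom_oracle <- function(q1, q2, rho1, rho2, r, eps_in, eps_out) {
  hct <- function(rho_i, rho_j, r) {
    if (rho_i >= r + rho_j) return(0)
    L <- max(rho_i, abs(r - rho_j)); U <- r + rho_j
    0.5 * (1 / L - 1 / U + (r / 4) * (1 / U^2 - 1 / L^2) +
             (1 / (2 * r)) * log(L / U) +
             (rho_j^2 / (4 * r)) * (1 / L^2 - 1 / U^2))
  }
  R1 <- 1 / (1 / rho1 - hct(rho1, rho2, r))
  R2 <- 1 / (1 / rho2 - hct(rho2, rho1, r))
  fgb <- sqrt(r^2 + R1 * R2 * exp(-r^2 / (4 * R1 * R2)))
  pref <- -332.0637 / 2 * (1 / eps_in - 1 / eps_out)
  pref * (q1^2 / R1 + q2^2 / R2 + 2 * q1 * q2 / fgb)
}

# ---- misc ------------------------------------------------------------------

# a minimal hand-built bead topology: n beads, one residue each, segment ids
toy_topology <- function(n, segid = rep("A", n), charge = rep(0, n),
                         eps = rep(0.1, n), rmin_half = rep(2, n)) {
  topology(data.frame(name = "CA", resid = seq_len(n), resname = "BEA",
                      segid = segid, mass = 12, charge = charge, eps = eps,
                      rmin_half = rmin_half, stringsAsFactors = FALSE))
}

# mean silhouette width in PC1-PC2 for a labeling
mean_silhouette <- function(points, labels) {
  d <- as.matrix(stats::dist(points))
  n <- nrow(points)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(k) mean(d[i, labels == k]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
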