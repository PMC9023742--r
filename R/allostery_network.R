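#' Dynamic cross-correlation matrix of C-alpha motions
#'
#' After superposition, the normalized covariance of displacement vectors
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` is computed for every
#' residue pair, with `dr` the displacement from the mean position.  Values
#' lie in `[-1, 1]`; the diagonal is exactly 1.
#'
#' @param ens An [ensemble()] with at least two frames.
#' @param fit_mask Atom indices for the superposition fit; default all
#'   C-alpha atoms.
#' @param superpose Set `FALSE` if the frames are already superposed.
#' @return `N_res x N_res` matrix of class `correlation_matrix` with
#'   attributes `resids`, `segids` and `n_frames`.
#' @export
compute_dccm <- function(ens, fit_mask = NULL, superpose = TRUE) {
  if (nrow(ens$xyz) < 2) abort("DCCM needs at least 2 frames")
  sup <- if (superpose) superpose_ensemble(ens, fit_mask, reference = "mean") else ens
  ca <- calpha_map(ens$topology)
  X <- sup$xyz[, xyz_cols(ca), drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  M <- crossprod(Xc) / nrow(X)          # 3N x 3N second-moment matrix
  n <- length(ca)
  # residue-block traces: sum over the x,y,z components
  blk <- function(i, j) M[3 * i - 2, 3 * j - 2] + M[3 * i - 1, 3 * j - 1] + M[3 * i, 3 * j]
  selfs <- vapply(seq_len(n), function(i) blk(i, i), numeric(1))
  if (any(selfs <= 0)) {
    bad <- which(selfs <= 0)
    a <- ens$topology$atoms
    abort("zero-variance residue(s): %s",
          paste(paste0(a$segid[ca[bad]], ":", a$resid[ca[bad]]), collapse = ", "))
  }
  C <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    C[i, j] <- C[j, i] <- blk(i, j) / sqrt(selfs[i] * selfs[j])
  a <- ens$topology$atoms
  structure(C, class = c("correlation_matrix", "matrix"),
            resids = a$resid[ca], segids = a$segid[ca], n_frames = nrow(X))
}

#' Occupancy-filtered residue interaction graph with correlation weights
#'
#' Residues are nodes; an edge is kept when the two residues stay within
#' `contact_cutoff` for at least the `occupancy_min` fraction of frames
#' (distances taken between the residues' beads/heavy atoms, minimum over
#' atom pairs).  Surviving edges are weighted by the information-distance
#' `d_ij = -log(|C_ij|)` (natural log by default); edges with `C_ij = 0`
#' are dropped as infinitely distant.
#'
#' @param ens An [ensemble()].
#' @param dccm A [compute_dccm()] result for the same ensemble.
#' @param contact_cutoff Contact distance cutoff (Angstrom), default 4.5.
#' @param occupancy_min Minimum contact occupancy, default 0.75.
#' @param log_base Base of the logarithm in the edge distance, default
#'   `exp(1)`.
#' @return Object of class `allostery_graph`: `edges` data.frame
#'   (`i`, `j`, `occupancy`, `cij`, `dij`), `n_nodes`, `resids`, `segids`,
#'   and the parameters used.
#' @export
build_graph <- function(ens, dccm, contact_cutoff = 4.5, occupancy_min = 0.75,
                        log_base = exp(1)) {
  if (occupancy_min <= 0 || occupancy_min > 1)
    abort("occupancy_min must lie in (0, 1]")
  n <- nrow(dccm)
  a <- ens$topology$atoms
  # per-residue atom lists (bead models: the single C-alpha)
  ca <- calpha_map(ens$topology)
  res_atoms <- split(seq_len(nrow(a)), match(paste(a$segid, a$resid),
                                             unique(paste(a$segid, a$resid))))
  nf <- nrow(ens$xyz)
  counts <- matrix(0L, n, n)
  for (f in seq_len(nf)) {
    m <- vec2mat(ens$xyz[f, ])
    if (all(lengths(res_atoms) == 1L)) {
      d <- as.matrix(stats::dist(m[unlist(res_atoms), , drop = FALSE]))
    } else {
      # minimum heavy-atom distance between residues
      d <- matrix(Inf, n, n)
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        A <- m[res_atoms[[i]], , drop = FALSE]
        B <- m[res_atoms[[j]], , drop = FALSE]
        d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
        d[i, j] <- d[j, i] <- sqrt(max(min(d2), 0))
      }
    }
    counts <- counts + (d <= contact_cutoff)
  }
  occ <- counts / nf
  pr <- which(upper.tri(occ) & occ >= occupancy_min, arr.ind = TRUE)
  cij <- dccm[pr]
  keep <- abs(cij) > 0
  pr <- pr[keep, , drop = FALSE]
  cij <- cij[keep]
  edges <- data.frame(i = pr[, 1], j = pr[, 2], occupancy = occ[pr],
                      cij = cij, dij = -log(abs(cij)) / log(log_base))
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, n_nodes = n,
                 resids = attr(dccm, "resids"), segids = attr(dccm, "segids"),
                 params = list(contact_cutoff = contact_cutoff,
                               occupancy_min = occupancy_min,
                               log_base = log_base)),
            class = "allostery_graph")
}

#' Build an allostery graph directly from an edge table
#'
#' Mostly for tests and toy examples: wraps a data.frame with columns `i`,
#' `j` and either `dij` or `cij` into an `allostery_graph`.
#'
#' @param edges Edge data.frame.
#' @param n_nodes Number of nodes.
#' @return An `allostery_graph`.
#' @export
allostery_graph <- function(edges, n_nodes) {
  if (is.null(edges$dij)) edges$dij <- -log(abs(edges$cij))
  if (is.null(edges$cij)) edges$cij <- exp(-edges$dij)
  if (is.null(edges$occupancy)) edges$occupancy <- 1
  if (any(edges$i == edges$j)) abort("self-edges are not allowed")
  structure(list(edges = edges, n_nodes = as.integer(n_nodes),
                 resids = seq_len(n_nodes), segids = rep("A", n_nodes),
                 params = list()),
            class = "allostery_graph")
}

#' @export
print.allostery_graph <- function(x, ...) {
  cat(sprintf("allostery graph: %d nodes, %d edges\n", x$n_nodes, nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(graph, weight = c("dij", "cij_abs", "none")) {
  weight <- match.arg(weight)
  g <- igraph::graph_from_data_frame(graph$edges[, c("i", "j")],
                                     directed = FALSE,
                                     vertices = data.frame(name = seq_len(graph$n_nodes)))
  if (weight == "dij") igraph::E(g)$weight <- graph$edges$dij
  if (weight == "cij_abs") igraph::E(g)$weight <- abs(graph$edges$cij)
  g
}

#' Export an allostery graph to GraphML or DOT
#'
#' @param graph An `allostery_graph`.
#' @param path Output file path.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(graph, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  g <- as_igraph(graph, "dij")
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

# weighted modularity of a node partition; weights default to |C_ij|
graph_modularity <- function(graph, membership, weights = NULL) {
  w <- weights %||% abs(graph$edges$cij)
  m2 <- 2 * sum(w)
  if (m2 == 0) return(0)
  deg <- numeric(graph$n_nodes)
  for (r in seq_len(nrow(graph$edges))) {
    deg[graph$edges$i[r]] <- deg[graph$edges$i[r]] + w[r]
    deg[graph$edges$j[r]] <- deg[graph$edges$j[r]] + w[r]
  }
  same <- membership[graph$edges$i] == membership[graph$edges$j]
  sum(2 * w[same]) / m2 - sum(tapply(deg, membership, sum)^2) / m2^2
}

#' Girvan-Newman community detection on the allostery graph
#'
#' Iteratively removes the edge of maximum betweenness (shortest paths
#' weighted by the `d_ij` edge distances; ties broken deterministically by
#' the lowest node-index pair), evaluating the weighted modularity of the
#' connected-component partition after every removal, and returns the
#' partition of maximum modularity over the whole dendrogram.
#'
#' @param graph An `allostery_graph` with at least one node.
#' @param weights Optional modularity edge weights; default `|C_ij|`.
#' @return Object of class `community_partition`: `membership` (community id
#'   per node, communities numbered by lowest member), `sizes`, `modularity`.
#' @export
detect_communities <- function(graph, weights = NULL) {
  if (graph$n_nodes < 1) abort("empty graph")
  edges <- graph$edges
  w_mod <- weights %||% abs(edges$cij)
  active <- rep(TRUE, nrow(edges))

  membership_of <- function(act) {
    g <- igraph::graph_from_data_frame(edges[act, c("i", "j"), drop = FALSE],
                                       directed = FALSE,
                                       vertices = data.frame(name = seq_len(graph$n_nodes)))
    comp <- igraph::components(g)$membership
    # canonical labels: communities numbered by their lowest node index
    match(comp, unique(comp))
  }

  best_mem <- membership_of(active)
  best_q <- graph_modularity(graph, best_mem, w_mod)
  while (any(active)) {
    g <- igraph::graph_from_data_frame(edges[active, c("i", "j"), drop = FALSE],
                                       directed = FALSE,
                                       vertices = data.frame(name = seq_len(graph$n_nodes)))
    eb <- igraph::edge_betweenness(g, weights = edges$dij[active])
    mx <- max(eb)
    cand <- which(eb >= mx - 1e-12)
    idx_active <- which(active)
    # deterministic tie-break: lowest (i, j) pair
    ord <- order(edges$i[idx_active[cand]], edges$j[idx_active[cand]])
    active[idx_active[cand[ord[1]]]] <- FALSE
    mem <- membership_of(active)
    q <- graph_modularity(graph, mem, w_mod)
    if (q > best_q + 1e-12) { best_q <- q; best_mem <- mem }
  }
  structure(list(membership = best_mem,
                 sizes = as.integer(table(best_mem)),
                 modularity = best_q),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("communities: %d (sizes %s), modularity %.3f\n",
              length(x$sizes), paste(x$sizes, collapse = ", "), x$modularity))
  invisible(x)
}

#' Intercommunity connection strengths
#'
#' For every community pair, sums a per-edge measure over the edges crossing
#' the pair: the edge betweenness of the full graph (default, mirroring
#' stick-width community maps) or a plain edge count.
#'
#' @param graph An `allostery_graph`.
#' @param partition A [detect_communities()] result (or membership vector).
#' @param measure `"betweenness"` or `"count"`.
#' @return Symmetric `K x K` matrix of strengths.
#' @export
intercommunity_strength <- function(graph, partition,
                                    measure = c("betweenness", "count")) {
  measure <- match.arg(measure)
  mem <- if (inherits(partition, "community_partition")) partition$membership else partition
  if (length(mem) != graph$n_nodes) abort("partition does not match graph nodes")
  K <- max(mem)
  edges <- graph$edges
  val <- if (measure == "betweenness") {
    g <- as_igraph(graph, "dij")
    igraph::edge_betweenness(g, weights = igraph::E(g)$weight)
  } else rep(1, nrow(edges))
  S <- matrix(0, K, K)
  for (r in seq_len(nrow(edges))) {
    a <- mem[edges$i[r]]; b <- mem[edges$j[r]]
    if (a != b) {
      S[a, b] <- S[a, b] + val[r]
      S[b, a] <- S[a, b]
    }
  }
  S
}

# all-pairs shortest distances by Floyd-Warshall, with next-hop matrix
floyd_warshall <- function(graph) {
  n <- graph$n_nodes
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  NXT <- matrix(NA_integer_, n, n)
  for (r in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[r]; j <- graph$edges$j[r]; d <- graph$edges$dij[r]
    if (d < D[i, j]) {
      D[i, j] <- D[j, i] <- d
      NXT[i, j] <- j; NXT[j, i] <- i
    }
  }
  for (k in seq_len(n)) {
    via <- outer(D[, k], D[k, ], `+`)
    upd <- via < D
    if (any(upd)) {
      D[upd] <- via[upd]
      NXT[upd] <- NXT[, k][row(upd)[upd]]
    }
  }
  list(dist = D, nxt = NXT)
}

#' Optimal (shortest) pathway between two residues
#'
#' Minimal total `d_ij` path via all-pairs Floyd-Warshall.  A disconnected
#' pair yields an explicit no-path report, not an error.
#'
#' @param graph An `allostery_graph`.
#' @param source,sink Node indices (residue positions in the graph).
#' @return Object of class `pathway_report` with `path` (node vector or
#'   `NULL`), `length` (sum of `d_ij`, `Inf` if unreachable) and
#'   `n_residues`.
#' @export
optimal_path <- function(graph, source, sink) {
  source <- as.integer(source); sink <- as.integer(sink)
  fw <- floyd_warshall(graph)
  len <- fw$dist[source, sink]
  if (!is.finite(len)) {
    return(structure(list(source = source, sink = sink, path = NULL,
                          length = Inf, n_residues = 0L, no_path = TRUE),
                     class = "pathway_report"))
  }
  path <- source
  cur <- source
  while (cur != sink) {
    cur <- fw$nxt[cur, sink]
    path <- c(path, cur)
  }
  structure(list(source = source, sink = sink, path = path, length = len,
                 n_residues = length(path), no_path = FALSE),
            class = "pathway_report")
}

#' @export
print.pathway_report <- function(x, ...) {
  if (isTRUE(x$no_path)) {
    cat(sprintf("pathway %d -> %d: no path\n", x$source, x$sink))
  } else {
    cat(sprintf("pathway %d -> %d: length %.3f, %d residues%s\n", x$source,
                x$sink, x$length, x$n_residues,
                if (!is.null(x$n_suboptimal))
                  sprintf(", %d path(s) within tolerance %.3g", x$n_suboptimal,
                          x$tolerance) else ""))
  }
  invisible(x)
}

#' Enumerate the suboptimal pathway set between two residues
#'
#' Depth-first enumeration of all simple paths with total length at most
#' `optimal + tolerance`, pruned by the exact remaining-distance lower bound
#' from Floyd-Warshall, with a hard expansion cap; a truncated search is
#' flagged and the count is then a lower bound.  The set includes the
#' optimal path(s) themselves, so `tolerance = 0` returns exactly the
#' shortest path(s).
#'
#' @param graph An `allostery_graph`.
#' @param source,sink Node indices.
#' @param tolerance Admissible excess over the optimal length (same unit as
#'   `d_ij`; unitless under the `-log|C|` convention), default 20.
#' @param max_expansions Search-node cap, default 1e6.
#' @return A `pathway_report` with additionally `paths` (list of node
#'   vectors), `path_lengths`, `n_suboptimal` (size of the set) and
#'   `truncated`.
#' @export
suboptimal_paths <- function(graph, source, sink, tolerance = 20,
                             max_expansions = 1e6) {
  source <- as.integer(source); sink <- as.integer(sink)
  opt <- optimal_path(graph, source, sink)
  if (isTRUE(opt$no_path)) abort("no path between %d and %d", source, sink)
  fw <- floyd_warshall(graph)
  limit <- opt$length + tolerance + 1e-9
  n <- graph$n_nodes
  adj <- vector("list", n)
  for (r in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[r]; j <- graph$edges$j[r]; d <- graph$edges$dij[r]
    adj[[i]] <- rbind(adj[[i]], c(j, d))
    adj[[j]] <- rbind(adj[[j]], c(i, d))
  }
  paths <- list()
  lens <- numeric(0)
  expansions <- 0L
  truncated <- FALSE
  visited <- rep(FALSE, n)
  recurse <- function(node, len, trail) {
    if (truncated) return()
    expansions <<- expansions + 1L
    if (expansions > max_expansions) { truncated <<- TRUE; return() }
    if (node == sink) {
      paths[[length(paths) + 1L]] <<- trail
      lens[length(lens) + 1L] <<- len
      return()
    }
    nb <- adj[[node]]
    if (is.null(nb)) return()
    ord <- order(nb[, 1])
    for (k in ord) {
      nxt <- as.integer(nb[k, 1]); d <- nb[k, 2]
      if (visited[nxt]) next
      if (len + d + fw$dist[nxt, sink] > limit) next
      visited[nxt] <<- TRUE
      recurse(nxt, len + d, c(trail, nxt))
      visited[nxt] <<- FALSE
    }
  }
  visited[source] <- TRUE
  recurse(source, 0, source)
  opt$paths <- paths
  opt$path_lengths <- lens
  opt$n_suboptimal <- length(paths)
  opt$tolerance <- tolerance
  opt$truncated <- truncated
  opt
}

#' Pathway summary table for a set of source-sink pairs
#'
#' One row per pair with the optimal length, the number of residues on the
#' optimal pathway, and the size of the suboptimal pathway set — the layout
#' of published allosteric-pathway tables.
#'
#' @param graph An `allostery_graph`.
#' @param pairs List of length-2 integer vectors, or a 2-column matrix.
#' @param tolerance Suboptimal-path tolerance, default 20.
#' @param max_expansions Search cap per pair.
#' @return Data.frame with `source`, `sink`, `length`, `residues`, `subopt`,
#'   `truncated`.
#' @export
pathway_table <- function(graph, pairs, tolerance = 20, max_expansions = 1e6) {
  if (is.matrix(pairs)) pairs <- split(pairs, seq_len(nrow(pairs)))
  do.call(rbind, lapply(pairs, function(p) {
    sp <- suboptimal_paths(graph, p[1], p[2], tolerance, max_expansions)
    data.frame(source = p[1], sink = p[2], length = sp$length,
               residues = sp$n_residues, subopt = sp$n_suboptimal,
               truncated = sp$truncated)
  }))
}
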