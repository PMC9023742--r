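#' Specification of a synthetic three-segment bead complex
#'
#' Defines the study conditions for generating toy complexes that emulate a
#' ternary GTPase/exchange-factor assembly: a catalytic Ras-like segment, a
#' central SOS-like segment, and an allosteric Ras-like segment.  Each
#' segment is laid out as a row of compact bead blocks ("blobs") connected by
#' narrow bridges; the blobs are the planted community structure.  Frames are
#' later drawn from the multivariate Gaussian implied by an elastic-network
#' Hessian built on this geometry, so every downstream statistic has a
#' closed-form expectation.
#'
#' @param residues_per_segment Integer vector of length 3; beads per segment
#'   (catalytic, central, allosteric).  Default `c(16, 32, 16)`, a
#'   desk-scale stand-in for a two-GTPase/exchange-factor complex.
#' @param segment_ids Segment names, default `c("RASC","SOS","RASA")`.
#' @param residues_per_community Beads per blob (planted community size),
#'   default 8; segments shorter than this form a single blob.
#' @param grid_spacing Bead lattice constant within a blob (Angstrom),
#'   default 3.0, chosen so blob-internal bead pairs fall inside a 4.5
#'   Angstrom contact cutoff while bead pairs two lattice steps apart do not.
#' @param bridge_gap Distance between consecutive blobs of a segment
#'   (Angstrom), default 4.0: inside the contact cutoff, but strictly looser
#'   than blob-internal contacts, so communities split at the bridges.
#' @param interface_gap Distance between facing beads of two segments at a
#'   designed interface (Angstrom), default 3.4, inside the default
#'   hydrogen-bond (3.5 A) and salt-bridge (4.0 A) criteria so designed
#'   interfacial interactions exist at the reference geometry.
#' @param contact_cutoff_build Elastic-network spring cutoff (Angstrom),
#'   default 10.
#' @param spring_constant Base spring constant (kcal mol^-1 A^-2), default 10.
#' @param coupling_edges Optional data.frame with columns `i`, `j` (global
#'   residue indices) of springs stiffened by `coupling_factor`; these are
#'   the planted allosteric pathway.
#' @param coupling_factor Stiffening factor for coupling edges, default 50.
#' @param plant_path Optional `list(source =, sink =)` of global residue
#'   indices; when given (and `coupling_edges` is `NULL`) the generator
#'   plants couplings along the fewest-hop reference-contact chain between
#'   them.
#' @param stiffen_segments Optional character vector of two segment ids whose
#'   interface contacts are stiffened by `stiffen_factor` (models enhanced
#'   interfacial affinity).
#' @param stiffen_factor Interface stiffening factor, default 10.
#' @param kT Thermal energy (kcal/mol), default 0.593 (300 K).
#' @param n_frames Number of frames to sample, default 2000.
#' @param seed Integer RNG seed; recorded in all outputs.
#' @param charge_magnitude Bead partial charges alternate `+/-` this value
#'   (e), default 0.5, giving nonzero hand-checkable interaction energies.
#' @param lj_eps Uniform LJ well depth (kcal/mol), default 0.1.
#' @param lj_rmin_half Uniform LJ r_min/2 (Angstrom), default 2.0.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(residues_per_segment = c(16L, 32L, 16L),
                           segment_ids = c("RASC", "SOS", "RASA"),
                           residues_per_community = 8L,
                           grid_spacing = 3.0,
                           bridge_gap = 4.0,
                           interface_gap = 3.4,
                           contact_cutoff_build = 10.0,
                           spring_constant = 10.0,
                           coupling_edges = NULL,
                           coupling_factor = 50.0,
                           plant_path = NULL,
                           stiffen_segments = NULL,
                           stiffen_factor = 10.0,
                           kT = 0.593,
                           n_frames = 2000L,
                           seed = 1L,
                           charge_magnitude = 0.5,
                           lj_eps = 0.1,
                           lj_rmin_half = 2.0) {
  if (length(residues_per_segment) != 3L || any(residues_per_segment < 2))
    abort("residues_per_segment must be three integers >= 2")
  if (kT < 0) abort("kT must be >= 0")
  if (n_frames < 1) abort("n_frames must be >= 1")
  if (!is.null(stiffen_segments) && length(stiffen_segments) != 2L)
    abort("stiffen_segments must name exactly two segments")
  structure(list(
    residues_per_segment = as.integer(residues_per_segment),
    segment_ids = segment_ids,
    residues_per_community = as.integer(residues_per_community),
    grid_spacing = grid_spacing, bridge_gap = bridge_gap,
    interface_gap = interface_gap,
    contact_cutoff_build = contact_cutoff_build,
    spring_constant = spring_constant,
    coupling_edges = coupling_edges, coupling_factor = coupling_factor,
    plant_path = plant_path,
    stiffen_segments = stiffen_segments, stiffen_factor = stiffen_factor,
    kT = kT, n_frames = as.integer(n_frames), seed = as.integer(seed),
    charge_magnitude = charge_magnitude, lj_eps = lj_eps,
    lj_rmin_half = lj_rmin_half), class = "synthetic_spec")
}

# local lattice coordinates of a blob of m beads: 2 x 2 x ceil(m/4) grid
blob_coords <- function(m, a) {
  idx <- seq_len(m) - 1L
  cbind((idx %% 2L) * a, ((idx %/% 2L) %% 2L) * a, (idx %/% 4L) * a)
}

#' Build the bead topology and reference coordinates of a synthetic complex
#'
#' Places the three segments so that designed inter-segment interfaces exist:
#' the catalytic segment sits above the start of the central segment, the
#' allosteric segment below its far end, with facing beads `interface_gap`
#' apart.  Deterministic (the geometry involves no randomness).
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `topology` (a [topology()] with bead charges and LJ
#'   parameters assigned), `reference` (`N x 3` coordinates, Angstrom), and
#'   `communities` (integer planted community id per residue).
#' @export
build_bead_complex <- function(spec) {
  a <- spec$grid_spacing
  n_seg <- spec$residues_per_segment
  coords <- NULL
  segid <- character(0)
  community <- integer(0)
  blob_counter <- 0L

  seg_block <- function(n_res) {
    m <- spec$residues_per_community
    sizes <- rep(m, n_res %/% m)
    if (n_res %% m) sizes <- c(sizes, n_res %% m)
    if (!length(sizes)) sizes <- n_res
    xy <- NULL
    comm <- integer(0)
    for (b in seq_along(sizes)) {
      loc <- blob_coords(sizes[b], a)
      loc[, 1] <- loc[, 1] + (b - 1) * (a + spec$bridge_gap)
      xy <- rbind(xy, loc)
      comm <- c(comm, rep(b, sizes[b]))
    }
    list(coords = xy, comm = comm)
  }

  s2 <- seg_block(n_seg[2])          # central segment at the origin
  s1 <- seg_block(n_seg[1])          # catalytic segment above its start
  s3 <- seg_block(n_seg[3])          # allosteric segment below its far end
  z2_top <- max(s2$coords[, 3])
  s1$coords[, 3] <- s1$coords[, 3] + z2_top + spec$interface_gap
  s3$coords[, 3] <- s3$coords[, 3] - max(s3$coords[, 3]) - spec$interface_gap
  s3$coords[, 1] <- s3$coords[, 1] + max(s2$coords[, 1]) - max(s3$coords[, 1])

  parts <- list(s1, s2, s3)
  for (k in 1:3) {
    coords <- rbind(coords, parts[[k]]$coords)
    segid <- c(segid, rep(spec$segment_ids[k], n_seg[k]))
    community <- c(community, parts[[k]]$comm + blob_counter)
    blob_counter <- blob_counter + max(parts[[k]]$comm)
  }

  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  if (min(d) < 2.0)
    abort("steric overlap: bead pair closer than 2 Angstrom in built geometry")

  n <- sum(n_seg)
  atoms <- data.frame(
    name = "CA", resid = seq_len(n), resname = "BEA", segid = segid,
    mass = 110.0,
    charge = spec$charge_magnitude * ifelse(seq_len(n) %% 2L == 1L, 1, -1),
    eps = spec$lj_eps, rmin_half = spec$lj_rmin_half,
    stringsAsFactors = FALSE)
  list(topology = topology(atoms, has_parameters = TRUE),
       reference = coords, communities = community)
}

# Spring list for the elastic network: data.frame(i, j, k, type) over residue
# pairs within the build cutoff.  Background springs are bond-directional
# (anisotropic-network style).  Planted couplings and stiffened interface
# contacts are isotropic restraints on the full displacement difference, so
# strongly coupled residues move in near lock-step and carry a near-unit
# motion correlation -- the designed high-correlation signalling channel.
enm_springs <- function(complex, spec) {
  ref <- complex$reference
  d <- as.matrix(stats::dist(ref))
  n <- nrow(ref)
  pairs <- which(upper.tri(d) & d <= spec$contact_cutoff_build, arr.ind = TRUE)
  k <- rep(spec$spring_constant, nrow(pairs))
  type <- rep("bond", nrow(pairs))
  segid <- complex$topology$atoms$segid
  if (!is.null(spec$stiffen_segments)) {
    ss <- spec$stiffen_segments
    cross <- (segid[pairs[, 1]] == ss[1] & segid[pairs[, 2]] == ss[2]) |
             (segid[pairs[, 1]] == ss[2] & segid[pairs[, 2]] == ss[1])
    near <- d[pairs] <= 5.0
    k[cross & near] <- k[cross & near] * spec$stiffen_factor
    type[cross & near] <- "iso"
  }
  ce <- resolve_coupling_edges(complex, spec)
  if (!is.null(ce)) {
    key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    ck <- paste(pmin(ce$i, ce$j), pmax(ce$i, ce$j))
    hit <- key %in% ck
    if (sum(hit) < nrow(ce))
      abort("coupling edge outside the elastic-network cutoff")
    k[hit] <- spec$spring_constant * spec$coupling_factor
    type[hit] <- "iso"
  }
  data.frame(i = pairs[, 1], j = pairs[, 2], k = k, type = type,
             stringsAsFactors = FALSE)
}

# coupling edges: explicit table, or fewest-hop contact chain between
# plant_path$source and plant_path$sink (contact = reference distance <= 4.5)
resolve_coupling_edges <- function(complex, spec) {
  if (!is.null(spec$coupling_edges)) return(spec$coupling_edges)
  if (is.null(spec$plant_path)) return(NULL)
  chain <- reference_contact_chain(complex$reference, spec$plant_path$source,
                                   spec$plant_path$sink)
  data.frame(i = chain[-length(chain)], j = chain[-1])
}

# fewest-hop path between two residues in the reference contact graph
reference_contact_chain <- function(reference, source, sink, cutoff = 4.5) {
  if (source == sink) abort("source and sink residues must differ")
  d <- as.matrix(stats::dist(reference))
  adj <- d <= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  p <- igraph::shortest_paths(g, from = source, to = sink, output = "vpath")
  chain <- as.integer(p$vpath[[1]])
  if (length(chain) < 2) abort("no contact path between residues %d and %d", source, sink)
  chain
}

# 3N x 3N elastic-network Hessian from a spring list; "bond" springs act
# along the reference bond direction, "iso" springs on the full
# displacement-difference vector
enm_hessian <- function(reference, springs) {
  n <- nrow(reference)
  H <- matrix(0, 3 * n, 3 * n)
  for (r in seq_len(nrow(springs))) {
    i <- springs$i[r]; j <- springs$j[r]; k <- springs$k[r]
    if (identical(springs$type[r], "iso")) {
      B <- k * diag(3)
    } else {
      dv <- reference[i, ] - reference[j, ]
      e <- dv / sqrt(sum(dv^2))
      B <- k * tcrossprod(e)
    }
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, ii] <- H[ii, ii] + B
    H[jj, jj] <- H[jj, jj] + B
    H[ii, jj] <- H[ii, jj] - B
    H[jj, ii] <- H[jj, ii] - B
  }
  H
}

# orthonormal basis of the 6 rigid-body modes (3 translations, 3 infinitesimal
# rotations) at the reference geometry
rigid_basis <- function(reference) {
  n <- nrow(reference)
  ctr <- colMeans(reference)
  rc <- sweep(reference, 2, ctr)
  vecs <- matrix(0, 3 * n, 6)
  for (a in 1:3) vecs[seq(a, 3 * n, by = 3), a] <- 1
  axes <- diag(3)
  for (a in 1:3) {
    cr <- t(apply(rc, 1, function(r) c(axes[a, 2] * r[3] - axes[a, 3] * r[2],
                                       axes[a, 3] * r[1] - axes[a, 1] * r[3],
                                       axes[a, 1] * r[2] - axes[a, 2] * r[1])))
    vecs[, 3 + a] <- mat2vec(cr)
  }
  qr.Q(qr(vecs))
}

#' Sample a Gaussian frame ensemble from the elastic-network covariance
#'
#' Frames are the reference coordinates plus Gaussian displacements with
#' covariance `Sigma = kT * H^+`, where `H` is the elastic-network Hessian
#' and the pseudo-inverse spans all non-rigid-body modes (the six zero modes
#' carry no variance, so frames come out already superposed).  The exact
#' sampling covariance is returned as planted ground truth.
#'
#' @param complex Output of [build_bead_complex()].
#' @param spec The [synthetic_spec()] used to build it.
#' @return A list with `ensemble` (an [ensemble()]), and `truth`: a list with
#'   `covariance` (exact `3N x 3N` Sigma), `partition` (planted community id
#'   per residue), `path` (planted pathway residue chain, or `NULL`),
#'   `coupling_edges`, and `seed`.
#' @export
sample_ensemble <- function(complex, spec) {
  ref <- complex$reference
  n <- nrow(ref)
  springs <- enm_springs(complex, spec)

  g <- igraph::graph_from_data_frame(springs[, c("i", "j")], directed = FALSE,
                                     vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    sizes <- paste(comp$csize, collapse = ", ")
    abort("elastic network is disconnected (%d components of sizes %s)", comp$no, sizes)
  }

  # project the 6 translation/rotation modes out of the Hessian, then invert
  # on the complement: the planted covariance carries zero rigid-body
  # variance, i.e. frames are sampled already superposed
  H <- enm_hessian(ref, springs)
  Q <- rigid_basis(ref)
  P <- diag(3 * n) - Q %*% t(Q)
  Hp <- P %*% H %*% P
  eig <- eigen(Hp, symmetric = TRUE)
  tol <- max(eig$values) * 1e-9
  nz <- eig$values > tol
  if (sum(!nz) != 6L)
    abort("elastic network has internal zero modes (%d null modes, expected the 6 rigid ones)",
          sum(!nz))
  V <- eig$vectors[, nz, drop = FALSE]
  lam <- eig$values[nz]
  Sigma <- spec$kT * V %*% (t(V) / lam)

  # sample displacements V diag(amp) Z, one column per frame
  amp <- sqrt(spec$kT / lam)
  xyz <- with_seed(spec$seed, {
    Z <- matrix(stats::rnorm(spec$n_frames * length(lam)), nrow = length(lam))
    disp <- V %*% (Z * amp)
    sweep(t(disp), 2, mat2vec(ref), `+`)
  })

  ens <- ensemble(complex$topology, xyz)
  chain <- NULL
  ce <- resolve_coupling_edges(complex, spec)
  if (!is.null(spec$plant_path)) {
    chain <- plant_pathway(complex, spec, spec$plant_path$source, spec$plant_path$sink)
  }
  list(ensemble = ens,
       truth = list(covariance = Sigma, partition = complex$communities,
                    path = chain, coupling_edges = ce, seed = spec$seed))
}

#' Planted allosteric pathway of a synthetic complex
#'
#' Returns the residue chain along which spring constants were raised so that
#' chain edges carry near-unit motion correlations and hence minimal
#' `-log|C|` edge distances: in the infinite-sampling limit the chain is the
#' optimal source-to-sink pathway.  Returns `NULL` when no couplings are
#' planted (no designed path).
#'
#' @param complex Output of [build_bead_complex()].
#' @param spec The matching [synthetic_spec()].
#' @param source,sink Global residue indices.
#' @return Integer residue chain from `source` to `sink`, or `NULL`.
#' @export
plant_pathway <- function(complex, spec, source, sink) {
  if (source == sink) abort("source and sink residues must differ")
  ce <- resolve_coupling_edges(complex, spec)
  if (is.null(ce) || !nrow(ce)) return(NULL)
  n <- nrow(complex$reference)
  g <- igraph::graph_from_data_frame(ce, directed = FALSE,
                                     vertices = data.frame(name = seq_len(n)))
  p <- suppressWarnings(igraph::shortest_paths(g, from = source, to = sink,
                                               output = "vpath"))
  chain <- as.integer(p$vpath[[1]])
  if (length(chain) < 2)
    abort("planted couplings do not connect residues %d and %d", source, sink)
  chain
}

#' Generate a complete synthetic system in one call
#'
#' Convenience wrapper: [build_bead_complex()] then [sample_ensemble()].
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `ensemble`, `truth`, `reference`, `complex` and `spec`.
#' @export
synthetic_system <- function(spec) {
  cx <- build_bead_complex(spec)
  s <- sample_ensemble(cx, spec)
  list(ensemble = s$ensemble, truth = s$truth, reference = cx$reference,
       complex = cx, spec = spec)
}

#' Closed-form residue-residue correlation matrix implied by a covariance
#'
#' For a `3N x 3N` positional covariance `Sigma`, the motion correlation of
#' residues i and j is `tr(Sigma_ij) / sqrt(tr(Sigma_ii) tr(Sigma_jj))`,
#' i.e. the infinite-sampling limit of the dynamic cross-correlation matrix.
#'
#' @param Sigma `3N x 3N` covariance matrix.
#' @return `N x N` correlation matrix.
#' @export
dccm_from_covariance <- function(Sigma) {
  n <- nrow(Sigma) / 3L
  tr3 <- function(i, j) {
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    sum(diag(Sigma[ii, jj, drop = FALSE]))
  }
  selfs <- vapply(seq_len(n), function(i) tr3(i, i), numeric(1))
  C <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    C[i, j] <- C[j, i] <- tr3(i, j) / sqrt(selfs[i] * selfs[j])
  }
  C
}
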