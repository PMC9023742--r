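#' Detect hydrogen bonds in one frame by geometric criteria
#'
#' A donor-acceptor contact is present when the donor-acceptor distance is at
#' most `d_max` and (when a hydrogen position is known) the donor-H-acceptor
#' angle is at least `angle_min`.  Bead models carry no hydrogens, so a
#' distance-only proxy mode is provided and flagged in the result; with
#' `strict = TRUE` missing hydrogens are an error instead.
#'
#' @param coords `N x 3` frame coordinates.
#' @param donors Integer vector of donor heavy-atom indices.
#' @param acceptors Integer vector of acceptor atom indices.
#' @param d_max Donor-acceptor distance cutoff (Angstrom), default 3.5
#'   (package convention; configurable).
#' @param angle_min Donor-H-acceptor angle cutoff (degrees), default 120.
#' @param hydrogens Optional integer vector, same length as `donors`, of
#'   attached hydrogen atom indices (`NA` allowed per donor).
#' @param strict Error on donors without hydrogens instead of falling back to
#'   the distance-only proxy.
#' @return Data.frame with `donor`, `acceptor`, `distance`, `angle` (`NA` in
#'   proxy mode); attribute `proxy_mode` records whether any contact was
#'   scored without an angle term.
#' @export
detect_hbonds <- function(coords, donors, acceptors, d_max = 3.5,
                          angle_min = 120, hydrogens = NULL, strict = FALSE) {
  if (!length(donors) || !length(acceptors)) abort("empty donor or acceptor set")
  if (is.null(hydrogens)) hydrogens <- rep(NA_integer_, length(donors))
  if (length(hydrogens) != length(donors))
    abort("hydrogens must align with donors")
  if (strict && any(is.na(hydrogens)))
    abort("strict mode: donors without hydrogen positions: %s",
          paste(donors[is.na(hydrogens)], collapse = ", "))
  out <- NULL
  proxy <- FALSE
  for (k in seq_along(donors)) {
    d_at <- donors[k]
    dv <- sweep(coords[acceptors, , drop = FALSE], 2, coords[d_at, ])
    dist <- sqrt(rowSums(dv^2))
    ok <- dist <= d_max & acceptors != d_at
    ang <- rep(NA_real_, length(acceptors))
    if (!is.na(hydrogens[k])) {
      h <- coords[hydrogens[k], ]
      v1 <- coords[d_at, ] - h
      for (m in which(ok)) {
        v2 <- coords[acceptors[m], ] - h
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang[m] <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      }
      ok <- ok & !is.na(ang) & ang >= angle_min
    } else if (any(ok)) proxy <- TRUE
    if (any(ok))
      out <- rbind(out, data.frame(donor = d_at, acceptor = acceptors[ok],
                                   distance = dist[ok], angle = ang[ok]))
  }
  out <- out %||% data.frame(donor = integer(0), acceptor = integer(0),
                             distance = numeric(0), angle = numeric(0))
  attr(out, "proxy_mode") <- proxy
  out
}

#' Detect salt bridges in one frame
#'
#' A bridge is present when the minimum heavy-atom distance between a
#' cationic and an anionic group is at most `d_max` (default 4.0 Angstrom,
#' package convention).
#'
#' @param coords `N x 3` frame coordinates.
#' @param cationic_groups,anionic_groups Lists of integer atom-index vectors,
#'   one element per charged group.
#' @param d_max Distance cutoff (Angstrom).
#' @return Data.frame with `cation_group`, `anion_group`, `min_distance`.
#' @export
detect_salt_bridges <- function(coords, cationic_groups, anionic_groups,
                                d_max = 4.0) {
  if (!length(cationic_groups) || !length(anionic_groups))
    abort("empty charged-group definitions")
  out <- NULL
  for (ci in seq_along(cationic_groups)) {
    for (ai in seq_along(anionic_groups)) {
      A <- coords[cationic_groups[[ci]], , drop = FALSE]
      B <- coords[anionic_groups[[ai]], , drop = FALSE]
      d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
      dmin <- sqrt(max(min(d2), 0))
      if (dmin <= d_max)
        out <- rbind(out, data.frame(cation_group = ci, anion_group = ai,
                                     min_distance = dmin))
    }
  }
  out %||% data.frame(cation_group = integer(0), anion_group = integer(0),
                      min_distance = numeric(0))
}

#' Interfacial interaction occupancy between two segments
#'
#' Scans every frame for cross-segment hydrogen bonds (distance-only proxy
#' for bead models) and salt bridges, restricted to residue pairs lying in
#' different segments, and reports per-pair occupancies plus the number of
#' distinct interactions present at a designated representative frame (the
#' cluster-table style count).
#'
#' @param ens An [ensemble()] whose topology carries charges.
#' @param segA,segB Segment ids (must be disjoint).
#' @param hbond_dmax Hydrogen-bond distance cutoff (A), default 3.5.
#' @param salt_dmax Salt-bridge distance cutoff (A), default 4.0.
#' @param representative_frame Frame index for the interaction count,
#'   default 1 (pass a cluster representative for cluster-style tables).
#' @return Object of class `interface_summary`: `records` (one row per
#'   interaction pair with class, residues, occupancy and presence at the
#'   representative frame), `count_representative`, and the criteria used.
#' @export
interface_summary <- function(ens, segA, segB, hbond_dmax = 3.5,
                              salt_dmax = 4.0, representative_frame = 1L) {
  a <- ens$topology$atoms
  if (identical(segA, segB)) abort("interface segments must differ")
  iA <- which(a$segid %in% segA); iB <- which(a$segid %in% segB)
  if (length(intersect(iA, iB))) abort("overlapping segment selections")
  if (!length(iA) || !length(iB)) abort("unknown segment id")

  # candidate cross-segment pairs: polar beads (|q|>0) for proxy H-bonds,
  # opposite-charge beads for salt bridges
  qa <- a$charge
  cand <- expand.grid(i = iA, j = iB)
  polar <- abs(qa[cand$i]) > 0 & abs(qa[cand$j]) > 0
  opposite <- qa[cand$i] * qa[cand$j] < 0

  dmat <- function(f) {
    m <- vec2mat(ens$xyz[f, ])
    sqrt(rowSums((m[cand$i, , drop = FALSE] - m[cand$j, , drop = FALSE])^2))
  }
  nf <- nrow(ens$xyz)
  hb_hits <- matrix(FALSE, nf, nrow(cand))
  sb_hits <- matrix(FALSE, nf, nrow(cand))
  for (f in seq_len(nf)) {
    d <- dmat(f)
    hb_hits[f, ] <- polar & d <= hbond_dmax
    sb_hits[f, ] <- opposite & d <= salt_dmax
  }
  build <- function(hits, klass) {
    occ <- colMeans(hits)
    keep <- occ > 0
    if (!any(keep)) return(NULL)
    data.frame(class = klass,
               atom_i = cand$i[keep], atom_j = cand$j[keep],
               resid_i = a$resid[cand$i[keep]], resid_j = a$resid[cand$j[keep]],
               segid_i = a$segid[cand$i[keep]], segid_j = a$segid[cand$j[keep]],
               occupancy = occ[keep],
               present_representative = hits[representative_frame, keep],
               stringsAsFactors = FALSE)
  }
  rec <- rbind(build(hb_hits, "hydrogen_bond"), build(sb_hits, "salt_bridge"))
  rec <- rec %||% data.frame(class = character(0), atom_i = integer(0),
                             atom_j = integer(0), resid_i = integer(0),
                             resid_j = integer(0), segid_i = character(0),
                             segid_j = character(0), occupancy = numeric(0),
                             present_representative = logical(0))
  structure(list(records = rec,
                 count_representative = sum(rec$present_representative),
                 mean_occupancy = if (nrow(rec)) mean(rec$occupancy) else 0,
                 criteria = list(hbond_dmax = hbond_dmax, salt_dmax = salt_dmax,
                                 proxy_mode = TRUE),
                 representative_frame = representative_frame),
            class = "interface_summary")
}

#' @export
print.interface_summary <- function(x, ...) {
  cat(sprintf("interface: %d interacting pair(s); %d present at frame %d; mean occupancy %.2f\n",
              nrow(x$records), x$count_representative, x$representative_frame,
              x$mean_occupancy))
  invisible(x)
}
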