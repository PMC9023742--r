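#' Kabsch superposition of one frame onto a reference
#'
#' Finds the proper rotation and translation minimizing the RMSD of the mask
#' atoms, applies it to the whole frame, and reports the minimized mask RMSD.
#'
#' @param mobile `N x 3` coordinates to move.
#' @param reference `N x 3` reference coordinates (same atom list).
#' @param mask Integer vector of atom indices used for the fit (default all).
#' @return A list with `coords` (superposed `N x 3`), `rmsd` (Angstrom),
#'   `rotation` (3x3) and `translation` (length 3).
#' @export
kabsch_superpose <- function(mobile, reference, mask = seq_len(nrow(reference))) {
  if (!all(dim(mobile) == dim(reference)))
    abort("mobile and reference coordinate sizes differ")
  if (length(mask) < 3) abort("superposition needs at least 3 mask atoms")
  P <- mobile[mask, , drop = FALSE]
  Q <- reference[mask, , drop = FALSE]
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  sv <- svd(crossprod(Pc, Qc))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-300))
    abort("degenerate (collinear) mask: superposition is ill-defined")
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  out <- sweep(sweep(mobile, 2, pc) %*% R, 2, qc, `+`)
  rmsd <- sqrt(mean(rowSums((out[mask, , drop = FALSE] - Q)^2)))
  list(coords = out, rmsd = rmsd, rotation = R, translation = qc - pc %*% R)
}

# Superpose every frame of an ensemble; reference is a frame index, an
# N x 3 matrix, or "mean" (two-pass: fit to frame 1, then to the mean).
superpose_ensemble <- function(ens, fit_mask = NULL, reference = 1L) {
  fit_mask <- fit_mask %||% select_atoms(ens$topology)
  fit_once <- function(xyz, ref_mat) {
    t(apply(xyz, 1, function(row) {
      mat2vec(kabsch_superpose(vec2mat(row), ref_mat, fit_mask)$coords)
    }))
  }
  if (is.matrix(reference)) {
    xyz <- fit_once(ens$xyz, reference)
  } else if (identical(reference, "mean")) {
    xyz <- fit_once(ens$xyz, vec2mat(ens$xyz[1L, ]))
    xyz <- fit_once(xyz, vec2mat(colMeans(xyz)))
  } else {
    xyz <- fit_once(ens$xyz, vec2mat(ens$xyz[as.integer(reference), ]))
  }
  ensemble(ens$topology, xyz, ens$frame_times)
}

#' Per-frame RMSD of an ensemble against a reference frame
#'
#' Each frame is first superposed on `fit_mask`, then the RMSD is evaluated
#' over `report_mask` (so e.g. switch-region deviations can be reported after
#' an all-C-alpha fit).  The reference defaults to the first frame, the usual
#' "relative to the initial structure" convention.
#'
#' @param ens An [ensemble()].
#' @param reference Frame index or `N x 3` matrix.
#' @param fit_mask,report_mask Atom index vectors; default all C-alpha atoms.
#' @return A data.frame with `frame` and `rmsd` (Angstrom); attributes `mean`
#'   and `sd` carry the summary.
#' @export
rmsd_series <- function(ens, reference = 1L, fit_mask = NULL, report_mask = NULL) {
  fit_mask <- fit_mask %||% select_atoms(ens$topology)
  report_mask <- report_mask %||% fit_mask
  if (!length(report_mask)) abort("empty report_mask")
  ref <- if (is.matrix(reference)) reference else vec2mat(ens$xyz[as.integer(reference), ])
  vals <- apply(ens$xyz, 1, function(row) {
    fit <- kabsch_superpose(vec2mat(row), ref, fit_mask)
    sqrt(mean(rowSums((fit$coords[report_mask, , drop = FALSE] -
                         ref[report_mask, , drop = FALSE])^2)))
  })
  out <- data.frame(frame = seq_len(nrow(ens$xyz)), rmsd = vals)
  attr(out, "mean") <- mean(vals)
  attr(out, "sd") <- stats::sd(vals)
  out
}

#' Per-residue RMSF of C-alpha atoms
#'
#' Frames are superposed on `fit_mask` (all C-alpha atoms by default) onto
#' the ensemble mean structure, then
#' `RMSF_i = sqrt(<|r_i - <r_i>|^2>)` is evaluated at each residue's
#' C-alpha position.
#'
#' @param ens An [ensemble()] with at least two frames.
#' @param fit_mask Atom index vector for the fit; default all C-alpha atoms.
#' @return A data.frame with `segid`, `resid` and `rmsf` (Angstrom).
#' @export
rmsf_per_residue <- function(ens, fit_mask = NULL) {
  if (nrow(ens$xyz) < 2) abort("RMSF needs at least 2 frames")
  fit_mask <- fit_mask %||% select_atoms(ens$topology)
  sup <- superpose_ensemble(ens, fit_mask, reference = "mean")
  ca <- calpha_map(ens$topology)
  cols <- xyz_cols(ca)
  X <- sup$xyz[, cols, drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  msf3 <- colMeans(Xc^2)                      # per-coordinate mean square
  rmsf <- sqrt(colSums(matrix(msf3, nrow = 3)))
  a <- ens$topology$atoms
  data.frame(segid = a$segid[ca], resid = a$resid[ca], rmsf = rmsf,
             row.names = NULL)
}

#' Distribution of a residue-pair C-alpha distance over an ensemble
#'
#' Tracks the Euclidean C-alpha distance of a residue pair per frame and
#' histograms it; such distributions diagnose e.g. nucleotide-pocket opening
#' via pairs flanking the phosphate and ribose sites.
#'
#' @param ens An [ensemble()].
#' @param pair Integer vector of two residue indices (global numbering), or a
#'   character vector of two `"segid:resid"` labels.
#' @param bin_width Histogram bin width (Angstrom), default 0.1.
#' @return A list of class `distance_series`: `distances` (per frame, A),
#'   `breaks`, `prob` (bin probabilities summing to 1), `mean`, `mode`.
#' @export
pair_distance_distribution <- function(ens, pair, bin_width = 0.1) {
  ca <- calpha_map(ens$topology)
  idx <- resolve_residue_pair(ens$topology, pair)
  if (idx[1] == idx[2]) abort("distance pair must be two distinct residues")
  c1 <- xyz_cols(ca[idx[1]]); c2 <- xyz_cols(ca[idx[2]])
  dv <- ens$xyz[, c1, drop = FALSE] - ens$xyz[, c2, drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  prob <- h$counts / sum(h$counts)
  structure(list(pair = idx, distances = d, breaks = breaks, prob = prob,
                 mean = mean(d), mode = h$mids[which.max(h$counts)]),
            class = "distance_series")
}

# residue pair spec -> positions in the residue (calpha_map) ordering
resolve_residue_pair <- function(top, pair) {
  ca <- calpha_map(top)
  a <- top$atoms
  if (is.character(pair)) {
    idx <- match(pair, names(ca))
    if (any(is.na(idx))) abort("unknown residue label(s): %s",
                               paste(pair[is.na(idx)], collapse = ", "))
  } else {
    resids <- a$resid[ca]
    idx <- match(as.integer(pair), resids)
    if (any(is.na(idx))) abort("unknown residue index(es): %s",
                               paste(pair[is.na(idx)], collapse = ", "))
  }
  idx
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("distance series: %d frames, mean %.2f A, mode %.2f A\n",
              length(x$distances), x$mean, x$mode))
  invisible(x)
}
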