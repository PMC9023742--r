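#' Atom topology for a multi-segment complex
#'
#' A topology holds the fixed per-atom annotation shared by every frame of an
#' ensemble: atom and residue names, 1-based residue indices (preserved from
#' the input file, matching the residue labels used in the structural biology
#' literature, e.g. G12, D30, K566), segment identifiers (e.g. `RASC`, `SOS`,
#' `RASA`; at most 4 characters if PDB output is wanted), masses, partial
#' charges (e), Lennard-Jones well depths epsilon (kcal/mol) and
#' minimum-energy half-distances r_min/2 (Angstrom).
#'
#' @param atoms A data.frame with columns `name`, `resid`, `resname`, `segid`,
#'   `mass`, `charge`, `eps`, `rmin_half`, one row per atom in file order.
#' @param has_parameters Logical; `TRUE` when charges and LJ parameters were
#'   supplied (by a sidecar or a generator).  Energy operations refuse to run
#'   on a topology without parameters.
#' @return An object of class `topology`.
#' @seealso [read_topology_sidecar()], [read_multimodel_pdb()]
#' @export
topology <- function(atoms, has_parameters = TRUE) {
  req <- c("name", "resid", "resname", "segid", "mass", "charge", "eps", "rmin_half")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) abort("topology atoms table lacks columns: %s", paste(miss, collapse = ", "))
  atoms$resid <- as.integer(atoms$resid)
  atoms$segid <- as.character(atoms$segid)
  atoms$name <- as.character(atoms$name)
  atoms$resname <- as.character(atoms$resname)
  if (any(!is.finite(atoms$charge))) abort("non-finite partial charge in topology")
  if (any(!is.finite(atoms$eps)) || any(atoms$eps < 0)) abort("LJ epsilon must be finite and >= 0")
  if (any(!is.finite(atoms$rmin_half)) || any(atoms$rmin_half <= 0)) abort("LJ r_min/2 must be > 0")
  # residue indices strictly increasing within each segment
  for (sg in unique(atoms$segid)) {
    r <- atoms$resid[atoms$segid == sg]
    ru <- unique(r)
    if (any(diff(ru) <= 0)) abort("residue indices not strictly increasing in segment %s", sg)
  }
  # exactly one C-alpha equivalent atom per residue
  key <- paste(atoms$segid, atoms$resid)
  ca <- atoms$name == "CA"
  n_ca <- tapply(ca, key, sum)
  if (any(n_ca != 1)) {
    bad <- names(n_ca)[n_ca != 1]
    abort("every residue needs exactly one CA atom; offending residue(s): %s",
          paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(list(atoms = atoms, has_parameters = isTRUE(has_parameters)),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d residues, %d segment(s) [%s]%s\n",
              nrow(x$atoms), length(unique(paste(x$atoms$segid, x$atoms$resid))),
              length(unique(x$atoms$segid)),
              paste(unique(x$atoms$segid), collapse = ", "),
              if (x$has_parameters) "" else " (no charges/LJ parameters)"))
  invisible(x)
}

#' Number of atoms in a topology
#' @param top A `topology`.
#' @return Integer atom count.
#' @export
n_atoms <- function(top) UseMethod("n_atoms")
#' @export
n_atoms.topology <- function(top) nrow(top$atoms)
#' @export
n_atoms.ensemble <- function(top) nrow(top$topology$atoms)

#' Map residues to their C-alpha atom rows
#'
#' @param top A `topology`.
#' @return Integer vector of atom indices, one per residue in segment/residue
#'   order of first appearance, named `segid:resid`.
#' @export
calpha_map <- function(top) {
  a <- top$atoms
  idx <- which(a$name == "CA")
  stats::setNames(idx, paste0(a$segid[idx], ":", a$resid[idx]))
}

#' Select atom indices by segment, residue and atom name
#'
#' The package's selection-mask primitive: every analysis operation takes a
#' plain integer vector of atom indices, and this helper builds one.
#'
#' @param top A `topology`.
#' @param segid Optional character vector of segment ids to keep.
#' @param resid Optional integer vector of residue indices to keep.
#' @param calpha If `TRUE` (default) restrict to C-alpha atoms.
#' @return Integer vector of atom indices (file order).
#' @export
select_atoms <- function(top, segid = NULL, resid = NULL, calpha = TRUE) {
  a <- top$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(segid)) keep <- keep & a$segid %in% segid
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (calpha) keep <- keep & a$name == "CA"
  out <- which(keep)
  if (!length(out)) abort("empty atom selection")
  out
}

# xyz column indices (into an F x 3N matrix) for a set of atom indices
xyz_cols <- function(atom_idx) {
  as.numeric(t(cbind(3 * atom_idx - 2, 3 * atom_idx - 1, 3 * atom_idx)))
}

#' Frame ensemble of a fixed atom list
#'
#' Couples a [topology()] with an `F x 3N` coordinate matrix (one row per
#' frame; columns `x1, y1, z1, x2, ...` in Angstrom), the layout also used by
#' classic trajectory-analysis packages.
#'
#' @param top A `topology`.
#' @param xyz Numeric `F x 3N` matrix of coordinates.
#' @param frame_times Optional numeric vector of frame times (ns).
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(top, xyz, frame_times = NULL) {
  if (!inherits(top, "topology")) abort("top must be a topology")
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(top$atoms))
    abort("xyz has %d columns but topology implies %d", ncol(xyz), 3L * nrow(top$atoms))
  if (nrow(xyz) < 1L) abort("ensemble needs at least one frame")
  if (any(!is.finite(xyz))) abort("non-finite coordinates in ensemble")
  if (!is.null(frame_times) && length(frame_times) != nrow(xyz))
    abort("frame_times length does not match frame count")
  structure(list(topology = top, xyz = xyz, frame_times = frame_times),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble: %d frame(s) x %d atoms\n", nrow(x$xyz), nrow(x$topology$atoms)))
  print(x$topology)
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ens An `ensemble`.
#' @return Integer frame count.
#' @export
n_frames <- function(ens) nrow(ens$xyz)

#' Coordinates of one frame
#' @param ens An `ensemble`.
#' @param i Frame index.
#' @return `N x 3` coordinate matrix.
#' @export
frame_coords <- function(ens, i) {
  if (i < 1 || i > nrow(ens$xyz)) abort("frame index %d out of range", i)
  vec2mat(ens$xyz[i, ])
}

#' Subset an ensemble by frame
#' @param ens An `ensemble`.
#' @param frames Integer vector of frame indices to keep.
#' @return A new `ensemble`.
#' @export
subset_frames <- function(ens, frames) {
  ensemble(ens$topology, ens$xyz[frames, , drop = FALSE],
           if (!is.null(ens$frame_times)) ens$frame_times[frames])
}

# ---------------------------------------------------------------------------
# Topology sidecar: plain CSV, one row per atom, documented schema.
# Standard PDB carries no charges or LJ parameters, so they travel in this
# sidecar.  Columns: name,resid,resname,segid,mass,charge,eps,rmin_half.
# ---------------------------------------------------------------------------

#' Read a per-atom parameter sidecar
#'
#' The sidecar is a CSV file with a header row and one record per atom, in
#' the same order as the coordinate file, with columns `name`, `resid`,
#' `resname`, `segid`, `mass`, `charge` (elementary charges), `eps`
#' (kcal/mol) and `rmin_half` (Angstrom).
#'
#' @param path File path.
#' @return A `topology` with `has_parameters = TRUE`.
#' @export
read_topology_sidecar <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  topology(df, has_parameters = TRUE)
}

#' Write a per-atom parameter sidecar
#' @param top A `topology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_topology_sidecar <- function(top, path) {
  utils::write.csv(top$atoms, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Multi-model PDB reader/writer
# ---------------------------------------------------------------------------

parse_atom_record <- function(line, lineno) {
  get <- function(a, b) substr(line, a, b)
  x <- suppressWarnings(as.numeric(get(31, 38)))
  y <- suppressWarnings(as.numeric(get(39, 46)))
  z <- suppressWarnings(as.numeric(get(47, 54)))
  resid <- suppressWarnings(as.integer(get(23, 26)))
  if (any(is.na(c(x, y, z))) || is.na(resid))
    abort("unparsable ATOM record at line %d", lineno)
  list(name = trimws(get(13, 16)), resname = trimws(get(18, 20)),
       chain = trimws(get(22, 22)), resid = resid,
       x = x, y = y, z = z, segid = trimws(get(73, 76)))
}

#' Read a multi-model PDB file into an ensemble
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; a file without `MODEL`
#' records is read as a single frame.  Residue numbering is preserved exactly
#' as in the file (1-based).  Segment identity is taken from the PDB segment
#' id field (columns 73-76) when present, else from the chain id, unless a
#' sidecar overrides it.  Without a sidecar, charges and LJ well depths
#' default to zero and energy operations refuse to run.
#'
#' @param path PDB file path.
#' @param topology_sidecar Optional path of a parameter sidecar CSV
#'   (see [read_topology_sidecar()]); its atom order must match the PDB.
#' @return An [ensemble()].
#' @export
read_multimodel_pdb <- function(path, topology_sidecar = NULL) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM")
  is_model <- startsWith(lines, "MODEL")
  is_end <- startsWith(lines, "ENDMDL")
  if (!any(is_atom)) abort("no ATOM/HETATM records in %s", path)

  # assign a model index to every line
  if (any(is_model)) {
    model_no <- cumsum(is_model)
    model_no[model_no == 0 | is_end | is_model] <- NA
  } else {
    model_no <- rep(1L, length(lines))
  }
  atom_lines <- which(is_atom & !is.na(model_no))
  if (!length(atom_lines)) abort("no ATOM records inside MODEL blocks in %s", path)
  models <- model_no[atom_lines]
  n_models <- length(unique(models))
  counts <- tabulate(models)
  counts <- counts[counts > 0]
  if (length(unique(counts)) != 1L) {
    # name the first model whose atom count deviates from model 1
    uniq <- sort(unique(models))
    nc <- vapply(uniq, function(m) sum(models == m), integer(1))
    off <- uniq[which(nc != nc[1])[1]]
    abort("inconsistent atom count across models: model %d has %d atoms, expected %d",
          off, nc[which(uniq == off)], nc[1])
  }
  n_at <- counts[1]

  recs <- lapply(atom_lines, function(i) parse_atom_record(lines[i], i))
  first <- recs[seq_len(n_at)]
  segid <- vapply(first, function(r) if (nzchar(r$segid)) r$segid else r$chain, "")
  segid[!nzchar(segid)] <- "A"
  atoms <- data.frame(
    name = vapply(first, `[[`, "", "name"),
    resid = vapply(first, `[[`, 0L, "resid"),
    resname = vapply(first, `[[`, "", "resname"),
    segid = segid,
    mass = 12.0, charge = 0.0, eps = 0.0, rmin_half = 1.7,
    stringsAsFactors = FALSE)

  if (!is.null(topology_sidecar)) {
    top <- read_topology_sidecar(topology_sidecar)
    if (nrow(top$atoms) != n_at)
      abort("sidecar has %d atoms but PDB has %d", nrow(top$atoms), n_at)
  } else {
    top <- topology(atoms, has_parameters = FALSE)
  }

  xyz <- matrix(NA_real_, nrow = n_models, ncol = 3 * n_at)
  for (f in seq_len(n_models)) {
    block <- recs[((f - 1) * n_at + 1):(f * n_at)]
    xyz[f, ] <- as.numeric(vapply(block, function(r) c(r$x, r$y, r$z), numeric(3)))
  }
  ensemble(top, xyz)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Standard fixed-width ATOM records framed by `MODEL`/`ENDMDL`;
#' `read_multimodel_pdb(write_multimodel_pdb(x))` reproduces coordinates to
#' the 1e-3 Angstrom precision of the format.
#'
#' @param ens An [ensemble()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(ens, path) {
  if (max(abs(ens$xyz)) >= 1e4)
    abort("coordinate magnitude >= 1e4 Angstrom overflows the PDB format")
  a <- ens$topology$atoms
  if (any(nchar(a$segid) > 4))
    abort("segment id longer than the 4-character PDB segment field: %s",
          paste(unique(a$segid[nchar(a$segid) > 4]), collapse = ", "))
  name_fmt <- ifelse(nchar(a$name) < 4, sprintf(" %-3s", a$name), a$name)
  chain <- substr(a$segid, 1, 1)
  con <- file(path, "w")
  on.exit(close(con))
  nf <- nrow(ens$xyz)
  for (f in seq_len(nf)) {
    m <- vec2mat(ens$xyz[f, ])
    lines <- sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %-4s",
                     seq_len(nrow(a)) %% 100000, name_fmt, a$resname, chain,
                     a$resid, m[, 1], m[, 2], m[, 3], 1, 0, a$segid)
    writeLines(c(sprintf("MODEL     %4d", f), lines, "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}
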