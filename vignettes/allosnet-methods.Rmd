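---
title: "Methods: ensemble statistics, binding energetics and allosteric networks in allosnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble statistics, binding energetics and allosteric networks in allosnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allosnet)
```

# Scope and model

`allosnet` analyses frame ensembles of multi-segment protein complexes with
the question of long-range allostery in mind: how does occupancy of a distal
site reshape fluctuations, interfacial energetics and residue-level
communication at a catalytic site?  The motivating architecture is the
Ras/SOS positive-feedback system — a catalytic GTPase bound at the active
site of an exchange factor whose distal site holds a second, GTP-loaded
GTPase — but every stage operates on generic ensembles: an `ensemble` is a
fixed atom list with `F x 3N` coordinates (Angstrom), read from multi-model
PDB files or generated synthetically.

The pipeline stages are, in order: Kabsch superposition and RMSD/RMSF,
residue-pair distance distributions, principal component analysis of the
C-alpha covariance with clustering of the PC1–PC2 landscape, geometric
interface-interaction occupancy, end-state binding free-energy bookkeeping
with per-residue decomposition, and a dynamic cross-correlation network with
community detection and optimal/suboptimal pathway search.

# Conformational statistics

Superposition minimizes mask-atom RMSD over proper rotations and
translations (SVD-based Kabsch with a reflection guard).  RMSD series are
reported against the first frame by default — the usual "relative to the
initial structure" convention — after fitting each frame on a configurable
mask (all C-alpha atoms by default).  RMSF is computed about the ensemble
mean after an all-C-alpha fit; the fit mask is recorded because RMSF is only
defined up to the superposition convention.  Distance distributions use a
0.1 Angstrom histogram bin by default, fine enough to resolve the few-
Angstrom pocket-opening shifts such analyses are meant to detect; bin
probabilities sum to one.

Functional regions (P-loop, switch I/II, Cdc25-domain analogues) are never
hard-coded: selections are built from segment ids and residue ranges
supplied by the caller or the run configuration.

# Essential dynamics

PCA diagonalizes the unbiased (`F - 1`) covariance of superposed C-alpha
coordinates.  Eigenvalues are clamped at zero (rank deficiency is expected
when `3N > F`), projections are centred, and the eigenvalue sum equals the
total positional variance by construction — that identity is tested rather
than assumed.  Conformer clustering runs k-means on the PC1–PC2 plane with
a seeded 25-restart initialization; `K` defaults to 2.  k-means is a
deliberate choice of reproducibility over cleverness: the cluster count is
an input, the seed is recorded, and the representative of each cluster is
the member frame nearest the centroid (never a mean structure, which can be
unphysical).

# Interface interactions

Published interface counts for such complexes typically come from external
services whose geometric criteria are not recoverable, so `allosnet` uses
explicit package conventions, configurable and recorded in outputs:
a hydrogen bond is donor–acceptor distance <= 3.5 Angstrom with a
donor–H–acceptor angle >= 120 degrees when hydrogen positions exist; bead
models fall back to a flagged distance-only proxy.  A salt bridge is an
opposite-charge group pair with minimum heavy-atom distance <= 4.0 Angstrom.
Occupancy is the fraction of frames a contact is present; "table-style"
counts are the distinct interactions present at a designated representative
frame (intended to be a cluster representative).  Only cross-segment pairs
are counted in interface mode; detection is monotone in the cutoffs, which
is covered by a property test.

# Binding energetics

The end-state (single-trajectory) protocol evaluates, per frame, the
difference complex minus receptor minus ligand with all three species taken
from the same coordinates.  Consequences, which hold exactly per frame and
are asserted in tests: the intramolecular term vanishes; gas-phase
electrostatics (Coulomb constant 332.0637 kcal A mol^-1 e^-2, interior
dielectric 4.0 by default) and 12-6 Lennard-Jones sums reduce to cross-group
sums evaluated without cutoff (group sizes at desk scale make exact `O(N^2)`
sums cheaper to verify than any cutoff scheme); and the bookkeeping
identities `dE_MM = dE_vdW + dE_ele + dE_int`,
`dG_solv = dE_polar + dE_nonpolar`, `dG_binding = dE_MM + dG_solv` hold to
machine precision.  The entropy term is omitted and explicitly recorded as
omitted — the standard practice when comparing closely related complexes of
the same composition.

The polar solvation slot is filled by a generalized-Born model (pairwise
descreening effective radii, with the LJ `r_min/2` as intrinsic radius, and
the canonical `f_GB` interpolation), labelled as such in every output.  A
finite-difference Poisson–Boltzmann grid would be out of proportion for
this package's purpose; the GB term plays the same physical role, has exact
closed-form limits to test against (the Born ion, matched dielectrics, the
two-atom expression), and keeps the bookkeeping — which is what end-state
summaries actually expose — fully auditable.  The exterior dielectric
defaults to 80 (water).

The nonpolar term is `gamma * SASA + b` per species with
`gamma = 0.00542 kcal mol^-1 A^-2` and `b = 0.92` kcal/mol; SASA comes from
deterministic Shrake–Rupley sampling with 960 golden-spiral points per atom
(accurate to well under 1% on a sphere and bit-reproducible).  Because the
intercept is applied per species, the binding difference is
`gamma * dSASA - b`: interaction-driven terms vanish for separated
partners while the constant survives by construction.  Per-residue
decomposition assigns each cross-group pair term half to each residue and
polar/nonpolar terms per atom (the intercept difference spread uniformly),
so residue columns sum exactly to the totals.

A bundled copy of a published component table is shipped solely for the
bookkeeping auditor `verify_table2_consistency()`, which recomputes the
derived rows from the printed component means and flags a known sign
inconsistency in the binary column's polar term rather than repairing it.

# Allosteric networks

The dynamic cross-correlation matrix is
`C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` over superposed frames;
a zero-variance residue is a hard error (it would divide by zero).  Nodes
are residues; an edge exists when the inter-residue minimum atom distance
stays within 4.5 Angstrom in at least 75% of frames, and carries the
information distance `d_ij = -log |C_ij|`.  The logarithm is natural by
default (the convention of the betweenness-network literature) and the base
is configurable and recorded.  Edges with `C_ij = 0` are dropped as
infinitely distant.  A common display mask (`|C| < 0.3` shown as blank) is
a visualization convention only and never feeds the weights.

Community detection is Girvan–Newman: iterative removal of the maximum
edge-betweenness edge (shortest paths weighted by `d_ij`; ties broken
deterministically at the lowest node-index pair), scoring the
connected-component partition after every removal with weighted modularity
(weights `|C_ij|`) and returning the best partition over the dendrogram.
A known limitation, documented deliberately: Girvan–Newman is a divisive
heuristic, so on graphs without clean modular structure the dendrogram need
not contain the globally modularity-optimal partition — no faithful
implementation can guarantee that.  The suite therefore checks exact
agreement with exhaustive max-modularity search on random clique-block
graphs joined by sparse bridges (where the optimum provably lies on the
dendrogram), and checks recovery of planted communities on synthetic
complexes.

Optimal pathways use Floyd–Warshall over all pairs (checked against
Dijkstra); a disconnected pair yields an explicit no-path report.
Suboptimal pathways are all simple paths within a tolerance of the optimal
length, enumerated depth-first with the exact remaining-distance lower
bound as pruning and a hard expansion cap (a truncated search is flagged
and its count is a lower bound).  The tolerance is unitless under the
`-log|C|` convention; the conventional default of 20 is retained at face
value from the allosteric-pathway literature even though lengths printed in
"Angstrom" there mix units — the parameter is a pure config knob here.

# The synthetic generator

Because real microsecond trajectories of this system are not public,
ground-truth validation uses synthetic complexes.  Three bead segments —
catalytic, central, allosteric — are laid out as rows of compact lattice
blobs (2x2xk grids, 3.0 Angstrom spacing) joined by 4.0 Angstrom bridges,
with designed interfaces (3.4 Angstrom facing-bead gaps, inside both
interaction criteria) between the catalytic segment and the start of the
central segment and between the allosteric segment and its far end.  The
blobs are the planted communities: blob-internal contacts are dense and
tight, inter-blob bridges sparse and looser, so the contact graph splits at
the bridges.

Frames are drawn directly from the Gaussian with covariance
`Sigma = kT * H^+`, where `H` is an elastic-network Hessian on all bead
pairs within 10 Angstrom (spring constant 10 kcal mol^-1 A^-2,
`kT = 0.593` kcal/mol) and the pseudo-inverse spans the complement of the
six explicitly projected rigid-body vectors.  Sampling the distribution
exactly — rather than integrating dynamics — is the point: every downstream
statistic (RMSF, covariance, DCCM, PCA spectra) has a closed-form
expectation in `Sigma`, giving the strongest possible oracles.  Frames come
out already superposed (the rigid modes carry zero variance); a separate
test re-injects random rigid motions to exercise the superposition stage.

Planted allosteric pathways are isotropic displacement-difference springs
(factor 50 over the background) along the fewest-hop contact chain between
a chosen source and sink.  Isotropy is essential, found the hard way: a
stiff *bond-directional* spring constrains only the along-bond relative
motion, so the planted correlation saturates near the elastic background
and the chain is not optimal under `-log|C|` weights; an isotropic
restraint drives the coupled pair toward lock-step motion (`|C| -> 1`).
Because isotropic springs break global rotational invariance of `H`, the
rigid modes are removed by explicit translation/rotation projection rather
than by relying on six automatic zero eigenvalues.  Optimality and
uniqueness of the planted chain under the exact `Sigma`-derived weights are
verified by exhaustive path enumeration on a 20-bead toy.

A "ternary-like" condition additionally stiffens the catalytic interface
contacts (isotropic, factor 10), emulating the tighter interface of the
doubly-occupied complex: relative fluctuations across the interface drop,
so marginal contacts persist longer (higher occupancy) and correlations
along the planted channel rise (shorter optimal paths) — the qualitative
signatures the comparative pipeline is designed to expose.  Bead charges
alternate +/-0.5 e with uniform LJ parameters (eps 0.1 kcal/mol, r_min/2
2.0 Angstrom): nonzero, hand-checkable energetics with no pretence of a
physical force field.  What the generator does **not** emulate — anharmonic
basin hopping, solvent, side-chain chemistry, real Ras/SOS geometry — bounds
what green tests mean: they certify the estimators and algorithms against
known structure, not force-field realism on real trajectories.

# Numerical choices and problem sizes

Degenerate inputs fail loudly: collinear superposition masks, single-frame
RMSF/DCCM requests, zero-variance residues, disconnected elastic networks
(components listed), steric overlap in generated geometry, atom-count
mismatches between PDB models (offending model named), unparsable records
(line numbers named).  Ties in k-means are handled by the seeded restarts;
ties in edge betweenness by the lowest-index rule; eigenvalue near-zero
tests use a relative `1e-9` threshold.  The test and validation sizes —
a 20-bead toy at 5000 frames for covariance/DCCM/PCA recovery, a 64-bead
complex at 2000 frames for community and pathway recovery, 400-frame runs
for pipeline determinism — were chosen as the smallest problems at which
the sampling tolerances (10% relative Frobenius error, 0.05 absolute DCCM
error, 10% leading-eigenvalue error) have comfortable statistical margins.

Replicate handling is deliberately simple: an `ensemble` is one frame set,
and whether replicate trajectories are pooled (concatenated before analysis,
the default recommendation — occupancies, covariances and DCCMs then refer
to the pooled distribution) or analysed separately is decided by what the
caller feeds in; nothing in the statistics assumes temporal ordering, so
concatenation is safe for every estimator in the package.

All randomness is seeded and restorable: generator specs carry a seed,
k-means consumes a named seed, the pipeline fans one global seed out to
stage seeds by a fixed affine rule, and rerunning a configuration produces
byte-identical outputs (tested, not promised).
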