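# allosnet

Conformational, energetic and network analysis of protein-complex ensembles
in R, built for studies of **long-range allosteric regulation** — the
archetype being SOS-mediated Ras activation, where a GTP-loaded GTPase at a
distal site of the exchange factor reshapes dynamics, interfacial energetics
and signalling routes at the catalytic site.  The package is aimed at
computational structural biologists who have (or simulate) frame ensembles
of a multi-segment complex and want the full comparative analysis chain as
tested, scriptable functions rather than a collection of one-off scripts.

## What it computes

Given an ensemble (multi-model PDB plus a plain-text per-atom parameter
sidecar, or a synthetic generator):

* **Conformational statistics** — Kabsch superposition; per-frame RMSD over
  arbitrary region masks; per-residue RMSF
  `RMSF_i = sqrt(<|r_i - <r_i>|^2>)`; residue-pair Cα distance
  distributions.
* **Essential dynamics** — PCA of the Cα covariance matrix, PC1–PC2
  landscapes, seeded k-means clustering with nearest-to-centroid
  representative frames.
* **Interface analysis** — geometric hydrogen-bond and salt-bridge
  detection with per-frame occupancy, restricted to cross-segment pairs.
* **Binding energetics** — single-trajectory end-state bookkeeping
  `ΔG_binding = ΔE_MM + ΔG_solv` (−TΔS recorded as omitted), with
  `ΔE_MM = ΔE_vdW + ΔE_ele + ΔE_int`, `ΔG_solv = ΔE_polar + ΔE_nonpolar`,
  `ΔE_nonpolar = γ·SASA + b` (γ = 0.00542 kcal mol⁻¹ Å⁻², b = 0.92
  kcal/mol), a generalized-Born polar term, Shrake–Rupley SASA, and exact
  per-residue decomposition.
* **Allosteric networks** — the dynamic cross-correlation matrix
  `C_ij = <Δr_i·Δr_j> / sqrt(<|Δr_i|²><|Δr_j|²>)`; a residue graph with
  edges for pairs within 4.5 Å in ≥ 75 % of frames, weighted by
  `d_ij = −log|C_ij|`; Girvan–Newman communities; Floyd–Warshall optimal
  pathways and exhaustive bounded suboptimal-path sets.
* **A synthetic-complex generator** — three-segment bead complexes whose
  frames are drawn from an exact elastic-network covariance `Σ = kT·H⁺`
  with planted community structure and a planted allosteric pathway, so
  every stage is validated against closed-form ground truth.
* **A pipeline** — `run_pipeline()` executes the whole binary-vs-ternary
  comparison from one (YAML) configuration, writing CSV/GraphML/DOT/PDB
  outputs that are byte-identical across reruns at a fixed seed.

## Worked example

Generate a "ternary-like" synthetic complex (planted allosteric pathway
from residue 57 in the allosteric segment to residue 8 in the catalytic
segment, stiffened catalytic interface) and run the core analyses:

```r
library(allosnet)
spec <- synthetic_spec(n_frames = 1000, seed = 42,
                       plant_path = list(source = 57, sink = 8),
                       stiffen_segments = c("RASC", "SOS"))
sys <- synthetic_system(spec)

dccm <- compute_dccm(sys$ensemble, superpose = FALSE)
g <- build_graph(sys$ensemble, dccm)     # 4.5 A / 75 % occupancy edges
g
#> allostery graph: 64 nodes, 228 edges

detect_communities(g)
#> communities: 6 (sizes 16, 16, 8, 8, 8, 8), modularity 0.632

optimal_path(g, 57, 8)
#> pathway 57 -> 8: length 3.352, 9 residues
sys$truth$path
#> [1] 57 50 53 33 26 29  9  2  8
```

The recovered optimal pathway is exactly the planted chain, and its length
(3.35, in −log|C| units) is short because correlations along the planted
channel approach 1.  Without the planted couplings the same source/sink
pair connects only through background elastic correlations and the optimal
length roughly quadruples — the comparative signature of an allosteric
channel.  (The 8 planted blobs merge into 6 communities here because the
stiff pathway fuses the blocks it crosses; the uncoupled complex recovers
all 8.)

Binding energetics between the central and catalytic segments:

```r
binding_energy(sys$ensemble, "SOS", "RASC", frames = seq(1, 1000, by = 250))
#> binding energy SOS vs RASC over 4 frame(s)  [-TdS omitted; polar: generalized-Born (pairwise descreening radii)]
#>    component   mean    sd
#>       dE_vdW -0.984 0.202
#>       dE_ele 17.865 0.263
#>       dE_int  0.000 0.000
#>        dE_MM 16.881 0.435
#>     dE_polar -1.408 0.141
#>  dE_nonpolar -2.716 0.008
#>      dG_solv -4.124 0.142
#>   dG_binding 12.757 0.523
```

The rows obey the bookkeeping identities exactly (`dE_MM = dE_vdW + dE_ele
+ dE_int`, `dG_binding = dE_MM + dG_solv`); the signs reflect the toy
alternating-charge beads, not a physical force field.  The same auditor
runs on the bundled published component table:

```r
vp <- verify_paper_tables()
subset(vp$consistency, system == "ternary")
#>    system   quantity recomputed printed consistent sign_flag
#> 4 ternary      dE_MM    -266.31 -266.31       TRUE     FALSE
#> 5 ternary    dG_solv     110.09  110.09       TRUE     FALSE
#> 6 ternary dG_binding    -156.22 -156.22       TRUE     FALSE
vp$binding_difference
#> [1] 9.68
```

i.e. the ternary column is internally consistent, the binary-to-ternary
binding-strength difference of 9.68 kcal/mol is reproduced from the printed
means, and (not shown) the binary column's polar term is flagged as
sign-inconsistent with its printed totals.

## Command line

A thin wrapper lives at `inst/cli/allosnet.R`:

```sh
Rscript inst/cli/allosnet.R run-all --config config.yaml --out outdir
Rscript inst/cli/allosnet.R generate --config spec.yaml --out ensemble.pdb
Rscript inst/cli/allosnet.R verify-paper
```

See the methods vignette (`vignettes/allosnet-methods.Rmd`) for the models,
parameter conventions, generator design and known limitations.
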