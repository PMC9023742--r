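# Shared synthetic fixtures, memoized so expensive ensembles are generated
# once per test run.  Seeds are fixed: the fixtures ARE the study conditions.

.fixture_env <- new.env()

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# 20-bead three-segment toy (small blobs, sparse enough for exhaustive path
# enumeration) with a planted pathway: the closed-form recovery benchmark
# (covariance, DCCM, PCA, planted-path optimality)
toy20_system <- function() {
  memo("toy20", synthetic_system(synthetic_spec(
    residues_per_segment = c(6L, 8L, 6L),
    residues_per_community = 4L,
    n_frames = 5000L, seed = 101L,
    plant_path = list(source = 15, sink = 3))))
}

# 64-bead complex with the planted 8-community structure, no couplings
complex64_system <- function() {
  memo("complex64", synthetic_system(synthetic_spec(n_frames = 2000L, seed = 202L)))
}

# "ternary"-like 64-bead complex: planted allosteric pathway from the
# allosteric segment to the catalytic segment plus stiffened interface
ternary64_system <- function() {
  memo("ternary64", synthetic_system(synthetic_spec(
    n_frames = 2000L, seed = 303L,
    plant_path = list(source = 57, sink = 8),
    stiffen_segments = c("RASC", "SOS"))))
}
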