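test_that("the Coulomb constant and LJ minimum come out exactly", {
  top <- toy_topology(2, charge = c(1, 1), eps = c(0.2, 0.2),
                      rmin_half = c(1.5, 1.5))
  coords <- rbind(c(0, 0, 0), c(1, 0, 0))
  mm <- pair_energy_mm(coords, 1, 2, top, eps_in = 1)
  expect_equal(mm$E_ele, 332.0637)

  coords_min <- rbind(c(0, 0, 0), c(3, 0, 0))   # r = r_min = 1.5 + 1.5 ... = 3
  mm2 <- pair_energy_mm(coords_min, 1, 2, top, eps_in = 1)
  expect_equal(mm2$E_vdW, -0.2, tolerance = 1e-12)

  # electrostatics scale as 1/eps_in
  mm4 <- pair_energy_mm(coords, 1, 2, top, eps_in = 4)
  expect_equal(mm4$E_ele * 4, mm$E_ele)

  expect_error(pair_energy_mm(rbind(c(0, 0, 0), c(1e-5, 0, 0)), 1, 2, top),
               "overlap")
})

test_that("group MM energies equal a brute-force double loop", {
  set.seed(16)
  top <- toy_topology(10, charge = runif(10, -1, 1), eps = runif(10, 0.05, 0.3),
                      rmin_half = runif(10, 1, 2.5))
  coords <- matrix(runif(30, 0, 10), ncol = 3)
  mm <- pair_energy_mm(coords, 1:5, 6:10, top, eps_in = 2)
  bf <- brute_force_mm(coords, 1:5, 6:10, top, eps_in = 2)
  expect_equal(mm$E_vdW, bf$E_vdW, tolerance = 1e-12)
  expect_equal(mm$E_ele, bf$E_ele, tolerance = 1e-12)
})

test_that("the one-atom generalized-Born limit is the Born ion formula", {
  q <- 1.3; R <- 2.0
  top <- toy_topology(1, charge = q, rmin_half = R)
  coords <- matrix(c(0, 0, 0), ncol = 3)
  pol <- polar_solvation(coords, 1, top, eps_in = 1, eps_out = 80)
  born <- -332.0637 / 2 * (1 - 1 / 80) * q^2 / R
  expect_equal(pol$E_polar, born, tolerance = 1e-12)

  # matched dielectrics switch solvation off entirely
  pol0 <- polar_solvation(coords, 1, top, eps_in = 80, eps_out = 80)
  expect_equal(pol0$E_polar, 0)
})

test_that("the two-atom generalized-Born energy matches the closed form", {
  top <- toy_topology(2, charge = c(0.8, -0.5), rmin_half = c(1.6, 2.1))
  r <- 3.7
  coords <- rbind(c(0, 0, 0), c(r, 0, 0))
  pol <- polar_solvation(coords, 1:2, top, eps_in = 4, eps_out = 80)
  want <- gb_two_atom_oracle(0.8, -0.5, 1.6, 2.1, r, 4, 80)
  expect_equal(pol$E_polar, want, tolerance = 1e-6)
  expect_equal(sum(pol$per_atom), pol$E_polar, tolerance = 1e-10)
})

test_that("SASA reproduces the closed-form sphere area and burial rules", {
  rho <- 1.9; probe <- 1.4
  top <- toy_topology(1, rmin_half = rho)
  s <- sasa_nonpolar(matrix(0, 1, 3), 1, top, probe_radius = probe)
  expect_equal(s$sasa, 4 * pi * (rho + probe)^2, tolerance = 0.01)
  # linear model bookkeeping: intercept b at zero area
  expect_equal(s$E_nonpolar - 0.00542 * s$sasa, 0.92, tolerance = 1e-12)

  # a duplicate atom fully inside another adds no area
  top2 <- toy_topology(2, rmin_half = c(1.9, 0.3))
  s2 <- sasa_nonpolar(rbind(c(0, 0, 0), c(0, 0, 0.1)), 1:2, top2,
                      probe_radius = probe)
  expect_equal(s2$per_atom_sasa[2], 0)
  expect_equal(s2$per_atom_sasa[1], s$per_atom_sasa[1])
})

test_that("binding bookkeeping identities hold exactly per frame", {
  sys <- synthetic_system(synthetic_spec(residues_per_segment = c(4, 6, 4),
                                         n_frames = 6, seed = 23))
  be <- binding_energy(sys$ensemble, "SOS", "RASC")
  pf <- be$per_frame
  expect_equal(pf$dE_MM, pf$dE_vdW + pf$dE_ele + pf$dE_int, tolerance = 1e-10)
  expect_equal(pf$dG_solv, pf$dE_polar + pf$dE_nonpolar, tolerance = 1e-10)
  expect_equal(pf$dG_binding, pf$dE_MM + pf$dG_solv, tolerance = 1e-10)
  expect_true(all(pf$dE_int == 0))
  s <- be$summary
  expect_equal(s$mean[s$component == "dG_binding"],
               s$mean[s$component == "dE_MM"] + s$mean[s$component == "dG_solv"],
               tolerance = 1e-6)
  expect_identical(be$entropy_term, "omitted")
  expect_error(binding_energy(sys$ensemble, "SOS", "SOS"), "overlap")
})

test_that("interaction terms vanish for well-separated partners", {
  top <- toy_topology(4, segid = c("A", "A", "B", "B"),
                      charge = c(0.5, -0.5, 0.5, -0.5))
  xyz <- matrix(c(0, 0, 0, 3, 0, 0, 500, 0, 0, 503, 0, 0), nrow = 1)
  be <- binding_energy(ensemble(top, xyz), "A", "B")
  s <- be$summary
  expect_lt(abs(s$mean[s$component == "dE_vdW"]), 1e-8)
  expect_lt(abs(s$mean[s$component == "dE_ele"]), 0.01)
  expect_lt(abs(s$mean[s$component == "dE_polar"]), 0.01)
  # the SASA intercept survives the single difference by construction
  expect_equal(s$mean[s$component == "dE_nonpolar"], -0.92, tolerance = 1e-9)
})

test_that("a designed two-bead complex matches closed-form electrostatics", {
  r <- 4.0
  top <- toy_topology(2, segid = c("A", "B"), charge = c(1, -1),
                      eps = c(0.1, 0.1), rmin_half = c(2, 2))
  xyz <- matrix(c(0, 0, 0, r, 0, 0), nrow = 1)
  be <- binding_energy(ensemble(top, xyz), "A", "B",
                       params = energy_params(eps_in = 1))
  s <- be$summary
  expect_equal(s$mean[s$component == "dE_ele"], -332.0637 / r, tolerance = 1e-12)
  expect_equal(s$mean[s$component == "dE_vdW"], 0.1 * ((4 / r)^12 - 2 * (4 / r)^6),
               tolerance = 1e-12)
  expect_equal(s$mean[s$component == "dG_binding"],
               s$mean[s$component == "dE_MM"] + s$mean[s$component == "dG_solv"])
})

test_that("per-residue decomposition conserves the totals", {
  sys <- synthetic_system(synthetic_spec(residues_per_segment = c(4, 6, 4),
                                         n_frames = 4, seed = 29))
  fr <- 1:4
  dec <- per_residue_decomposition(sys$ensemble, "SOS", "RASC", frames = fr)
  be <- binding_energy(sys$ensemble, "SOS", "RASC", frames = fr)
  s <- be$summary
  expect_equal(sum(dec$vdw), s$mean[s$component == "dE_vdW"], tolerance = 1e-6)
  expect_equal(sum(dec$ele), s$mean[s$component == "dE_ele"], tolerance = 1e-6)
  expect_equal(sum(dec$polar), s$mean[s$component == "dE_polar"], tolerance = 1e-6)
  expect_equal(sum(dec$nonpolar), s$mean[s$component == "dE_nonpolar"],
               tolerance = 1e-6)
  expect_equal(sum(dec$total), s$mean[s$component == "dG_binding"],
               tolerance = 1e-3)
  # only residues of the two partners appear
  expect_true(all(dec$segid %in% c("SOS", "RASC")))
})

test_that("a single interacting residue pair carries the whole gas-phase term", {
  top <- toy_topology(2, segid = c("A", "B"), charge = c(1, -1))
  xyz <- matrix(c(0, 0, 0, 3.5, 0, 0), nrow = 1)
  dec <- per_residue_decomposition(ensemble(top, xyz), "A", "B")
  be <- binding_energy(ensemble(top, xyz), "A", "B")
  s <- be$summary
  expect_equal(sum(dec$vdw + dec$ele),
               s$mean[s$component == "dE_vdW"] + s$mean[s$component == "dE_ele"],
               tolerance = 1e-10)
  expect_equal(dec$vdw[1] + dec$ele[1], dec$vdw[2] + dec$ele[2],
               tolerance = 1e-10)    # split half and half
})

test_that("the published component table is audited faithfully", {
  tab <- reference_energy_table()
  rep <- verify_table2_consistency(tab)
  tern <- rep[rep$system == "ternary", ]
  expect_true(all(tern$consistent))
  expect_equal(tern$recomputed[tern$quantity == "dE_MM"], -266.31)
  expect_equal(tern$recomputed[tern$quantity == "dG_solv"], 110.09)
  expect_equal(tern$recomputed[tern$quantity == "dG_binding"], -156.22)

  bin <- rep[rep$system == "binary", ]
  expect_equal(bin$recomputed[bin$quantity == "dE_MM"], -292.81)
  expect_lte(abs(bin$recomputed[bin$quantity == "dE_MM"] -
                   bin$printed[bin$quantity == "dE_MM"]), 0.02)
  expect_true(all(bin$sign_flag))    # polar sign inconsistency flagged

  expect_error(verify_table2_consistency(tab[tab$component != "dE_ele", ]),
               "missing component")

  vp <- verify_paper_tables()
  expect_true(vp$binding_difference_consistent)
  expect_equal(vp$binding_difference, 9.68, tolerance = 1e-9)
  expect_true(vp$binary_sign_flag)
})
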