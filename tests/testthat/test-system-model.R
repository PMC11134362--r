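test_that("chain topologies count beads and bonds correctly", {
  topo <- build_topology("polyanion", 48)
  expect_equal(nrow(topo$beads), 96)
  expect_equal(nrow(topo$bonds), 95)  # 47 backbone + 48 side-chain
  # every side chain bonded to exactly one backbone bead, backbone linear
  side <- which(topo$beads$role == "sidechain")
  side_bonds <- apply(topo$bonds, 1, function(b) sum(b %in% side))
  expect_equal(sum(side_bonds == 1), 48)
  expect_equal(sum(side_bonds == 0), 47)
})

test_that("oligocation side chains titrate and the protected termini carry no charge", {
  topo <- build_topology("oligocation", 8)
  expect_equal(nrow(topo$beads), 16)
  expect_true(all(topo$beads$titratable[topo$beads$role == "sidechain"]))
  expect_false(any(topo$beads$titratable[topo$beads$role == "backbone"]))
  expect_true(all(topo$beads$valence_when_ionized[
    topo$beads$role == "backbone"] == 0))
  expect_equal(topo$beads$pKa[topo$beads$role == "sidechain"][1], 10.68)
})

test_that("degenerate topologies are rejected", {
  expect_error(build_topology("polyanion", 0), "positive integer")
  expect_error(build_topology("oligocation", -3), "positive integer")
  expect_error(bead_spec("X", 1, is_titratable = TRUE, pKa = NA), "pKa")
})

test_that("composition arithmetic fixes the oligocation count exactly", {
  expect_equal(system_composition(48, 8, pH = 10)$n_oligocation_chains, 3)
  expect_equal(system_composition(48, 2, pH = 10)$n_oligocation_chains, 12)
  expect_equal(system_composition(48, 4, pH = 10)$n_oligocation_chains, 6)
  err <- tryCatch(system_composition(48, 5, pH = 10), error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "allowed n")
  expect_match(conditionMessage(err), "8")  # names a valid length
})

test_that("box length follows from the polyanion monomer concentration", {
  comp <- system_composition(48, 8, pH = 10)
  expect_equal(comp$box_length,
               (48 / (5e-3 * 0.602214076))^(1 / 3), tolerance = 1e-12)
  half <- system_composition(48, 8, pH = 10,
                             polyanion_monomer_concentration = 2.5e-3)
  expect_equal(half$box_length / comp$box_length, 2^(1 / 3),
               tolerance = 1e-12)
})

test_that("built systems are electroneutral with non-overlapping beads", {
  ff <- force_field()
  for (n in c(2, 8)) {
    comp <- system_composition(48, n, pH = 10, seed = 100 + n)
    st <- build_system(comp, ff)
    expect_equal(total_charge(st), 0)
    expect_equal(nrow(st$positions),
                 96 + 2 * n * comp$n_oligocation_chains)
    # finite energy and no pair closer than 0.8 sigma
    expect_true(is.finite(total_energy(st, ff)))
    P <- st$positions
    L <- st$box_length
    dmin <- Inf
    for (i in seq_len(nrow(P) - 1)) {
      d <- sweep(P[(i + 1):nrow(P), , drop = FALSE], 2, P[i, ])
      d <- d - L * round(d / L)
      dmin <- min(dmin, sqrt(min(rowSums(d * d))))
    }
    expect_gt(dmin, 0.8 * ff$sigma)
    # PMAA side chains permanently ionized
    pa_side <- st$topology$chain_kind == "polyanion" &
      st$topology$role == "sidechain"
    expect_true(all(st$charges[pa_side] == -1))
  }
})

test_that("oligocation ionization is initialized near the ideal level", {
  ff <- force_field()
  comp <- system_composition(48, 8, pH = 10.68, seed = 7)
  st <- build_system(comp, ff)
  tit <- which(st$topology$titratable)
  a0 <- mean(st$charges[tit] != 0)
  expect_gt(a0, 0.2)  # Bernoulli(0.5) over 24 sites
  expect_lt(a0, 0.8)
})

test_that("explicit-ion builds carry real salt and counterion particles", {
  ff <- force_field(electrostatics_mode = "coulomb_explicit_ions")
  comp <- system_composition(8, 2, pH = 10, monomer_ratio = c(1, 1),
                             seed = 3)
  st <- build_system(comp, ff)
  expect_equal(total_charge(st), 0)
  expect_equal(st$implicit_cations, 0)
  ions <- st$topology$chain_kind == "ion"
  expect_gt(sum(ions), 0)
  expect_equal(sum(st$charges[ions]), -sum(st$charges[!ions]))
})

test_that("a box smaller than the polyanion contour is refused", {
  comp <- system_composition(48, 8, pH = 10,
                             polyanion_monomer_concentration = 0.05,
                             seed = 1)
  expect_error(build_system(comp, force_field()), "contour")
})
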