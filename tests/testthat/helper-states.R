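# Small hand-built states and trajectories used across the test files.

# A bare cg_state from explicit arrays (no chains, arbitrary charges).
toy_state <- function(positions, charges = rep(0, nrow(positions)),
                      bonds = matrix(integer(0), 0, 2), L = 10,
                      titratable = rep(FALSE, nrow(positions)),
                      implicit_cations = 0, implicit_anions = 0,
                      chain_kind = rep("oligocation", nrow(positions))) {
  n <- nrow(positions)
  topo <- data.frame(
    label = ifelse(titratable, "OLS", "OLB"),
    role = "sidechain",
    valence_when_ionized = ifelse(titratable, 1L, as.integer(charges)),
    titratable = titratable, pKa = ifelse(titratable, 10.68, NA_real_),
    sigma = 0.35, molecule = seq_len(n), chain_kind = chain_kind,
    stringsAsFactors = FALSE)
  structure(list(positions = positions,
                 velocities = matrix(0, n, 3),
                 charges = charges, topology = topo,
                 bonds = bonds, box_length = L,
                 implicit_cations = implicit_cations,
                 implicit_anions = implicit_anions,
                 n_polymer_beads = n, composition = NULL),
            class = "cg_state")
}

# N titratable, otherwise free sites at fixed positions (for oracle
# comparisons with exact_titration; run with ld_steps_per_cycle = 0).
toy_titration_state <- function(positions, L = 10, ionized = NULL) {
  n <- nrow(positions)
  if (is.null(ionized)) ionized <- rep(1L, n)
  st <- toy_state(positions, charges = as.numeric(ionized), L = L,
                  titratable = rep(TRUE, n))
  # neutralize: charges + cations - anions = 0
  st$implicit_cations <- 100
  st$implicit_anions <- 100 + sum(ionized)
  st
}

# Oligocation-only system (no polyanion): one chain in a cubic box.
oligo_only_state <- function(n, pH, ff, L = 20, seed = 1) {
  set.seed(seed)
  topo <- build_topology("oligocation", n)
  pos <- regucharge:::place_chain(topo, NULL, L, ff$bond_r0, 0.9 * ff$sigma,
                                 start = rep(L / 2, 3))
  beads <- topo$beads
  beads$molecule <- 1L
  beads$chain_kind <- "oligocation"
  tit <- which(beads$titratable)
  a0 <- alpha_mean_field(pH, 10.68)
  charges <- numeric(nrow(beads))
  charges[tit] <- rbinom(length(tit), 1L, a0)
  st <- structure(list(positions = pos,
                       velocities = matrix(rnorm(3 * nrow(pos)), ncol = 3),
                       charges = charges, topology = beads,
                       bonds = topo$bonds, box_length = L,
                       implicit_cations = 100,
                       implicit_anions = 100 + sum(charges),
                       n_polymer_beads = nrow(beads), composition = NULL),
                  class = "cg_state")
  st
}

# Trajectory with a one-bead "polyanion" and point oligocations at given
# distances (used for distance/observable unit tests).
point_trajectory <- function(oligo_pos, rod_pos = matrix(c(1, 0, 0), 1),
                             oligo_q = rep(1, nrow(oligo_pos)), L = 10,
                             n_frames = 1) {
  n_oc <- nrow(oligo_pos)
  topo <- data.frame(
    label = c(rep("PAS", nrow(rod_pos)), rep("OLS", n_oc)),
    role = c(rep("backbone", nrow(rod_pos)), rep("sidechain", n_oc)),
    valence_when_ionized = c(rep(-1L, nrow(rod_pos)), rep(1L, n_oc)),
    titratable = c(rep(FALSE, nrow(rod_pos)), rep(TRUE, n_oc)),
    pKa = NA_real_, sigma = 0.35,
    molecule = c(rep(1L, nrow(rod_pos)), 1L + seq_len(n_oc)),
    chain_kind = c(rep("polyanion", nrow(rod_pos)),
                   rep("oligocation", n_oc)),
    stringsAsFactors = FALSE)
  fr <- list(pos = rbind(rod_pos, oligo_pos),
             q = c(rep(-1, nrow(rod_pos)), oligo_q))
  new_trajectory(topo, rep(list(fr), n_frames),
                 data.frame(cycle = seq_len(n_frames)), L, nrow(topo),
                 metadata = list(pH = 10, pKa = 10.68))
}

# DH pair energy exactly as the engine computes it (truncated and shifted).
dh_pair_energy_shifted <- function(r, lB, kappa, rc) {
  ifelse(r < rc, lB * exp(-kappa * r) / r - lB * exp(-kappa * rc) / rc, 0)
}
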