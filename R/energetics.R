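#' WCA (cut-and-shifted Lennard-Jones) pair energy
#'
#' Purely repulsive excluded-volume interaction: the Lennard-Jones potential
#' shifted up by `epsilon` and truncated at its minimum \eqn{2^{1/6}\sigma},
#' so the energy is continuous (zero) at the cutoff.
#'
#' @param r pair distance, nm (vectorized).
#' @param epsilon well depth, kBT.
#' @param sigma bead diameter, nm.
#' @return energy in kBT.
#' @export
#' @examples
#' wca_energy(2^(1/6) * 0.35, 1, 0.35)  # 0 at the cutoff
#' wca_energy(0.35, 1, 0.35)            # epsilon at r = sigma
wca_energy <- function(r, epsilon = 1, sigma = 0.35) {
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  rc <- 2^(1 / 6) * sigma
  sr6 <- (sigma / r)^6
  u <- 4 * epsilon * (sr6^2 - sr6) + epsilon
  ifelse(r < rc, u, 0)
}

#' Harmonic bond energy
#'
#' @param r bond length, nm (vectorized).
#' @param k spring constant, kBT/nm^2.
#' @param r0 rest length, nm.
#' @return energy `(k/2) (r - r0)^2` in kBT.
#' @export
#' @examples
#' bond_energy(0, k = 400, r0 = 0.4)  # 32
bond_energy <- function(r, k = 400, r0 = 0.4) {
  if (any(r < 0)) stop("r must be non-negative", call. = FALSE)
  0.5 * k * (r - r0)^2
}

#' Electrostatic pair energy
#'
#' Screened (Debye-Hueckel) or bare Coulomb interaction between two point
#' charges, in kBT: \eqn{z_1 z_2 \lambda_B e^{-\kappa r} / r}.  Two unit
#' charges one Bjerrum length apart in salt-free solution interact with
#' exactly 1 kBT.  This is the untruncated pair law; the simulation engine
#' additionally truncates and shifts it at the run-time cutoff.
#'
#' @param r pair distance, nm (vectorized).
#' @param z1,z2 valences.
#' @param ff a [force_field()]; its `bjerrum_length`, `kappa` and
#'   `electrostatics_mode` are used (`kappa` ignored in Coulomb mode).
#' @return energy in kBT.
#' @export
#' @examples
#' ff0 <- force_field(ionic_strength = 0, kappa = 0)
#' electrostatic_pair_energy(0.71, 1, 1, ff0)  # 1 kBT
electrostatic_pair_energy <- function(r, z1, z2, ff = force_field()) {
  if (any(r <= 0)) stop("r must be positive", call. = FALSE)
  stopifnot(inherits(ff, "force_field"))
  kap <- if (ff$electrostatics_mode == "coulomb_explicit_ions") 0 else
    ff$kappa
  z1 * z2 * ff$bjerrum_length * exp(-kap * r) / r
}

#' Total potential energy of a system state
#'
#' Sum of bonded, WCA and electrostatic terms over all minimum-image pairs,
#' with the electrostatic pair potential truncated and shifted at the
#' resolved cutoff.  Overlapping beads give `Inf`.
#'
#' @param state a `"cg_state"` from [build_system()].
#' @param ff a [force_field()].
#' @return energy in kBT.
#' @export
total_energy <- function(state, ff) {
  stopifnot(inherits(state, "cg_state"))
  cpp_total_energy(state$positions, state$charges,
                   bonds_for_cpp(state$bonds), state$box_length,
                   resolve_ff(ff, state$box_length))
}

#' Forces on all beads
#'
#' Analytic negative gradient of [total_energy()]; consistent with central
#' finite differences of the energy to high accuracy.
#'
#' @inheritParams total_energy
#' @return N x 3 matrix of forces, kBT/nm.
#' @export
forces <- function(state, ff) {
  stopifnot(inherits(state, "cg_state"))
  cpp_forces(state$positions, state$charges,
             bonds_for_cpp(state$bonds), state$box_length,
             resolve_ff(ff, state$box_length))
}
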