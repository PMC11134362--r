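#' Inverse Debye screening length from ionic strength
#'
#' For a monovalent (1:1) salt at ionic strength `I`,
#' \eqn{\kappa^2 = 8 \pi \lambda_B N_A I}, with \eqn{\lambda_B} the Bjerrum
#' length.  At `I = 0.01` mol/L in water (\eqn{\lambda_B = 0.71} nm) the
#' screening length \eqn{1/\kappa} is about 3 nm.
#'
#' @param ionic_strength ionic strength in mol/L.
#' @param bjerrum_length Bjerrum length in nm (default 0.71, water at 298 K).
#' @return \eqn{\kappa} in 1/nm.
#' @export
#' @examples
#' kappa_from_ionic_strength(0.01)
kappa_from_ionic_strength <- function(ionic_strength, bjerrum_length = 0.71) {
  stopifnot(ionic_strength >= 0, bjerrum_length > 0)
  sqrt(8 * pi * bjerrum_length * .NA_PER_NM3 * ionic_strength)
}

#' Force-field parameters in reduced units
#'
#' Bundles the excluded-volume (WCA), bonded (harmonic) and electrostatic
#' parameters of the bead-spring model.  Two electrostatics treatments are
#' available:
#' \describe{
#'   \item{`debye_hueckel_implicit_ions`}{screened Coulomb pair potential
#'     \eqn{z_1 z_2 \lambda_B e^{-\kappa r}/r}; small ions enter only through
#'     \eqn{\kappa} and through implicit counterion bookkeeping.  This is the
#'     default, desk-scale mode.}
#'   \item{`coulomb_explicit_ions`}{bare Coulomb \eqn{z_1 z_2 \lambda_B / r}
#'     under the minimum image, truncated and shifted at `rcut_elec`;
#'     small ions are explicit particles.  Intended for small-system
#'     cross-checks of the implicit-ion mode.}
#' }
#' The engine truncates and shifts the electrostatic pair potential at
#' `rcut_elec` so the energy is continuous; when `rcut_elec` is `NULL` it is
#' resolved at run time to `min(4/kappa, L/2)` (DH) or `L/2` (Coulomb).
#'
#' @param wca_epsilon WCA well depth, kBT.
#' @param sigma bead diameter, nm.
#' @param bond_k harmonic bond constant, kBT/nm^2.
#' @param bond_r0 bond rest length, nm.
#' @param bjerrum_length Bjerrum length, nm.
#' @param electrostatics_mode `"debye_hueckel_implicit_ions"` or
#'   `"coulomb_explicit_ions"`.
#' @param ionic_strength mol/L; used to derive `kappa` in DH mode and the
#'   number of explicit salt ions in Coulomb mode.
#' @param kappa inverse screening length, 1/nm; derived from `ionic_strength`
#'   when `NULL` (Coulomb mode uses `kappa = 0`).
#' @param rcut_elec electrostatic cutoff, nm, or `NULL` to resolve from the
#'   box at run time.
#' @return An object of class `"force_field"`.
#' @export
#' @examples
#' ff <- force_field()
#' ff$kappa
force_field <- function(wca_epsilon = 1,
                        sigma = 0.35,
                        bond_k = 400,
                        bond_r0 = 0.4,
                        bjerrum_length = 0.71,
                        electrostatics_mode = c("debye_hueckel_implicit_ions",
                                                "coulomb_explicit_ions"),
                        ionic_strength = 0.01,
                        kappa = NULL,
                        rcut_elec = NULL) {
  electrostatics_mode <- match.arg(electrostatics_mode)
  stopifnot(wca_epsilon >= 0, sigma > 0, bond_k >= 0, bond_r0 >= 0,
            bjerrum_length >= 0, ionic_strength >= 0)
  if (is.null(kappa)) {
    kappa <- if (electrostatics_mode == "debye_hueckel_implicit_ions" &&
                 bjerrum_length > 0) {
      kappa_from_ionic_strength(ionic_strength, bjerrum_length)
    } else 0
  }
  stopifnot(kappa >= 0)
  structure(
    list(wca_epsilon = wca_epsilon, sigma = sigma,
         bond_k = bond_k, bond_r0 = bond_r0,
         bjerrum_length = bjerrum_length,
         electrostatics_mode = electrostatics_mode,
         ionic_strength = ionic_strength,
         kappa = kappa, rcut_elec = rcut_elec),
    class = "force_field")
}

#' @export
print.force_field <- function(x, ...) {
  cat("Coarse-grained force field (reduced units: kBT, nm)\n")
  cat(sprintf("  WCA: epsilon = %g, sigma = %g nm\n", x$wca_epsilon, x$sigma))
  cat(sprintf("  bonds: harmonic, k = %g kBT/nm^2, r0 = %g nm\n",
              x$bond_k, x$bond_r0))
  cat(sprintf("  electrostatics: %s, lambda_B = %g nm, kappa = %.4g 1/nm\n",
              x$electrostatics_mode, x$bjerrum_length, x$kappa))
  cat(sprintf("  ionic strength: %g mol/L; cutoff: %s\n", x$ionic_strength,
              if (is.null(x$rcut_elec)) "auto" else
                sprintf("%g nm", x$rcut_elec)))
  invisible(x)
}

# Fill run-time-dependent fields (cutoff) given a box length; returns the
# plain list handed to the C++ kernels.
resolve_ff <- function(ff, box_length) {
  stopifnot(inherits(ff, "force_field"), box_length > 0)
  rc <- ff$rcut_elec
  if (is.null(rc)) {
    rc <- if (ff$kappa > 0) min(4 / ff$kappa, box_length / 2) else
      box_length / 2
  }
  out <- unclass(ff)
  out$rcut_elec <- rc
  out
}
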