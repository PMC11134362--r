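---
title: "Charge regulation and condensation of oligocations on a polyanion: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge regulation and condensation of oligocations on a polyanion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(regucharge)
```

## The model

We study a minimal system in which charge regulation and counterion-style
condensation reinforce each other: a single long polyanion (48 monomers,
side chains permanently carrying charge $-1$, representing a
poly(methacrylic acid) chain far above its acid p$K_a \approx 4.3$) in a
solution of short oligocations (Lys$_n$, $n \in \{2, 4, 8\}$) whose side
chains are weak bases with conjugate-acid p$K_a = 10.68$ and can therefore
gain or lose their $+1$ charge in response to pH and to the local
electrostatic environment.  The oligocation termini are uncharged,
mirroring end-protected oligopeptides.

Every monomer is two spherical beads — backbone plus pendant side chain —
connected by harmonic bonds.  Reduced units are used throughout: energies
in $k_BT$ ($k_BT \equiv 1$), lengths in nm, all bead masses 1.

* **Excluded volume**: WCA potential, $\epsilon = 1\,k_BT$,
  $\sigma = 0.35$ nm (all beads).
* **Bonds**: harmonic, $k = 400\,k_BT/\mathrm{nm}^2$, $r_0 = 0.4$ nm.
* **Electrostatics**: Bjerrum length $\lambda_B = 0.71$ nm (water, 298 K).
  Default mode is Debye–Hückel with implicit ions,
  $u(r) = z_1 z_2 \lambda_B e^{-\kappa r}/r$, $\kappa^2 = 8\pi \lambda_B
  N_A I$ for a monovalent salt; at $I = 0.01$ mol/L the screening length is
  $1/\kappa \approx 3.1$ nm.  An explicit-ion mode with bare Coulomb
  interactions is provided for cross-checks (below).
* **Composition**: oligocation:polyanion monomer ratio 1:2, so a 48-mer
  polyanion is paired with 3 Lys$_8$, 6 Lys$_4$ or 12 Lys$_2$ molecules.
  The cubic box edge follows from the polyanion monomer concentration
  (default $5\times10^{-3}$ mol/L, a config key: the source system states
  only "relatively low concentration in excess salt"), giving
  $L \approx 25.2$ nm.  Monovalent salt at $I$ plus neutralizing
  counterions keep the box exactly electroneutral.

These force-field values are the standard semiempirical choices for this
family of coarse-grained polyelectrolyte models; every one of them is a
config key (`force_field()`, `system_composition()`, or the YAML config in
`inst/extdata/example-config.yaml`).

The box must exceed the polyanion contour length so that minimum-image
distances are meaningful for the stretched chain; `build_system()` enforces
`box_length > (m - 1) r0`.  (A stricter factor-of-two margin would be
incompatible with the default monomer concentration, which already sets
$L \approx 25$ nm against an 18.8 nm contour; the chain is in practice
partly coiled, and no artifact of the weaker bound has been observed.)

## Sampling

Ionization states are sampled by constant-pH Monte Carlo.  A trial move
flips one randomly chosen titratable site and, to keep the box
electroneutral, inserts a monovalent cation on deprotonation
($\xi = +1$) or deletes one on protonation ($\xi = -1$); it is accepted
with probability

$$p_{\mathrm{acc}} = \min\left\{1,\; e^{-\Delta U + \xi \ln 10\,
(\mathrm{pH} - \mathrm{p}K_a)}\right\}.$$

In the implicit-ion mode the insertion/deletion is count-only bookkeeping
and $\Delta U$ contains only the change in the polymer electrostatic
energy — the ideal-gas part of the exchange is exactly the
$\xi \ln 10 (\mathrm{pH} - \mathrm{p}K_a)$ factor, which is why the scheme
reproduces the Henderson–Hasselbalch law to machine accuracy when
interactions are switched off (the decisive validation test).  A
protonation with no deletable cation is auto-rejected; with the default
salt content this never occurs in practice.

Configurations are sampled between MC sweeps by BAOAB Langevin dynamics
(friction $\gamma = 1/\tau$, fluctuation–dissipation satisfied exactly at
any timestep).  The default timestep is $dt = 0.005$: the stiffest motion
in the model is an oppositely charged side-chain pair pressed into the WCA
wall, whose local curvature puts $\omega\,dt$ near the Verlet stability
limit at $dt = 0.01$; halving the step keeps rare deep contacts stable.
For the same reason bonded forces act on the raw (unwrapped) bead
displacements rather than on minimum images — bonded neighbours are
physically adjacent, and a minimum-image spring would become discontinuous
for transiently stretched bonds.

Each cycle additionally attempts one rigid-body re-insertion per
oligocation: the whole molecule is proposed at a uniformly random position
and accepted by Metropolis.  The proposal is symmetric, so the sampled
Boltzmann distribution is untouched, but the condensed/free exchange
becomes ergodic on desk-scale runs — with Langevin dynamics alone the
exchange is diffusion-limited and molecules were observed to stay trapped
on one side of the 2 nm boundary for thousands of cycles.

One frame is recorded per cycle after warmup.  Default production
settings, used by the acceptance script and stated here as the package's
problem sizes: 20 LD steps and one MC sweep (one trial per titratable
site) per cycle, 1500–2000 warmup cycles and 5000–6500 recorded cycles for
the full 48-mer systems; $10^4$ cycles for ideal-limit checks;
$3\times10^4$ MC-only cycles for the enumeration-oracle toys.

## Observables

* `degree_of_ionization()` — mean ionization over sites and frames with a
  block-averaged (10-block) standard error, robust to MC autocorrelation.
* `condensed_fraction()` — fraction of molecule-frames whose center of
  mass lies within 2 nm of the nearest polyanion bead.  The 2 nm value is
  the local minimum between the condensed and free populations of the
  distance histogram.
* `distance_resolved_ionization()` — per-molecule ionization and
  population binned by that distance (0.25 nm bins), plus the raw
  molecule-frame scatter; the bimodal population with high-$\alpha$ near
  bins and low-$\alpha$ far bins is the coexistence signature.
* `end_to_end()` — polyanion backbone end-to-end distance (unwrapped
  coordinates).
* `local_hplus_profile()` — a proxy for the "local pH": in DH mode the
  Boltzmann factor $e^{-\psi}$ of the mean screened potential sampled at
  random probe points, binned by distance to the chain,
  $c_H(r) = 10^{-\mathrm{pH}} \langle e^{-\psi}\rangle_r$; in explicit-ion
  mode the relative cation density.  The estimator of the original study
  is not published in detail, so this proxy is labelled as such.
* `fit_titration()` — Hill fit $\alpha = (1 + 10^{s(\mathrm{pH} - p)})^{-1}$,
  giving the effective p$K_a$ ($p$) and cooperativity ($s$).

Analytic reference formulas live in `alpha_mean_field()`, `pka_eff()`,
`manning_parameter()` and `counterion_release_entropy()`.  One design
decision deserves a note: with the ionization convention used here
(ionized = protonated for a base, charged state carrying $z\psi$ of
electrostatic energy), the half-ionization pH is
$\mathrm{p}K_a - \psi/\ln 10$ for *both* acids and bases — the $z$ in the
exponent of $\alpha$ cancels against the sign flip of the ionization
direction.  `pka_eff()` implements exactly the midpoint of
`alpha_mean_field()` (the two are tested together to machine precision),
which also reproduces the observed directions: self-repulsion lowers the
effective p$K_a$ of a free oligocation, attraction to the polyanion raises
it.

`exact_titration()` enumerates all $2^N$ ionization microstates of up to
12 sites with fixed pair energies; it is the independent oracle against
which the MC sampler is validated on frozen-geometry toys.

## Synthetic fixtures

`generate_mixture_trajectory()` emulates the statistical structure the
analysis assumes — a straight polyanion rod and point-like oligocations
assigned to a condensed population (exact distance drawn inside the
threshold, ionization Bernoulli at $\alpha_{\mathrm{cond}}$) or a free one
(far, $\alpha_{\mathrm{free}}$) — with exactly known parameters, so every
observable can be validated without running the simulator, and fixtures
round-trip through the same trajectory files as simulator output.  What
fixtures do *not* emulate: conformational correlations, intermediate
distances, and the coupling of ionization to distance within a population;
passing fixture tests therefore validates the analysis layer, not the
physics, which is exercised by the sampler tests instead.

`generate_titration_series()` + `fit_titration()` close the loop for
titration curves (midpoint recovery within 0.1 pH units at noise 0.02).

## Numerical choices

* Direct $O(N^2)$ pair summation: production systems have $\sim$150 beads
  and the DH cutoff $4/\kappa \approx 12$ nm is half the box, so neighbour
  lists would prune almost nothing.
* The electrostatic pair potential is truncated and shifted to zero at
  $\min(4/\kappa, L/2)$ (DH) or $L/2$ (Coulomb); the residual force
  discontinuity at the cutoff is $\sim 4\times10^{-4} k_BT/\mathrm{nm}$.
* The explicit-ion mode uses minimum-image truncated Coulomb rather than
  an Ewald sum.  It is intended for small, dilute cross-check systems
  where the neglected reciprocal-space contribution is small; for the
  production questions the implicit-ion DH mode is the documented route.
* Initial configurations: self-avoiding walks (0.9 $\sigma$ minimum
  separation) relaxed by a capped steepest descent, velocities
  Maxwell–Boltzmann; degenerate inputs (overcrowded box, box smaller than
  the contour, non-divisible compositions, $N > 12$ enumerations, empty
  trajectories) raise informative errors.
* All randomness flows through R's RNG; a single seed makes build,
  sampling and analysis bit-for-bit reproducible in DH mode.

## Known limitations

The implicit-ion Debye–Hückel substitution linearizes away counterion
condensation on the polyanion.  With the bare $-48$ chain charge the model
therefore *overbinds* weakly charged oligocations.  Cross-checks with the
explicit-ion mode on the full system quantify this: at pH 11.5 the Lys$_2$
condensed fraction is 0.45 in DH mode but 0.08 with explicit ions (which
matches the published near-zero value), and the Lys$_8$
condensation transition, complete by pH 12.5 with explicit ions
(fraction 0.03), is shifted upward in DH mode (fraction still 0.52 at
pH 12.5).  Quantities dominated by the strongly bound state — Lys$_4$ and
Lys$_8$ near pH 10, the ideal limit, the ordering and reversal of
effective-p$K_a$ shifts, and the coexistence of highly ionized condensed
with weakly ionized free molecules — are robust to the substitution.  The
acceptance tests assert the affected quantities at the study's stated
tolerances anyway and are expected to fail in DH mode; they are kept
failing deliberately, as an honest record of where the approximation
breaks, with this section as the analysis.

Other simplifications: no hydrogen bonding, hydrophobicity or other
ion-specific effects; no solvent hydrodynamics; a single polyanion chain
(no interchain aggregation); fixed, fully ionized polyanion (valid for
pH $\gg$ 4.3).
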