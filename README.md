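# regucharge

Coarse-grained constant-pH simulation of **charge regulation**: how short
weak-base oligocations (oligolysines, Lys\_n) ionize and condense on a long,
fully ionized polyanion (a poly(methacrylic acid)-like 48-mer), and how the
two effects feed back on each other.

## The science

A titratable base follows the Henderson–Hasselbalch law augmented by the
local electrostatic potential ψ (expressed as eψ/k\_BT):

    alpha = 1 / (1 + 10^( z (pH - pKa) + z psi / ln 10 )),      z = +1 (base)

so the effective pKa — the pH at which alpha = 1/2 — is shifted by
`-psi / ln 10`.  In free solution the repulsion between like charges on an
oligocation (ψ > 0) *suppresses* ionization, the more so the longer the
chain; near a polyanion (ψ < 0) ionization is *enhanced*.  The enhanced
charge in turn drives counterion-style condensation of the oligocation on
the polyanion, so condensation and ionization cooperate: the same solution
can contain almost non-ionized free molecules and highly ionized condensed
ones, and the transition between the two states sharpens with chain length.

The package implements:

* a two-beads-per-monomer bead-spring model (WCA excluded volume, harmonic
  bonds, Debye–Hückel *or* explicit-ion Coulomb electrostatics, reduced
  units: k\_BT = 1, lengths in nm, Bjerrum length 0.71 nm),
* constant-pH Monte Carlo over the protonation states (acceptance
  `min{1, exp(-dU + xi ln10 (pH - pKa))}`, ξ = +1 for deprotonation, with
  exact electroneutrality via counterion insertion/deletion) coupled to
  BAOAB Langevin dynamics, plus whole-molecule re-insertion moves for
  ergodic condensed/free exchange,
* observables: titration curves α(pH) with block-averaged errors, effective
  pKa via Hill fits, center-of-mass distance to the polyanion, condensed
  fraction (2 nm criterion), distance-resolved ionization, polyanion
  end-to-end distance, local-H⁺ ("local pH") profiles,
* analytic references (mean-field α and pKa_eff, Manning parameter,
  counterion-release entropy) and an exact 2^N enumeration oracle,
* synthetic two-population trajectory fixtures that make every analysis
  function testable without the simulator,
* a pH-sweep driver with YAML configs, extended-XYZ + CSV trajectory I/O
  and a reproducibility manifest.

## Worked example

Three Lys₈ molecules with one 48-mer polyanion (1:2 monomer ratio,
I = 0.01 M) at pH 10:

```r
library(regucharge)

comp <- system_composition(m = 48, n = 8, pH = 10, seed = 1)
ff   <- force_field()                      # DH mode, kappa from I = 0.01 M
st   <- build_system(comp, ff)
tr   <- run_cph_ld(st, ff, integrator_params(),
                   cph_params(pH = 10, seed = 2),
                   n_cycles = 6500, warmup_cycles = 1500)

degree_of_ionization(tr)$alpha   # 0.990
condensed_fraction(tr)           # condensed fraction (< 2 nm): 1.000 +/- 0.000
end_to_end(tr)$mean              # 6.92 (nm)
```

The ideal Henderson–Hasselbalch value at pH 10 would be
`alpha_mean_field(10, 10.68) = 0.827`: the polyanion pulls the oligolysines
in, charges them up to α ≈ 0.99, and every molecule stays within 2 nm of the
chain, which in turn contracts (end-to-end distance ≈ 7 nm).  Rebuilding at
`pH = 12.5` instead gives α ≈ 0.21, a condensed fraction ≈ 0.48 — condensed,
highly ionized molecules coexisting with free, weakly ionized ones — and a
re-expanded chain (end-to-end ≈ 12.7 nm).

A whole titration sweep with per-pH tables:

```r
res <- sweep_ph(example_config(n = 8), pH_list = seq(10, 12.5, 0.5),
                seeds = 1:2, out_dir = "sweep_out")
res$tables$condensation
```

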