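# Complete run configuration (all values are the package defaults).
# Reduced units: energies in kBT, lengths in nm.
composition:
  m: 48                                # polyanion length, monomers
  "n": 8                               # oligocation length, monomers (quoted: bare n is a YAML boolean)
  n_polyanion_chains: 1
  monomer_ratio: [1, 2]                # oligocation : polyanion monomers
  ionic_strength: 0.01                 # mol/L
  pKa: 10.68                           # oligocation side-chain pKa
  polyanion_monomer_concentration: 0.005  # mol/L, sets the box size
force_field:
  wca_epsilon: 1.0                     # kBT
  sigma: 0.35                          # nm
  bond_k: 400.0                        # kBT/nm^2
  bond_r0: 0.4                         # nm
  bjerrum_length: 0.71                 # nm (water, 298 K)
  electrostatics_mode: debye_hueckel_implicit_ions
  ionic_strength: 0.01                 # mol/L (sets kappa in DH mode)
integrator:
  dt: 0.005                            # reduced time
  gamma: 1.0                           # 1/time
cph:
  pKa: 10.68
  ld_steps_per_cycle: 20
run:
  n_cycles: 6500
  warmup_cycles: 1500
  threshold: 2.0                       # nm, condensation criterion
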