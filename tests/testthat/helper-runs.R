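# Standard-conditions runs shared by the acceptance-level tests: one 48-mer
# polyanion, 1:2 oligocation:polyanion monomer ratio, I = 0.01 M,
# pKa = 10.68, Debye-Hueckel electrostatics.  Run lengths are the package's
# desk-scale defaults (see the methods vignette).

study_run <- function(n, pH, seed, n_cycles = 6500, warmup_cycles = 1500) {
  comp <- system_composition(m = 48, n = n, pH = pH, seed = seed)
  ff <- force_field()
  st <- build_system(comp, ff)
  run_cph_ld(st, ff, integrator_params(),
             cph_params(pH = pH, ld_steps_per_cycle = 20,
                        seed = seed + 7919L),
             n_cycles = n_cycles, warmup_cycles = warmup_cycles)
}

# Titration of a single oligocation in solution (no polyanion): returns the
# fitted effective pKa and the degree of ionization at pH = pKa.
oligo_only_titration <- function(n, seed,
                                 grid = c(9.4, 9.8, 10.1, 10.4, 10.68,
                                          11.0, 11.4),
                                 n_cycles = 3000, warmup_cycles = 500) {
  ff <- force_field()
  alphas <- vapply(grid, function(pH) {
    st <- oligo_only_state(n, pH, ff, seed = seed)
    tr <- run_cph_ld(st, ff, integrator_params(),
                     cph_params(pH = pH, ld_steps_per_cycle = 10,
                                seed = seed + round(1000 * pH)),
                     n_cycles = n_cycles, warmup_cycles = warmup_cycles)
    degree_of_ionization(tr)$alpha
  }, numeric(1))
  fit <- fit_titration(data.frame(pH = grid, alpha = alphas))
  list(pKa_eff = fit$pKa_eff,
       alpha_at_pKa = alphas[grid == 10.68])
}
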