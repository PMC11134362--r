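test_that("acceptance probability implements the constant-pH rule", {
  expect_equal(acceptance_probability(0, +1, 10.68, 10.68), 1)
  expect_equal(acceptance_probability(0, +1, 11.68, 10.68), 1)  # min(1, 10)
  expect_equal(acceptance_probability(0, -1, 11.68, 10.68), 0.1)
  expect_equal(acceptance_probability(log(10), +1, 11.68, 10.68), 1)
  expect_equal(acceptance_probability(2, +1, 10.68, 10.68), exp(-2))
})

test_that("trial moves preserve electroneutrality through counterion bookkeeping", {
  st <- toy_titration_state(rbind(c(1, 1, 1), c(3, 3, 3)),
                            ionized = c(1L, 0L))
  expect_equal(total_charge(st), 0)
  # deprotonation of the ionized site inserts a cation
  mv <- propose_move(st, 1)
  expect_equal(mv$xi, +1)
  expect_equal(mv$trial$charges[1], 0)
  expect_equal(mv$trial$implicit_cations, st$implicit_cations + 1)
  expect_equal(total_charge(mv$trial), 0)
  # protonation of the neutral site deletes a cation
  mv2 <- propose_move(st, 2)
  expect_equal(mv2$xi, -1)
  expect_equal(mv2$trial$charges[2], 1)
  expect_equal(mv2$trial$implicit_cations, st$implicit_cations - 1)
  expect_equal(total_charge(mv2$trial), 0)
})

test_that("protonation with no deletable cation is auto-rejected", {
  st <- toy_titration_state(matrix(1, 1, 3), ionized = 0L)
  st$implicit_cations <- 0
  st$implicit_anions <- 0
  mv <- propose_move(st, 1)
  expect_true(mv$auto_rejected)
  expect_null(mv$trial)
})

test_that("electroneutrality holds after a full sampling run", {
  comp <- system_composition(48, 8, pH = 10.5, seed = 31)
  ff <- force_field()
  st <- build_system(comp, ff)
  tr <- run_cph_ld(st, ff, integrator_params(),
                   cph_params(pH = 10.5, ld_steps_per_cycle = 5, seed = 32),
                   n_cycles = 200, warmup_cycles = 0)
  # the engine asserts neutrality after every MC sweep and stops on any
  # violation; the final state must balance exactly
  expect_equal(total_charge(tr$metadata$final_state), 0)
  # recorded counterion counts mirror the recorded polymer charge
  tit <- which(st$topology$titratable)
  qfix <- sum(st$charges[-tit])
  qtit <- vapply(tr$frames, function(fr) sum(fr$q[tit]), numeric(1))
  expect_true(all(qfix + qtit + tr$scalars$cations - tr$scalars$anions == 0))
})

test_that("the ideal (non-interacting) limit reproduces Henderson-Hasselbalch", {
  ff0 <- force_field(bjerrum_length = 0, ionic_strength = 0, kappa = 0)
  comp <- system_composition(8, 8, pH = 10.68, monomer_ratio = c(1, 1),
                             seed = 33)
  st <- build_system(comp, ff0)
  run_at <- function(pH, seed) {
    tr <- run_cph_ld(st, ff0, integrator_params(),
                     cph_params(pH = pH, ld_steps_per_cycle = 5,
                                seed = seed),
                     n_cycles = 10000, warmup_cycles = 500)
    degree_of_ionization(tr)
  }
  d <- run_at(10.68, 34)
  expect_lt(abs(d$alpha - 0.5), 0.02)
  expect_lt(abs(d$alpha - 0.5), 3 * d$se)
  d1 <- run_at(11.68, 35)
  expect_lt(abs(d1$alpha - 1 / 11), 0.01)
})

test_that("stationary one-site ionization follows the HH Bernoulli law (detailed balance)", {
  st <- toy_titration_state(matrix(1, 1, 3), ionized = 1L)
  ff0 <- force_field(bjerrum_length = 0, ionic_strength = 0, kappa = 0)
  set.seed(36)
  tr <- run_cph_ld(st, ff0, integrator_params(),
                   cph_params(pH = 11.18, pKa = 10.68, moves_per_cycle = 5,
                              ld_steps_per_cycle = 0),
                   n_cycles = 4000, warmup_cycles = 200)
  ion <- tr$scalars$alpha  # single site: 0/1 series
  p_hh <- alpha_mean_field(11.18, 10.68)
  obs <- c(sum(ion == 1), sum(ion == 0))
  chi <- stats::chisq.test(obs, p = c(p_hh, 1 - p_hh))
  expect_gt(chi$p.value, 0.01)
})

test_that("with interactions off, the titration curve is independent of chain length", {
  ff0 <- force_field(bjerrum_length = 0, ionic_strength = 0, kappa = 0)
  alphas <- lapply(c(2, 8), function(n) {
    comp <- system_composition(8, n, pH = 11.18, monomer_ratio = c(1, 1),
                               seed = 40 + n)
    st <- build_system(comp, ff0)
    tr <- run_cph_ld(st, ff0, integrator_params(),
                     cph_params(pH = 11.18, ld_steps_per_cycle = 5,
                                seed = 50 + n),
                     n_cycles = 6000, warmup_cycles = 500)
    degree_of_ionization(tr)
  })
  se <- sqrt(alphas[[1]]$se^2 + alphas[[2]]$se^2)
  expect_lt(abs(alphas[[1]]$alpha - alphas[[2]]$alpha), 3 * se + 1e-6)
})

test_that("interacting toys match the exact enumeration oracle", {
  ff <- force_field()  # DH at I = 0.01
  L <- 10
  ffr <- regucharge:::resolve_ff(ff, L)
  rc <- ffr$rcut_elec
  # two sites 0.5 nm apart, and a 4-site line with 0.45 nm spacing
  configs <- list(
    rbind(c(5, 5, 5), c(5.5, 5, 5)),
    cbind(5 + 0.45 * (0:3), 5, 5))
  for (pos in configs) {
    n <- nrow(pos)
    E <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
        E[i, j] <- E[j, i] <- dh_pair_energy_shifted(
          r, ff$bjerrum_length, ff$kappa, rc)
      }
    }
    for (pH in c(10.3, 10.68, 11.1)) {
      a_exact <- exact_titration(E, pH, 10.68)
      st <- toy_titration_state(pos, L = L)
      tr <- run_cph_ld(st, ff, integrator_params(),
                       cph_params(pH = pH, moves_per_cycle = n,
                                  ld_steps_per_cycle = 0,
                                  translation_moves_per_cycle = 0,
                                  seed = round(100 * pH)),
                       n_cycles = 30000, warmup_cycles = 1000)
      d <- degree_of_ionization(tr)
      expect_lt(abs(d$alpha - a_exact), 3 * d$se + 0.005)
    }
  }
})

test_that("self-repulsion suppresses ionization more for longer oligocations", {
  # single molecules in solution, DH electrostatics, pH = pKa, 3 seeds
  ff <- force_field()
  mean_alpha <- function(n) {
    a <- vapply(1:3, function(s) {
      st <- oligo_only_state(n, 10.68, ff, seed = 60 + s)
      tr <- run_cph_ld(st, ff, integrator_params(),
                       cph_params(pH = 10.68, ld_steps_per_cycle = 10,
                                  seed = 70 + n + s),
                       n_cycles = 4000, warmup_cycles = 500)
      degree_of_ionization(tr)$alpha
    }, numeric(1))
    mean(a)
  }
  a2 <- mean_alpha(2); a4 <- mean_alpha(4); a8 <- mean_alpha(8)
  expect_gt(a2, a4)
  expect_gt(a4, a8)
  expect_lt(a2, 0.5)  # all below the ideal value at pH = pKa
})
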