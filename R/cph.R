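#' Constant-pH sampling parameters
#'
#' @param pH imposed solution pH.
#' @param pKa conjugate-acid pKa of the titratable sites (default 10.68,
#'   the lysine side-chain value used throughout).
#' @param moves_per_cycle trial ionization moves per cycle; defaults to the
#'   number of titratable sites when `NULL`.
#' @param ld_steps_per_cycle Langevin steps between MC sweeps (default 20).
#' @param translation_moves_per_cycle rigid-body re-insertion trial moves of
#'   whole oligocation molecules per cycle (uniform random placement,
#'   Metropolis-accepted; symmetric, so the sampled distribution is
#'   unchanged).  These make the condensed/free exchange ergodic on short
#'   runs; defaults to the number of oligocation molecules when `NULL`, 0
#'   disables them.
#' @param seed optional integer seed applied at the start of a run.
#' @return An object of class `"cph_params"`.
#' @export
cph_params <- function(pH, pKa = 10.68, moves_per_cycle = NULL,
                       ld_steps_per_cycle = 20,
                       translation_moves_per_cycle = NULL, seed = NULL) {
  stopifnot(is.finite(pH), is.finite(pKa),
            is.null(moves_per_cycle) || moves_per_cycle >= 1,
            is.null(translation_moves_per_cycle) ||
              translation_moves_per_cycle >= 0,
            ld_steps_per_cycle >= 0)
  structure(list(pH = pH, pKa = pKa, moves_per_cycle = moves_per_cycle,
                 ld_steps_per_cycle = ld_steps_per_cycle,
                 translation_moves_per_cycle = translation_moves_per_cycle,
                 seed = seed),
            class = "cph_params")
}

#' Acceptance probability of a constant-pH trial move
#'
#' \deqn{p_{\mathrm{acc}} = \min\{1,\
#'   \exp(-\Delta U + \xi \ln 10\,(\mathrm{pH} - \mathrm{p}K_a))\}}
#' with energies in kBT and \eqn{\xi = +1} for deprotonation of the base
#' (charged to neutral), \eqn{\xi = -1} for protonation.  In the ideal
#' limit (\eqn{\Delta U = 0}) the stationary distribution of repeated moves
#' is exactly the Henderson-Hasselbalch law.
#'
#' @param dU potential-energy change of the trial move, kBT.
#' @param xi +1 (deprotonation) or -1 (protonation).
#' @param pH,pKa titration parameters.
#' @return acceptance probability in `[0, 1]`.
#' @export
#' @examples
#' acceptance_probability(0, +1, 10.68, 10.68)  # 1
#' acceptance_probability(0, -1, 11.68, 10.68)  # 0.1
acceptance_probability <- function(dU, xi, pH, pKa) {
  stopifnot(all(is.finite(dU)), all(xi %in% c(-1, 1)))
  pmin(1, exp(-dU + xi * log(10) * (pH - pKa)))
}

#' Propose a single constant-pH move
#'
#' Flips the ionization state of one titratable site while preserving exact
#' electroneutrality: deprotonation (\eqn{\xi = +1}) inserts one monovalent
#' cation (in implicit-ion mode, increments the implicit cation count;
#' in explicit-ion mode, a cation particle placed uniformly at random),
#' protonation (\eqn{\xi = -1}) deletes/decrements one.  A protonation with
#' no deletable cation is auto-rejected (`trial = NULL`).
#'
#' @param state a `"cg_state"`.
#' @param site index into the titratable sites (1-based).
#' @return list with `trial` (the trial `"cg_state"`, or `NULL` if
#'   auto-rejected), `xi`, and `auto_rejected`.
#' @export
propose_move <- function(state, site) {
  stopifnot(inherits(state, "cg_state"))
  sites <- titratable_sites(state)
  stopifnot(site >= 1, site <= length(sites))
  i <- sites[site]
  val <- state$topology$valence_when_ionized[i]
  explicit <- any(state$topology$chain_kind == "ion")
  trial <- state
  if (state$charges[i] != 0) {
    xi <- +1
    trial$charges[i] <- 0
    if (explicit) {
      p <- runif(3, 0, state$box_length)
      trial$positions <- rbind(trial$positions, p)
      trial$velocities <- rbind(trial$velocities, rnorm(3))
      trial$charges <- c(trial$charges, 1)
      trial$topology <- rbind(trial$topology, data.frame(
        label = "CAT", role = "ion", valence_when_ionized = 1L,
        titratable = FALSE, pKa = NA_real_,
        sigma = state$topology$sigma[1],
        molecule = max(state$topology$molecule) + 1L,
        chain_kind = "ion", stringsAsFactors = FALSE))
    } else {
      trial$implicit_cations <- trial$implicit_cations + 1L
    }
  } else {
    xi <- -1
    if (explicit) {
      cations <- which(trial$topology$chain_kind == "ion" &
                         trial$charges > 0)
      if (length(cations) == 0L)
        return(list(trial = NULL, xi = xi, auto_rejected = TRUE))
      k <- cations[sample.int(length(cations), 1L)]
      trial$positions <- trial$positions[-k, , drop = FALSE]
      trial$velocities <- trial$velocities[-k, , drop = FALSE]
      trial$charges <- trial$charges[-k]
      trial$topology <- trial$topology[-k, , drop = FALSE]
    } else {
      if (trial$implicit_cations < 1L)
        return(list(trial = NULL, xi = xi, auto_rejected = TRUE))
      trial$implicit_cations <- trial$implicit_cations - 1L
    }
    trial$charges[i] <- val
  }
  list(trial = trial, xi = xi, auto_rejected = FALSE)
}

#' Run coupled constant-pH Monte Carlo / Langevin dynamics
#'
#' Alternates `moves_per_cycle` trial ionization moves (sites chosen
#' uniformly at random; acceptance rule of [acceptance_probability()];
#' electroneutrality enforced after every move) with `ld_steps_per_cycle`
#' Langevin steps, recording one frame per cycle after the warmup.  The
#' ensemble average of the recorded ionization states estimates the degree
#' of ionization; see [degree_of_ionization()].
#'
#' In Debye-Hueckel implicit-ion mode the counterion insertion/deletion is
#' count-only and the move's \eqn{\Delta U} contains only the polymer
#' electrostatic change (the ideal-gas part of the exchange is carried by
#' the \eqn{\xi \ln 10 (\mathrm{pH} - \mathrm{p}K_a)} factor).  In
#' explicit-ion mode the neutralizing cation is a real particle.
#'
#' @param state a `"cg_state"` from [build_system()].
#' @param ff a [force_field()].
#' @param integrator an [integrator_params()].
#' @param cph a [cph_params()].
#' @param n_cycles total cycles (must exceed `warmup_cycles`).
#' @param warmup_cycles equilibration cycles discarded before recording.
#' @return A `"cg_trajectory"`; `$scalars` has columns `cycle`, `alpha`,
#'   `energy`, `kinetic`, `acceptance`, `cations`, `anions`, and
#'   `$metadata$final_state` holds the final `"cg_state"` for restarts.
#' @export
run_cph_ld <- function(state, ff, integrator = integrator_params(),
                       cph, n_cycles, warmup_cycles = 0) {
  stopifnot(inherits(state, "cg_state"), inherits(ff, "force_field"),
            inherits(integrator, "integrator_params"),
            inherits(cph, "cph_params"))
  if (n_cycles <= warmup_cycles)
    stop("n_cycles must exceed warmup_cycles", call. = FALSE)
  seed <- cph$seed %||% integrator$seed
  if (!is.null(seed)) set.seed(seed)
  sites <- titratable_sites(state)
  moves <- cph$moves_per_cycle %||% max(1L, length(sites))
  explicit <- ff$electrostatics_mode == "coulomb_explicit_ions"
  ffr <- resolve_ff(ff, state$box_length)

  n_all <- nrow(state$positions)
  pos <- state$positions
  vel <- state$velocities
  q <- state$charges
  if (explicit) {
    # spare capacity rows for cation insertions
    spare <- length(sites)
    pos <- rbind(pos, matrix(0, spare, 3))
    vel <- rbind(vel, matrix(0, spare, 3))
    q <- c(q, numeric(spare))
  }
  val <- if (length(sites) > 0)
    state$topology$valence_when_ionized[sites[1]] else 1
  # contiguous bead ranges of the oligocation molecules (translation moves)
  oc <- state$topology$chain_kind == "oligocation"
  mol_start <- integer(0); mol_n <- integer(0)
  if (any(oc)) {
    for (mid in unique(state$topology$molecule[oc])) {
      rows <- which(oc & state$topology$molecule == mid)
      stopifnot(all(diff(rows) == 1L))
      mol_start <- c(mol_start, rows[1] - 1L)
      mol_n <- c(mol_n, length(rows))
    }
  }
  trans <- cph$translation_moves_per_cycle %||% length(mol_start)
  res <- cpp_run_cph_ld(pos, vel, q,
                        as.integer(sites - 1L), as.numeric(val),
                        bonds_for_cpp(state$bonds), state$box_length, ffr,
                        integrator$dt, integrator$gamma,
                        cph$pH, cph$pKa,
                        as.integer(moves),
                        as.integer(cph$ld_steps_per_cycle),
                        as.integer(n_cycles), as.integer(warmup_cycles),
                        explicit, n_all, state$n_polymer_beads,
                        state$implicit_cations, state$implicit_anions,
                        mol_start, mol_n, as.integer(trans))

  final <- state
  nact <- res$final$n_active
  final$positions <- res$final$pos[seq_len(nact), , drop = FALSE]
  final$velocities <- res$final$vel[seq_len(nact), , drop = FALSE]
  final$charges <- res$final$q[seq_len(nact)]
  final$implicit_cations <- res$final$implicit_cations
  final$implicit_anions <- res$final$implicit_anions
  if (explicit) {
    # rebuild the ion part of the topology to the final ion census
    poly <- state$topology[seq_len(state$n_polymer_beads), , drop = FALSE]
    n_ion <- nact - state$n_polymer_beads
    qi <- final$charges[state$n_polymer_beads + seq_len(n_ion)]
    ion <- data.frame(
      label = ifelse(qi > 0, "CAT", "ANI"), role = "ion",
      valence_when_ionized = as.integer(sign(qi)),
      titratable = FALSE, pKa = NA_real_, sigma = ff$sigma,
      molecule = max(poly$molecule) + seq_len(n_ion),
      chain_kind = "ion", stringsAsFactors = FALSE)
    final$topology <- rbind(poly, ion)
  }

  scalars <- data.frame(cycle = res$cycle, alpha = res$alpha,
                        energy = res$epot, kinetic = res$ekin,
                        acceptance = res$acceptance,
                        cations = res$cations, anions = res$anions)
  new_trajectory(
    state$topology[seq_len(state$n_polymer_beads), , drop = FALSE],
    res$frames, scalars, state$box_length, state$n_polymer_beads,
    metadata = list(pH = cph$pH, pKa = cph$pKa,
                    force_field = unclass(ff),
                    dt = integrator$dt, gamma = integrator$gamma,
                    moves_per_cycle = moves,
                    ld_steps_per_cycle = cph$ld_steps_per_cycle,
                    warmup_cycles = warmup_cycles, seed = seed,
                    composition = state$composition,
                    final_state = final))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
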