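#' Langevin integrator parameters
#'
#' BAOAB splitting of underdamped Langevin dynamics at kBT = 1 with unit
#' masses; the noise amplitude satisfies fluctuation-dissipation exactly at
#' any timestep.  With `gamma = 0` the scheme reduces to velocity Verlet
#' (no thermostat).
#'
#' The default timestep 0.005 (reduced time, nm-based units) keeps the
#' stiffest motion in the model — an oppositely charged contact pair pressed
#' into the WCA wall — well inside the Verlet stability limit.
#'
#' @param dt timestep, reduced time (default 0.005).
#' @param gamma friction coefficient, 1/time (default 1).
#' @param seed optional integer seed applied before a run.
#' @return An object of class `"integrator_params"`.
#' @export
integrator_params <- function(dt = 0.005, gamma = 1.0, seed = NULL) {
  stopifnot(dt > 0, gamma >= 0)
  structure(list(dt = dt, gamma = gamma, seed = seed),
            class = "integrator_params")
}

#' Run plain Langevin dynamics at fixed ionization states
#'
#' @param state a `"cg_state"`.
#' @param ff a [force_field()].
#' @param params an [integrator_params()].
#' @param n_steps total number of steps.
#' @param record_every record one frame (positions, energies, kinetic
#'   energy) every this many steps.
#' @return list with the final `$state` and a `$trajectory`
#'   (`"cg_trajectory"`; `scalars` carry `energy`, `kinetic`).
#' @export
ld_run <- function(state, ff, params = integrator_params(), n_steps,
                   record_every = 100) {
  stopifnot(inherits(state, "cg_state"),
            inherits(params, "integrator_params"),
            n_steps >= 1, record_every >= 1)
  if (!is.null(params$seed)) set.seed(params$seed)
  n_cycles <- as.integer(ceiling(n_steps / record_every))
  ffr <- resolve_ff(ff, state$box_length)
  res <- cpp_run_cph_ld(state$positions, state$velocities, state$charges,
                        integer(0), 1.0,
                        bonds_for_cpp(state$bonds), state$box_length, ffr,
                        params$dt, params$gamma, 0, 0,
                        0L, as.integer(record_every),
                        n_cycles, 0L,
                        FALSE, nrow(state$positions),
                        state$n_polymer_beads,
                        state$implicit_cations, state$implicit_anions,
                        integer(0), integer(0), 0L)
  out_state <- state
  out_state$positions <- res$final$pos
  out_state$velocities <- res$final$vel
  scalars <- data.frame(step = res$cycle * record_every,
                        energy = res$epot, kinetic = res$ekin)
  traj <- new_trajectory(state$topology, res$frames, scalars,
                         state$box_length, state$n_polymer_beads,
                         metadata = list(dt = params$dt,
                                         gamma = params$gamma))
  list(state = out_state, trajectory = traj)
}

#' Single Langevin step
#'
#' One BAOAB update of positions and velocities at fixed ionization states.
#'
#' @inheritParams ld_run
#' @return the updated `"cg_state"`.
#' @export
ld_step <- function(state, ff, params = integrator_params()) {
  ld_run(state, ff, params, n_steps = 1, record_every = 1)$state
}
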