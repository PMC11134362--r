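#' Default run configuration
#'
#' The study conditions used throughout: one 48-mer polyanion with
#' oligocations at a 1:2 oligocation:polyanion monomer ratio, ionic
#' strength 0.01 mol/L, side-chain pKa 10.68, polyanion monomer
#' concentration 5e-3 mol/L, Debye-Hueckel electrostatics, BAOAB Langevin
#' dynamics with dt = 0.01 and gamma = 1.
#'
#' @param n oligocation length (monomers).
#' @return nested configuration list (the same shape [read_config()]
#'   returns), with sections `composition`, `force_field`, `integrator`,
#'   `cph` and `run`.
#' @export
example_config <- function(n = 8) {
  list(composition = list(m = 48L, n = as.integer(n),
                          n_polyanion_chains = 1L,
                          monomer_ratio = c(1, 2),
                          ionic_strength = 0.01,
                          pKa = 10.68,
                          polyanion_monomer_concentration = 5e-3),
       force_field = list(wca_epsilon = 1, sigma = 0.35,
                          bond_k = 400, bond_r0 = 0.4,
                          bjerrum_length = 0.71,
                          electrostatics_mode =
                            "debye_hueckel_implicit_ions",
                          ionic_strength = 0.01),
       integrator = list(dt = 0.005, gamma = 1.0),
       cph = list(pKa = 10.68, ld_steps_per_cycle = 20),
       run = list(n_cycles = 6500L, warmup_cycles = 1500L,
                  threshold = 2))
}

#' Read a run configuration file
#'
#' One documented dialect: YAML with the sections of [example_config()]
#' (`composition`, `force_field`, `integrator`, `cph`, `run`); every
#' default of the model is representable.  Missing keys fall back to the
#' defaults.  See `system.file("extdata", "example-config.yaml",
#' package = "regucharge")` for a complete example.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  # YAML 1.1 treats bare y/n keys as booleans; map them back so the
  # oligocation length can be written as a plain `n:` key
  user <- lapply(user, function(sec) {
    if (is.list(sec)) {
      names(sec)[names(sec) == "FALSE"] <- "n"
      names(sec)[names(sec) == "TRUE"] <- "y"
    }
    sec
  })
  base <- example_config()
  for (sec in names(base)) {
    if (!is.null(user[[sec]]))
      base[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  extra <- setdiff(names(user), names(base))
  if (length(extra) > 0)
    warning("ignoring unknown config sections: ",
            paste(extra, collapse = ", "), call. = FALSE)
  base
}

config_objects <- function(config, pH, seed = NULL) {
  comp <- do.call(system_composition,
                  c(config$composition, list(pH = pH, seed = seed)))
  ff <- do.call(force_field, config$force_field)
  ip <- do.call(integrator_params, config$integrator)
  cp <- do.call(cph_params, c(config$cph, list(pH = pH)))
  list(comp = comp, ff = ff, integrator = ip, cph = cp)
}

#' Run one constant-pH simulation from a configuration
#'
#' Convenience wrapper: build the system for the given pH and seed, run
#' the coupled constant-pH / Langevin sampler, and return the trajectory.
#'
#' @param config configuration list ([example_config()] / [read_config()]).
#' @param pH solution pH.
#' @param seed integer seed (controls building and sampling).
#' @param n_cycles,warmup_cycles override the `run` section when non-NULL.
#' @return a `"cg_trajectory"`.
#' @export
run_simulation <- function(config = example_config(), pH, seed = 1,
                           n_cycles = NULL, warmup_cycles = NULL) {
  obj <- config_objects(config, pH, seed)
  state <- build_system(obj$comp, obj$ff)
  run_cph_ld(state, obj$ff, obj$integrator, obj$cph,
             n_cycles = n_cycles %||% config$run$n_cycles,
             warmup_cycles = warmup_cycles %||% config$run$warmup_cycles)
}

#' pH sweep with per-run analysis and across-seed aggregation
#'
#' Runs build -> constant-pH/Langevin sampling -> analysis for every
#' (pH, seed) pair, aggregates titration, condensation and end-to-end
#' tables with across-seed standard errors, and (optionally) writes the
#' tables, a reproducibility manifest with file checksums, and the raw
#' trajectories.  A failed run is recorded in the manifest and the sweep
#' continues.
#'
#' @param config configuration list.
#' @param pH_list pH values to sweep.
#' @param seeds integer seeds (one run per pH per seed).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param n_cycles,warmup_cycles override the `run` section when non-NULL.
#' @param write_trajectories also write each run's trajectory (large).
#' @return list with `manifest` (config snapshot, runs table with status,
#'   checksums) and `tables` (`titration`, `condensation`, `end_to_end`).
#' @export
sweep_ph <- function(config = example_config(), pH_list, seeds = 1L,
                     out_dir = NULL, n_cycles = NULL, warmup_cycles = NULL,
                     write_trajectories = FALSE) {
  stopifnot(length(pH_list) >= 1, length(seeds) >= 1)
  threshold <- config$run$threshold %||% 2
  grid <- expand.grid(pH = pH_list, seed = seeds)
  runs <- data.frame(grid, status = "ok",
                     alpha = NA_real_, alpha_se = NA_real_,
                     condensed = NA_real_, condensed_se = NA_real_,
                     end_to_end = NA_real_, end_to_end_se = NA_real_,
                     stringsAsFactors = FALSE)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (ri in seq_len(nrow(grid))) {
    res <- tryCatch({
      traj <- run_simulation(config, pH = grid$pH[ri], seed = grid$seed[ri],
                             n_cycles = n_cycles,
                             warmup_cycles = warmup_cycles)
      a <- degree_of_ionization(traj)
      cf <- condensed_fraction(traj, threshold = threshold)
      ee <- end_to_end(traj)
      if (!is.null(out_dir) && write_trajectories)
        write_trajectory(traj, file.path(out_dir,
                                         sprintf("run_pH%g_seed%d",
                                                 grid$pH[ri],
                                                 grid$seed[ri])))
      c(a$alpha, a$se, cf$fraction, cf$se, ee$mean, ee$se)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      runs$status[ri] <- paste("error:", conditionMessage(res))
    } else {
      runs[ri, c("alpha", "alpha_se", "condensed", "condensed_se",
                 "end_to_end", "end_to_end_se")] <- res
    }
  }
  ok <- runs[runs$status == "ok", ]
  agg <- function(col) {
    mean_ <- tapply(ok[[col]], ok$pH, mean)
    se_ <- tapply(ok[[col]], ok$pH, function(v)
      if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
    data.frame(pH = as.numeric(names(mean_)),
               mean = as.numeric(mean_), se = as.numeric(se_))
  }
  tables <- list(titration = setNames(agg("alpha"),
                                      c("pH", "alpha", "alpha_se")),
                 condensation = setNames(agg("condensed"),
                                         c("pH", "condensed_fraction",
                                           "condensed_se")),
                 end_to_end = setNames(agg("end_to_end"),
                                       c("pH", "end_to_end",
                                         "end_to_end_se")))
  checksums <- character(0)
  if (!is.null(out_dir)) {
    paths <- c(titration = file.path(out_dir, "titration.csv"),
               condensation = file.path(out_dir, "condensation.csv"),
               end_to_end = file.path(out_dir, "end_to_end.csv"),
               runs = file.path(out_dir, "runs.csv"))
    write.csv(tables$titration, paths["titration"], row.names = FALSE)
    write.csv(tables$condensation, paths["condensation"], row.names = FALSE)
    write.csv(tables$end_to_end, paths["end_to_end"], row.names = FALSE)
    write.csv(runs, paths["runs"], row.names = FALSE)
    checksums <- tools::md5sum(paths)
    names(checksums) <- basename(paths)
  }
  manifest <- list(config = config,
                   pH_list = pH_list, seeds = seeds,
                   n_cycles = n_cycles %||% config$run$n_cycles,
                   warmup_cycles = warmup_cycles %||%
                     config$run$warmup_cycles,
                   package_version =
                     as.character(utils::packageVersion("regucharge")),
                   runs = runs,
                   checksums = as.list(checksums))
  if (!is.null(out_dir)) {
    man <- manifest
    man$runs <- NULL
    yaml::write_yaml(man, file.path(out_dir, "manifest.yaml"))
  }
  list(manifest = manifest, tables = tables)
}
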