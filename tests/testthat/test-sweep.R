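# Small, fast sweep configuration: a short polyanion keeps these
# orchestration tests cheap while exercising the full build/run/analyze
# path.
tiny_config <- function() {
  cfg <- example_config(n = 2)
  cfg$composition$m <- 8L
  cfg$composition$monomer_ratio <- c(1, 1)
  cfg$cph$ld_steps_per_cycle <- 5
  cfg$run$n_cycles <- 300L
  cfg$run$warmup_cycles <- 100L
  cfg
}

test_that("a pH sweep produces one run per (pH, seed) and aggregated tables", {
  res <- sweep_ph(tiny_config(), pH_list = c(10, 11, 12), seeds = c(1, 2))
  expect_equal(nrow(res$manifest$runs), 6)
  expect_true(all(res$manifest$runs$status == "ok"))
  expect_equal(nrow(res$tables$titration), 3)
  expect_equal(res$tables$titration$pH, c(10, 11, 12))
  expect_true(all(is.finite(res$tables$condensation$condensed_fraction)))
  expect_true(all(res$tables$titration$alpha >= 0 &
                    res$tables$titration$alpha <= 1))
  # ionization falls with pH across the transition for a base
  expect_gt(res$tables$titration$alpha[1], res$tables$titration$alpha[3])
})

test_that("sweeps are exactly reproducible at fixed seeds (DH mode)", {
  cfg <- tiny_config()
  r1 <- sweep_ph(cfg, pH_list = c(10.5, 11.5), seeds = 7L)
  r2 <- sweep_ph(cfg, pH_list = c(10.5, 11.5), seeds = 7L)
  expect_identical(r1$tables, r2$tables)
  expect_identical(r1$manifest$runs, r2$manifest$runs)
})

test_that("sweep outputs are written with checksums in the manifest", {
  dir <- withr::local_tempdir()
  res <- sweep_ph(tiny_config(), pH_list = 11, seeds = 1L, out_dir = dir)
  expect_true(file.exists(file.path(dir, "titration.csv")))
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  expect_equal(length(res$manifest$checksums), 4)
  expect_identical(unname(unlist(res$manifest$checksums["titration.csv"])),
                   unname(tools::md5sum(file.path(dir, "titration.csv"))))
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(man$config$composition$m, 8)
})

test_that("a failing run is recorded and the sweep continues", {
  cfg <- tiny_config()
  cfg$composition$polyanion_monomer_concentration <- 1  # box < contour
  res <- sweep_ph(cfg, pH_list = c(10, 11), seeds = 1L)
  expect_true(all(grepl("error", res$manifest$runs$status)))
  expect_equal(nrow(res$manifest$runs), 2)
})

test_that("config files read back with defaults filled in", {
  path <- system.file("extdata", "example-config.yaml",
                      package = "regucharge")
  cfg <- read_config(path)
  expect_equal(cfg$composition$m, 48)
  expect_equal(cfg$force_field$bjerrum_length, 0.71)
  expect_equal(cfg$integrator$dt, 0.005)
  # partial files inherit defaults
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("composition:\n  n: 4\n", f)  # bare n: a YAML boolean key
  cfg2 <- read_config(f)
  expect_equal(cfg2$composition$n, 4)
  expect_equal(cfg2$composition$m, 48)
  expect_warning(read_config({
    f2 <- withr::local_tempfile(fileext = ".yaml")
    writeLines("bogus:\n  a: 1\n", f2); f2
  }), "unknown config")
})

test_that("implicit-ion DH and explicit-ion Coulomb modes agree on the condensation trend", {
  # small system: condensation strong at pH below pKa, gone far above it
  base <- tiny_config()
  frac <- function(mode, pH, seed) {
    cfg <- base
    cfg$force_field$electrostatics_mode <- mode
    tr <- run_simulation(cfg, pH = pH, seed = seed,
                         n_cycles = 1200, warmup_cycles = 400)
    condensed_fraction(tr)$fraction
  }
  lo <- hi <- c()
  for (mode in c("debye_hueckel_implicit_ions", "coulomb_explicit_ions")) {
    lo[mode] <- frac(mode, 9.5, 5)
    hi[mode] <- frac(mode, 13.5, 5)
    expect_gt(lo[mode], hi[mode] + 0.2)  # same pH response in both modes
  }
  # and the two treatments agree on the magnitude for this dilute system
  expect_lt(abs(lo[1] - lo[2]), 0.2)
})
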