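test_that("degree of ionization averages sites and frames", {
  expect_equal(degree_of_ionization(matrix(c(1, 1, 0, 0), nrow = 1))$alpha,
               0.5)
  expect_equal(degree_of_ionization(list(c(1, 1), c(0, 0)))$alpha, 0.5)
  set.seed(81)
  big <- matrix(rbinom(1e4 * 4, 1, 0.3), ncol = 4)
  d <- degree_of_ionization(big)
  expect_lt(abs(d$alpha - 0.3), 0.01)
  expect_error(degree_of_ionization(matrix(numeric(0), 0, 2)), "frame")
  expect_error(degree_of_ionization(matrix(c(0, 2), 1)), "0/1")
})

test_that("minimum distance to the polyanion respects the minimum image", {
  tr <- point_trajectory(oligo_pos = matrix(0, 1, 3),
                         rod_pos = matrix(c(1, 0, 0), 1), L = 10)
  expect_equal(min_distance_to_polyanion(tr), 1)
  # periodic wrap across the box boundary
  trw <- point_trajectory(oligo_pos = matrix(c(0.5, 0, 0), 1),
                          rod_pos = matrix(c(9.5, 0, 0), 1), L = 10)
  expect_equal(min_distance_to_polyanion(trw), 1)
  tr0 <- point_trajectory(oligo_pos = matrix(c(1, 0, 0), 1),
                          rod_pos = matrix(c(1, 0, 0), 1), L = 10)
  expect_equal(min_distance_to_polyanion(tr0), 0)
  expect_error(min_distance_to_polyanion(tr, molecule = 5), "molecule")
})

test_that("condensed fraction counts molecule-frames inside the threshold", {
  near <- point_trajectory(oligo_pos = rbind(c(1.5, 0, 0), c(0.2, 0, 0)),
                           rod_pos = matrix(c(1, 0, 0), 1), L = 10,
                           n_frames = 5)
  expect_equal(condensed_fraction(near)$fraction, 1)
  far <- point_trajectory(oligo_pos = rbind(c(6, 0, 0), c(1, 5, 0)),
                          rod_pos = matrix(c(1, 0, 0), 1), L = 20,
                          n_frames = 5)
  expect_equal(condensed_fraction(far)$fraction, 0)
})

test_that("condensed fraction of a generated fixture matches a brute-force count", {
  spec <- mixture_fixture_spec(n_molecules = 10, n_frames = 1000,
                               condensed_fraction = 0.3, seed = 82)
  tr <- generate_mixture_trajectory(spec)
  cf <- condensed_fraction(tr, threshold = 2)
  # independent count straight from the coordinates
  pa <- which(tr$topology$chain_kind == "polyanion")
  oc <- which(tr$topology$chain_kind == "oligocation")
  mols <- unique(tr$topology$molecule[oc])
  L <- tr$box_length
  hits <- 0; tot <- 0
  for (fr in tr$frames) {
    for (m in mols) {
      rows <- oc[tr$topology$molecule[oc] == m]
      com <- colMeans(fr$pos[rows, , drop = FALSE])
      d <- sweep(fr$pos[pa, , drop = FALSE], 2, com)
      d <- d - L * round(d / L)
      tot <- tot + 1
      if (sqrt(min(rowSums(d * d))) < 2) hits <- hits + 1
    }
  }
  expect_equal(cf$fraction, hits / tot, tolerance = 1e-12)
  # binomial consistency with the generator probability
  expect_lt(abs(cf$fraction - 0.3), 3 * sqrt(0.3 * 0.7 / tot))
})

test_that("condensed fraction is monotone non-decreasing in the threshold", {
  spec <- mixture_fixture_spec(n_molecules = 6, n_frames = 200,
                               condensed_fraction = 0.5, seed = 83)
  tr <- generate_mixture_trajectory(spec)
  fr <- vapply(c(0.5, 1, 2, 5, 10, 19),
               function(th) condensed_fraction(tr, th)$fraction, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("distance-resolved ionization resolves the two populations", {
  spec <- mixture_fixture_spec(n_molecules = 10, n_frames = 500,
                               condensed_fraction = 0.5,
                               condensed_range = c(0.75, 0.85),
                               free_range = c(14.9, 15.1),
                               alpha_condensed = 0.95, alpha_free = 0.05,
                               seed = 84)
  tr <- generate_mixture_trajectory(spec)
  dri <- distance_resolved_ionization(tr)
  tab <- dri$table
  near <- tab[tab$bin_mid > 0.6 & tab$bin_mid < 1.0 & tab$population > 0, ]
  farb <- tab[tab$bin_mid > 14.5 & tab$bin_mid < 15.5 & tab$population > 0, ]
  expect_gt(sum(near$population), 0)
  expect_gt(sum(farb$population), 0)
  expect_lt(abs(stats::weighted.mean(near$mean_alpha, near$population) -
                  0.95), 0.02)
  expect_lt(abs(stats::weighted.mean(farb$mean_alpha, farb$population) -
                  0.05), 0.02)
  # intermediate bins are empty (bimodal population)
  mid <- tab[tab$bin_mid > 2 & tab$bin_mid < 14, ]
  expect_equal(sum(mid$population), 0)
  expect_true(all(is.na(mid$mean_alpha)))
  # scatter has one row per molecule-frame
  expect_equal(nrow(dri$scatter), 10 * 500)
})

test_that("population-weighted binned ionization conserves the global mean", {
  spec <- mixture_fixture_spec(n_molecules = 8, n_frames = 300,
                               condensed_fraction = 0.4, seed = 85)
  tr <- generate_mixture_trajectory(spec)
  dri <- distance_resolved_ionization(tr)
  tab <- dri$table[dri$table$population > 0, ]
  global <- stats::weighted.mean(tab$mean_alpha, tab$population)
  expect_equal(global, degree_of_ionization(tr)$alpha, tolerance = 1e-12)
})

test_that("ionization is flat in distance when independent of position", {
  spec <- mixture_fixture_spec(n_molecules = 10, n_frames = 800,
                               condensed_fraction = 0.5,
                               alpha_condensed = 0.4, alpha_free = 0.4,
                               sites_per_molecule = 8, seed = 86)
  tr <- generate_mixture_trajectory(spec)
  tab <- distance_resolved_ionization(tr)$table
  occ <- tab[tab$population >= 50, ]
  ci <- 3 * sqrt(0.4 * 0.6 / (8 * occ$population))
  expect_true(all(abs(occ$mean_alpha - 0.4) < ci + 0.02))
})

test_that("end-to-end distance of a straight rod and of an ideal chain", {
  spec <- mixture_fixture_spec(n_molecules = 2, n_frames = 20,
                               condensed_fraction = 0.5, rod_monomers = 48,
                               seed = 87)
  tr <- generate_mixture_trajectory(spec)
  ee <- end_to_end(tr)
  expect_equal(ee$mean, 47 * 0.4, tolerance = 1e-9)
  expect_equal(stats::sd(ee$per_frame), 0)  # frozen conformation
  # ideal random walk: <R^2> = N b^2
  set.seed(88)
  N <- 30; b <- 0.4; nconf <- 1000
  topo <- data.frame(label = "PAB", role = "backbone",
                     valence_when_ionized = 0L, titratable = FALSE,
                     pKa = NA_real_, sigma = 0.35, molecule = 1L,
                     chain_kind = "polyanion", stringsAsFactors = FALSE)
  topo <- topo[rep(1, N + 1), ]
  frames <- lapply(seq_len(nconf), function(i) {
    steps <- matrix(rnorm(3 * N), ncol = 3)
    steps <- b * steps / sqrt(rowSums(steps^2))
    pos <- apply(rbind(0, steps), 2, cumsum) + 50
    list(pos = pos, q = rep(0, N + 1))
  })
  trw <- new_trajectory(topo, frames, data.frame(cycle = seq_len(nconf)),
                        100, N + 1)
  ee2 <- end_to_end(trw)
  expect_equal(mean(ee2$per_frame^2), N * b^2, tolerance = 0.1)
  expect_error(end_to_end(point_trajectory(matrix(0, 1, 3))), "two backbone")
})

test_that("local H+ profile equals bulk pH for an uncharged system", {
  spec <- mixture_fixture_spec(n_molecules = 2, n_frames = 3,
                               condensed_fraction = 0.5, seed = 89)
  tr <- generate_mixture_trajectory(spec)
  for (fi in seq_along(tr$frames)) tr$frames[[fi]]$q[] <- 0
  set.seed(90)
  prof <- local_hplus_profile(tr, breaks = seq(0, 8, 1), bulk_pH = 10)
  got <- prof[prof$samples > 0, ]
  expect_true(all(abs(got$local_pH - 10) < 1e-9))
})

test_that("local H+ profile around a single screened charge follows the closed form", {
  # one positive fixed bead: c_H(r)/bulk = exp(-lB e^{-kr}/r)
  topo <- data.frame(label = "PAS", role = "sidechain",
                     valence_when_ionized = 1L, titratable = FALSE,
                     pKa = NA_real_, sigma = 0.35, molecule = 1L,
                     chain_kind = "polyanion", stringsAsFactors = FALSE)
  L <- 20
  fr <- list(pos = matrix(L / 2, 1, 3), q = 1)
  ffm <- unclass(force_field(kappa = 1))  # 1 nm screening length
  tr <- new_trajectory(topo, list(fr), data.frame(cycle = 1), L, 1,
                       metadata = list(pH = 10, pKa = 10.68,
                                       force_field = ffm))
  set.seed(91)
  prof <- local_hplus_profile(tr, breaks = seq(0, 8, 0.25), bulk_pH = 10,
                              n_probes = 3e5)
  lB <- ffm$bjerrum_length; kap <- ffm$kappa
  sel <- prof$samples > 100 & prof$bin_mid > 1 & prof$bin_mid < 4
  expect_gt(sum(sel), 5)
  expected <- exp(-lB * exp(-kap * prof$bin_mid) / prof$bin_mid)
  ratio <- prof$c_h / 10^-10
  expect_lt(max(abs(ratio[sel] - expected[sel])), 0.02)
  # far field (r > 5/kappa): bulk value within 1%
  farf <- prof$bin_mid > 5 / kap & prof$samples > 100
  expect_gt(sum(farf), 3)
  expect_true(all(abs(ratio[farf] - 1) < 0.01))
})
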