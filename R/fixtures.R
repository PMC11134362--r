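#' Specification of a synthetic two-population trajectory
#'
#' Describes synthetic data with the statistical structure the analysis
#' assumes for charge-regulating oligocations around a polyanion: each
#' molecule-frame belongs with probability `condensed_fraction` to a
#' condensed population (close to the chain, highly ionized) and otherwise
#' to a free population (far from the chain, weakly ionized).  Distances
#' are drawn uniformly from the respective range; per-site ionization is
#' Bernoulli at the population level.
#'
#' @param n_molecules number of oligocation molecules.
#' @param n_frames number of frames.
#' @param condensed_fraction probability f of the condensed population.
#' @param condensed_range,free_range uniform distance laws, nm.
#' @param alpha_condensed,alpha_free per-site ionization probabilities.
#' @param sites_per_molecule titratable sites per molecule.
#' @param rod_monomers straight polyanion length (monomers, 0.4 nm spacing).
#' @param box_length cubic box edge, nm.
#' @param threshold condensation threshold the geometry must respect, nm.
#' @param seed integer seed.
#' @return An object of class `"mixture_fixture_spec"`.
#' @export
mixture_fixture_spec <- function(n_molecules, n_frames,
                                 condensed_fraction,
                                 condensed_range = c(0.3, 1.5),
                                 free_range = c(8, 18),
                                 alpha_condensed = 0.95,
                                 alpha_free = 0.05,
                                 sites_per_molecule = 8,
                                 rod_monomers = 48,
                                 box_length = 40,
                                 threshold = 2,
                                 seed = NULL) {
  stopifnot(n_molecules >= 1, n_frames >= 1,
            condensed_fraction >= 0, condensed_fraction <= 1,
            alpha_condensed >= 0, alpha_condensed <= 1,
            alpha_free >= 0, alpha_free <= 1,
            sites_per_molecule >= 1, rod_monomers >= 2,
            length(condensed_range) == 2L, length(free_range) == 2L,
            box_length > 0)
  if (condensed_range[1] <= 0 || condensed_range[2] >= threshold)
    stop("condensed distance law must lie strictly inside the threshold",
         call. = FALSE)
  if (free_range[1] < threshold)
    stop("free distance law reaches inside the condensation threshold; ",
         "impossible geometry", call. = FALSE)
  if (free_range[2] > box_length / 2)
    stop("free distance law exceeds half the box", call. = FALSE)
  structure(list(n_molecules = as.integer(n_molecules),
                 n_frames = as.integer(n_frames),
                 condensed_fraction = condensed_fraction,
                 condensed_range = condensed_range,
                 free_range = free_range,
                 alpha_condensed = alpha_condensed,
                 alpha_free = alpha_free,
                 sites_per_molecule = as.integer(sites_per_molecule),
                 rod_monomers = as.integer(rod_monomers),
                 box_length = box_length,
                 threshold = threshold,
                 seed = seed),
            class = "mixture_fixture_spec")
}

#' Generate a synthetic two-population trajectory
#'
#' Builds a `"cg_trajectory"` realizing a [mixture_fixture_spec()]: a
#' straight polyanion rod through the box center (0.4 nm bead spacing along
#' z) and point-like oligocation molecules placed at exactly known minimum
#' distances (radial offsets from a randomly chosen rod bead), so every
#' observable of the analysis layer can be validated against the generator
#' parameters without running the simulator.  The object is
#' indistinguishable from simulator output at the contract level and
#' round-trips through [write_trajectory()].
#'
#' @param spec a [mixture_fixture_spec()].
#' @return a `"cg_trajectory"`.
#' @export
generate_mixture_trajectory <- function(spec) {
  stopifnot(inherits(spec, "mixture_fixture_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  L <- spec$box_length
  m <- spec$rod_monomers
  rod_z <- L / 2 + (seq_len(m) - (m + 1) / 2) * 0.4
  rod <- cbind(L / 2, L / 2, rod_z)

  topo_rod <- data.frame(
    label = "PAS", role = "backbone", valence_when_ionized = -1L,
    titratable = FALSE, pKa = NA_real_, sigma = 0.35,
    molecule = 1L, chain_kind = "polyanion", stringsAsFactors = FALSE)
  topo_rod <- topo_rod[rep(1L, m), ]
  ns <- spec$sites_per_molecule
  topo_oc <- data.frame(
    label = "OLS", role = "sidechain", valence_when_ionized = 1L,
    titratable = TRUE, pKa = 10.68, sigma = 0.35,
    molecule = rep(1L + seq_len(spec$n_molecules), each = ns),
    chain_kind = "oligocation", stringsAsFactors = FALSE)
  topology <- rbind(topo_rod, topo_oc)
  rownames(topology) <- NULL

  frames <- vector("list", spec$n_frames)
  alpha_frame <- numeric(spec$n_frames)
  for (fi in seq_len(spec$n_frames)) {
    pos <- matrix(NA_real_, nrow(topology), 3)
    pos[seq_len(m), ] <- rod
    q <- c(rep(-1, m), numeric(ns * spec$n_molecules))
    for (mi in seq_len(spec$n_molecules)) {
      condensed <- runif(1) < spec$condensed_fraction
      rng <- if (condensed) spec$condensed_range else spec$free_range
      d <- runif(1, rng[1], rng[2])
      b <- sample.int(m, 1)
      th <- runif(1, 0, 2 * pi)
      p <- rod[b, ] + c(d * cos(th), d * sin(th), 0)
      rows <- m + (mi - 1L) * ns + seq_len(ns)
      pos[rows, ] <- matrix(p, ns, 3, byrow = TRUE)
      a <- if (condensed) spec$alpha_condensed else spec$alpha_free
      q[rows] <- rbinom(ns, 1L, a)
    }
    frames[[fi]] <- list(pos = pos, q = q)
    tit <- which(topology$titratable)
    alpha_frame[fi] <- mean(q[tit] != 0)
  }
  scalars <- data.frame(cycle = seq_len(spec$n_frames),
                        alpha = alpha_frame)
  new_trajectory(topology, frames, scalars, L, nrow(topology),
                 metadata = list(pH = NA_real_, pKa = 10.68,
                                 fixture_spec = unclass(spec)))
}

#' Generate a noisy synthetic titration series
#'
#' Hill-type sigmoid for a weak base,
#' \eqn{\alpha(\mathrm{pH}) = 1/(1 + 10^{s(\mathrm{pH} -
#' \mathrm{p}K_a^{\mathrm{eff}})})}, with additive Gaussian noise clipped
#' to `[0, 1]` — the statistical shape of a simulated or measured
#' degree-of-ionization curve.
#'
#' @param pKa_eff midpoint (pH at alpha = 0.5).
#' @param hill_slope cooperativity parameter s (ideal HH: 1).
#' @param pH_grid pH values.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return data frame with columns `pH`, `alpha`.
#' @export
generate_titration_series <- function(pKa_eff, hill_slope = 1, pH_grid,
                                      noise_sd = 0, seed = NULL) {
  stopifnot(is.finite(pKa_eff), is.finite(hill_slope), noise_sd >= 0,
            length(pH_grid) >= 1)
  if (!is.null(seed)) set.seed(seed)
  a <- 1 / (1 + 10^(hill_slope * (pH_grid - pKa_eff)))
  if (noise_sd > 0) a <- a + rnorm(length(a), 0, noise_sd)
  data.frame(pH = pH_grid, alpha = pmin(1, pmax(0, a)))
}

#' Fit a Hill-type titration curve
#'
#' Least-squares fit of \eqn{\alpha = 1/(1 + 10^{s(\mathrm{pH} - p)})} to a
#' degree-of-ionization series of a weak base; the fitted midpoint `p` is
#' the effective pKa (pH at alpha = 0.5) and `s` the Hill slope (1 for the
#' ideal Henderson-Hasselbalch curve, > 1 for a cooperative transition).
#'
#' @param data data frame with columns `pH` and `alpha` (>= 4 points
#'   spanning the transition).
#' @return list with `pKa_eff`, `hill_slope` and the `nls` fit object.
#' @export
#' @examples
#' d <- generate_titration_series(10.68, 1, seq(8, 13, 0.5))
#' fit_titration(d)$pKa_eff
fit_titration <- function(data) {
  stopifnot(is.data.frame(data), all(c("pH", "alpha") %in% names(data)))
  data <- data[is.finite(data$alpha), ]
  if (nrow(data) < 4)
    stop("need at least 4 titration points", call. = FALSE)
  if (min(data$alpha) > 0.5 || max(data$alpha) < 0.5 ||
      diff(range(data$alpha)) < 0.2)
    stop("no ionization transition in the sampled pH range; cannot fit",
         call. = FALSE)
  p0 <- data$pH[which.min(abs(data$alpha - 0.5))]
  fit <- minpack.lm::nlsLM(alpha ~ 1 / (1 + 10^(s * (pH - p))),
                           data = data,
                           start = list(s = 1, p = p0),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200))
  co <- coef(fit)
  list(pKa_eff = unname(co["p"]), hill_slope = unname(co["s"]), fit = fit)
}
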