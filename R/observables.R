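#' Degree of ionization with block-averaged uncertainty
#'
#' Mean ionization over all titratable sites and frames; the standard error
#' comes from block averaging of the per-frame means (at least 10 blocks
#' when enough frames are available), which is robust to the
#' autocorrelation of Monte Carlo series.
#'
#' @param x a `"cg_trajectory"`, or a frames x sites 0/1 matrix, or a list
#'   of per-frame 0/1 vectors.
#' @param n_blocks number of blocks for the error estimate.
#' @return list with `alpha`, `se`, `n_frames`, `n_sites`.
#' @export
#' @examples
#' degree_of_ionization(matrix(c(1, 1, 0, 0), nrow = 1))$alpha  # 0.5
degree_of_ionization <- function(x, n_blocks = 10) {
  ion <- if (inherits(x, "cg_trajectory")) ionization_matrix(x)
         else if (is.list(x) && !is.data.frame(x)) do.call(rbind, x)
         else as.matrix(x)
  if (length(ion) == 0L || nrow(ion) == 0L)
    stop("need at least one frame of ionization states", call. = FALSE)
  if (!all(ion %in% c(0, 1)))
    stop("ionization states must be 0/1", call. = FALSE)
  per_frame <- rowMeans(ion)
  list(alpha = mean(per_frame), se = block_se(per_frame, n_blocks),
       n_frames = nrow(ion), n_sites = ncol(ion))
}

# polyanion bead row indices of a trajectory/topology
polyanion_rows <- function(topology) {
  which(topology$chain_kind == "polyanion")
}

# per-frame, per-molecule minimum-image distance between each oligocation's
# center of mass and the nearest polyanion bead, plus the molecule's alpha
oligo_frame_stats <- function(traj) {
  topo <- traj$topology
  pa <- polyanion_rows(topo)
  if (length(pa) == 0L)
    stop("trajectory contains no polyanion", call. = FALSE)
  oc <- which(topo$chain_kind == "oligocation")
  mols <- sort(unique(topo$molecule[oc]))
  if (length(mols) == 0L)
    stop("trajectory contains no oligocation molecules", call. = FALSE)
  L <- traj$box_length
  mol_of <- topo$molecule[oc]
  mol_fac <- factor(mol_of, levels = mols)
  tit <- topo$titratable[oc]
  out <- vector("list", length(traj$frames))
  for (fi in seq_along(traj$frames)) {
    fr <- traj$frames[[fi]]
    P <- fr$pos[pa, , drop = FALSE]
    X <- fr$pos[oc, , drop = FALSE]
    com <- apply(X, 2, function(col) tapply(col, mol_fac, mean))
    com <- matrix(com, ncol = 3)
    d2 <- matrix(0, nrow(com), nrow(P))
    for (k in 1:3) {
      dk <- outer(com[, k], P[, k], "-")
      dk <- dk - L * round(dk / L)
      d2 <- d2 + dk * dk
    }
    dmin <- sqrt(apply(d2, 1, min))
    qoc <- fr$q[oc]
    amol <- tapply(as.integer(qoc[tit] != 0), mol_fac[tit], mean)
    out[[fi]] <- data.frame(frame = fi, molecule = mols,
                            distance = dmin,
                            alpha = as.numeric(amol))
  }
  do.call(rbind, out)
}

#' Minimum distance from an oligocation to the polyanion
#'
#' Minimum-image distance between the center of mass of one oligocation
#' molecule and the nearest polyanion bead.
#'
#' @param state a `"cg_state"` (or a single-frame `"cg_trajectory"`).
#' @param molecule which oligocation (1-based among the oligocations).
#' @return distance in nm.
#' @export
min_distance_to_polyanion <- function(state, molecule = 1) {
  if (inherits(state, "cg_state")) {
    traj <- new_trajectory(
      state$topology[seq_len(state$n_polymer_beads), , drop = FALSE],
      list(list(pos = state$positions, q = state$charges)),
      data.frame(cycle = 1L), state$box_length, state$n_polymer_beads)
  } else traj <- state
  st <- oligo_frame_stats(traj)
  st <- st[st$frame == 1L, ]
  if (molecule < 1 || molecule > nrow(st))
    stop("no such oligocation molecule", call. = FALSE)
  st$distance[molecule]
}

#' Condensed fraction of oligocations
#'
#' Fraction of (molecule, frame) pairs whose center of mass lies within
#' `threshold` of the nearest polyanion bead — the 2 nm criterion
#' corresponds to the local minimum between the condensed and free
#' populations of the distance histogram.  The standard error is block
#' averaged over the per-frame fractions.
#'
#' @param traj a `"cg_trajectory"` containing a polyanion.
#' @param threshold condensation distance threshold, nm (default 2).
#' @param n_blocks blocks for the error estimate.
#' @return An object of class `"condensation_result"`: `fraction`, `se`,
#'   `threshold`, per-frame fractions (`$per_frame`) and the raw
#'   molecule-frame distances (`$distances`).
#' @export
condensed_fraction <- function(traj, threshold = 2, n_blocks = 10) {
  st <- oligo_frame_stats(traj)
  cond <- st$distance < threshold
  per_frame <- tapply(cond, st$frame, mean)
  structure(list(fraction = mean(cond),
                 se = block_se(as.numeric(per_frame), n_blocks),
                 threshold = threshold,
                 per_frame = as.numeric(per_frame),
                 distances = st),
            class = "condensation_result")
}

#' @export
print.condensation_result <- function(x, ...) {
  cat(sprintf("condensed fraction (< %g nm): %.3f +/- %.3f\n",
              x$threshold, x$fraction, as.numeric(x$se)))
  invisible(x)
}

#' Distance-resolved ionization and population of oligocations
#'
#' Bins the per-molecule, per-frame minimum distance to the polyanion and
#' reports the mean per-molecule degree of ionization and the molecule-frame
#' population per bin, together with the raw scatter (one row per molecule
#' per frame).  The two-population structure of charge-regulating
#' oligocations shows up as a bimodal population with high ionization in
#' the near bins and low ionization in the far bins.
#'
#' @param traj a `"cg_trajectory"`.
#' @param breaks bin breaks in nm; default 0.25 nm bins spanning 0 to L/2.
#' @return list with `table` (bin_lo, bin_hi, bin_mid, mean_alpha — `NA`
#'   for empty bins — and population) and `scatter`.
#' @export
distance_resolved_ionization <- function(traj,
                                         breaks = seq(0, traj$box_length / 2,
                                                      by = 0.25)) {
  st <- oligo_frame_stats(traj)
  if (max(st$distance) > max(breaks))
    breaks <- c(breaks, max(st$distance) + 0.25)
  bin <- cut(st$distance, breaks = breaks, include.lowest = TRUE,
             labels = FALSE)
  nb <- length(breaks) - 1L
  pop <- tabulate(bin, nbins = nb)
  mean_alpha <- rep(NA_real_, nb)
  got <- sort(unique(bin))
  mean_alpha[got] <- as.numeric(tapply(st$alpha, factor(bin, levels = got),
                                       mean))
  list(table = data.frame(bin_lo = breaks[-length(breaks)],
                          bin_hi = breaks[-1],
                          bin_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                          mean_alpha = mean_alpha,
                          population = pop),
       scatter = st)
}

#' Polyanion end-to-end distance
#'
#' Distance between the first and last backbone bead of the polyanion,
#' averaged over frames, using unwrapped coordinates.
#'
#' @param traj a `"cg_trajectory"`.
#' @param n_blocks blocks for the error estimate.
#' @return list with `mean`, `se` and the per-frame series.
#' @export
end_to_end <- function(traj, n_blocks = 10) {
  topo <- traj$topology
  pa <- which(topo$chain_kind == "polyanion" & topo$role == "backbone")
  if (length(pa) < 2L)
    stop("polyanion needs at least two backbone beads", call. = FALSE)
  mol1 <- topo$molecule[pa[1]]
  pa <- pa[topo$molecule[pa] == mol1]
  i <- pa[1]; j <- pa[length(pa)]
  series <- vapply(traj$frames, function(fr)
    sqrt(sum((fr$pos[i, ] - fr$pos[j, ])^2)), numeric(1))
  list(mean = mean(series), se = block_se(series, n_blocks),
       per_frame = series)
}

#' Local hydronium-concentration profile (proxy)
#'
#' Estimates the local H+ concentration as a function of the distance to
#' the nearest polyanion bead.  In Debye-Hueckel mode the estimate is the
#' Boltzmann factor of the mean screened potential of the charged beads,
#' sampled at random probe points:
#' \eqn{c_H(r) = 10^{-\mathrm{pH}} \langle e^{-\psi} \rangle_r}.  In
#' explicit-ion mode the cation pair-density relative to bulk is counted
#' instead.  The result is also expressed as a "local pH"
#' \eqn{-\log_{10} c_H}; far from the chain it tends to the bulk pH.
#'
#' @param traj a `"cg_trajectory"`.
#' @param breaks distance-bin breaks, nm.
#' @param bulk_pH bulk solution pH (defaults to the trajectory metadata).
#' @param n_probes random probe points per analysed frame (DH mode).
#' @param max_frames analyse at most this many equally spaced frames.
#' @return data frame with bin_mid, c_h (mol/L), local_pH, samples.
#' @export
local_hplus_profile <- function(traj, breaks = seq(0, 10, by = 0.5),
                                bulk_pH = traj$metadata$pH,
                                n_probes = 2000, max_frames = 50) {
  stopifnot(inherits(traj, "cg_trajectory"), is.finite(bulk_pH))
  topo <- traj$topology
  pa <- polyanion_rows(topo)
  if (length(pa) == 0L)
    stop("trajectory contains no polyanion", call. = FALSE)
  L <- traj$box_length
  md <- traj$metadata
  ffm <- md$force_field
  explicit <- length(traj$frames[[1]]$q) > traj$n_polymer_beads
  sel <- unique(round(seq(1, length(traj$frames),
                          length.out = min(max_frames,
                                           length(traj$frames)))))
  nb <- length(breaks) - 1L
  wsum <- numeric(nb); cnt <- numeric(nb)
  for (fi in sel) {
    fr <- traj$frames[[fi]]
    P <- fr$pos[pa, , drop = FALSE]
    if (explicit) {
      np <- nrow(fr$pos)
      ion <- seq(traj$n_polymer_beads + 1L, np)
      cat_rows <- ion[fr$q[ion] > 0]
      probes <- fr$pos[cat_rows, , drop = FALSE]
      w <- rep(1, nrow(probes))
    } else {
      probes <- matrix(runif(3 * n_probes, 0, L), ncol = 3)
      lB <- ffm$bjerrum_length %||% 0.71
      kap <- ffm$kappa %||% 0
      chg <- which(fr$q != 0)
      Q <- fr$pos[chg, , drop = FALSE]
      qv <- fr$q[chg]
      psi <- numeric(nrow(probes))
      for (k in seq_len(nrow(Q))) {
        d <- sweep(probes, 2, Q[k, ])
        d <- d - L * round(d / L)
        r <- sqrt(rowSums(d * d))
        r[r < 1e-6] <- 1e-6
        psi <- psi + qv[k] * lB * exp(-kap * r) / r
      }
      w <- exp(-psi)
    }
    d2 <- matrix(0, nrow(probes), nrow(P))
    for (k in 1:3) {
      dk <- outer(probes[, k], P[, k], "-")
      dk <- dk - L * round(dk / L)
      d2 <- d2 + dk * dk
    }
    dmin <- sqrt(apply(d2, 1, min))
    bin <- cut(dmin, breaks = breaks, include.lowest = TRUE, labels = FALSE)
    keep <- !is.na(bin)
    if (!any(keep)) next
    wsum <- wsum + as.numeric(tapply(w[keep], factor(bin[keep],
                                                     levels = seq_len(nb)),
                                     sum, default = 0))
    cnt <- cnt + tabulate(bin[keep], nbins = nb)
  }
  if (explicit) {
    # cation count per bin vs the count a uniform bulk gas would give
    vol_frac <- rep(NA_real_, nb)
    mean_g <- rep(NA_real_, nb)
    # estimate bin volumes by uniform sampling
    probes <- matrix(runif(3 * 20000, 0, L), ncol = 3)
    fr <- traj$frames[[sel[1]]]
    P <- fr$pos[pa, , drop = FALSE]
    d2 <- matrix(0, nrow(probes), nrow(P))
    for (k in 1:3) {
      dk <- outer(probes[, k], P[, k], "-")
      dk <- dk - L * round(dk / L)
      d2 <- d2 + dk * dk
    }
    dmin <- sqrt(apply(d2, 1, min))
    vbin <- tabulate(cut(dmin, breaks = breaks, include.lowest = TRUE,
                         labels = FALSE), nbins = nb) / 20000 * L^3
    n_cat_bulk <- mean(vapply(sel, function(fi) {
      frx <- traj$frames[[fi]]
      sum(frx$q[-seq_len(traj$n_polymer_beads)] > 0)
    }, numeric(1)))
    rho_bulk <- n_cat_bulk / L^3
    g <- (wsum / length(sel)) / (vbin * rho_bulk)
    g[vbin <= 0] <- NA_real_
    c_h <- 10^(-bulk_pH) * g
  } else {
    g <- wsum / pmax(cnt, 1)
    g[cnt == 0] <- NA_real_
    c_h <- 10^(-bulk_pH) * g
  }
  data.frame(bin_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
             c_h = c_h, local_pH = -log10(c_h),
             samples = cnt)
}
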