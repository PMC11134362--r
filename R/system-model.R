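#' Bead specification
#'
#' One bead type of the two-beads-per-monomer model: every monomeric unit is
#' a backbone bead plus a pendant side-chain bead.  Polyanion (PMAA-like)
#' side chains carry a fixed charge of -1 (fully ionized, since the pH range
#' of interest is far above the acid pKa of about 4.28); oligocation
#' (oligolysine-like) side chains are titratable weak bases with conjugate
#' acid pKa 10.68.
#'
#' @param label short species label (used in trajectory files).
#' @param valence_when_ionized integer charge in the ionized state (-1, 0, +1).
#' @param is_titratable logical; does this bead undergo constant-pH moves?
#' @param pKa conjugate-acid pKa (finite iff titratable).
#' @param diameter_sigma bead diameter, nm.
#' @return An object of class `"bead_spec"`.
#' @export
bead_spec <- function(label, valence_when_ionized, is_titratable = FALSE,
                      pKa = NA_real_, diameter_sigma = 0.35) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            valence_when_ionized %in% c(-1L, 0L, 1L),
            is.logical(is_titratable), length(is_titratable) == 1L,
            diameter_sigma > 0)
  if (is_titratable && !is.finite(pKa))
    stop("titratable beads require a finite pKa", call. = FALSE)
  structure(list(label = label,
                 valence_when_ionized = as.integer(valence_when_ionized),
                 is_titratable = is_titratable,
                 pKa = as.numeric(pKa),
                 diameter_sigma = diameter_sigma),
            class = "bead_spec")
}

default_bead_specs <- function(kind, pKa = 10.68, sigma = 0.35) {
  switch(kind,
    polyanion = list(
      backbone  = bead_spec("PAB", 0L, FALSE, diameter_sigma = sigma),
      sidechain = bead_spec("PAS", -1L, FALSE, diameter_sigma = sigma)),
    oligocation = list(
      backbone  = bead_spec("OLB", 0L, FALSE, diameter_sigma = sigma),
      sidechain = bead_spec("OLS", 1L, TRUE, pKa = pKa,
                            diameter_sigma = sigma)),
    stop("unknown chain kind: ", kind, call. = FALSE))
}

#' Build a chain topology
#'
#' Linear backbone of `n_monomers` beads, each carrying one pendant
#' side-chain bead; `2 * n_monomers` beads and `2 * n_monomers - 1` bonds in
#' total.  Chain ends carry no extra ionizable groups (the modelled
#' oligopeptides have protected, nonionizable termini), so oligocation
#' termini are the ordinary uncharged backbone beads.
#'
#' @param kind `"polyanion"` or `"oligocation"`.
#' @param n_monomers number of monomeric units (>= 1).
#' @param bead_specs list with elements `backbone` and `sidechain`, each a
#'   [bead_spec()]; defaults appropriate for `kind` when `NULL`.
#' @return An object of class `"chain_topology"`: the per-bead table
#'   (`$beads`), the bond list (`$bonds`, 1-based index pairs), `$kind` and
#'   `$n_monomers`.  Beads are ordered monomer by monomer
#'   (backbone, sidechain, backbone, sidechain, ...).
#' @export
#' @examples
#' topo <- build_topology("polyanion", 48)
#' nrow(topo$beads)  # 96
#' nrow(topo$bonds)  # 95
build_topology <- function(kind = c("polyanion", "oligocation"), n_monomers,
                           bead_specs = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(n_monomers) || length(n_monomers) != 1L ||
      n_monomers < 1 || n_monomers != round(n_monomers))
    stop("n_monomers must be a positive integer", call. = FALSE)
  n_monomers <- as.integer(n_monomers)
  if (is.null(bead_specs)) bead_specs <- default_bead_specs(kind)
  stopifnot(inherits(bead_specs$backbone, "bead_spec"),
            inherits(bead_specs$sidechain, "bead_spec"))
  bb <- bead_specs$backbone
  sc <- bead_specs$sidechain

  n_beads <- 2L * n_monomers
  role <- rep(c("backbone", "sidechain"), n_monomers)
  beads <- data.frame(
    label = ifelse(role == "backbone", bb$label, sc$label),
    role = role,
    valence_when_ionized = ifelse(role == "backbone",
                                  bb$valence_when_ionized,
                                  sc$valence_when_ionized),
    titratable = ifelse(role == "backbone", bb$is_titratable,
                        sc$is_titratable),
    pKa = ifelse(role == "backbone", bb$pKa, sc$pKa),
    sigma = ifelse(role == "backbone", bb$diameter_sigma, sc$diameter_sigma),
    stringsAsFactors = FALSE)

  backbone_idx <- seq(1L, n_beads, by = 2L)
  side_idx <- backbone_idx + 1L
  bonds <- rbind(
    if (n_monomers > 1L)
      cbind(backbone_idx[-n_monomers], backbone_idx[-1L]),
    cbind(backbone_idx, side_idx))
  structure(list(kind = kind, n_monomers = n_monomers,
                 beads = beads, bonds = bonds),
            class = "chain_topology")
}

#' System composition
#'
#' Defines one simulated solution: a polyanion of `m` monomers plus enough
#' oligocations of length `n` to give the chosen oligocation:polyanion
#' monomer ratio (default 1:2, as in the modelled experiments), at a given
#' pH and ionic strength.  The cubic box edge follows from the polyanion
#' monomer concentration.
#'
#' @param m polyanion length (monomers).
#' @param n oligocation length (monomers).
#' @param pH solution pH.
#' @param n_polyanion_chains number of polyanion chains (default 1).
#' @param monomer_ratio length-2 integer vector `c(oligocation, polyanion)`
#'   monomer ratio; default `c(1, 2)`.
#' @param ionic_strength mol/L.
#' @param pKa conjugate-acid pKa of the oligocation side chains.
#' @param polyanion_monomer_concentration mol/L of polyanion monomers; sets
#'   the box volume.
#' @param seed integer seed used by [build_system()] for the initial
#'   configuration (optional).
#' @return An object of class `"system_composition"`, including the derived
#'   `$n_oligocation_chains` and `$box_length` (nm).
#' @export
#' @examples
#' comp <- system_composition(m = 48, n = 8, pH = 10)
#' comp$n_oligocation_chains  # 3
system_composition <- function(m = 48, n = 8, pH,
                               n_polyanion_chains = 1,
                               monomer_ratio = c(1, 2),
                               ionic_strength = 0.01,
                               pKa = 10.68,
                               polyanion_monomer_concentration = 5e-3,
                               seed = NULL) {
  stopifnot(m >= 1, m == round(m), n >= 1, n == round(n),
            n_polyanion_chains >= 1,
            length(monomer_ratio) == 2L, all(monomer_ratio > 0),
            ionic_strength >= 0, is.finite(pH), is.finite(pKa),
            polyanion_monomer_concentration > 0)
  m <- as.integer(m); n <- as.integer(n)
  n_polyanion_chains <- as.integer(n_polyanion_chains)
  oligo_monomers <- m * n_polyanion_chains * monomer_ratio[1] /
    monomer_ratio[2]
  n_oligo <- oligo_monomers / n
  if (abs(oligo_monomers - round(oligo_monomers)) > 1e-9 ||
      abs(n_oligo - round(n_oligo)) > 1e-9) {
    total <- m * n_polyanion_chains * monomer_ratio[1] / monomer_ratio[2]
    divisors <- Filter(function(k) total %% k == 0, seq_len(floor(total)))
    stop(sprintf(paste0("oligocation length n = %d does not divide the ",
                        "%g oligocation monomers implied by the %d:%d ",
                        "ratio; allowed n: %s"),
                 n, total, monomer_ratio[1], monomer_ratio[2],
                 paste(divisors, collapse = ", ")), call. = FALSE)
  }
  n_oligo <- as.integer(round(n_oligo))
  n_mono_total <- m * n_polyanion_chains
  box_length <- (n_mono_total /
                   (polyanion_monomer_concentration * .NA_PER_NM3))^(1 / 3)
  structure(list(m = m, n = n, pH = pH,
                 n_polyanion_chains = n_polyanion_chains,
                 n_oligocation_chains = n_oligo,
                 monomer_ratio = monomer_ratio,
                 ionic_strength = ionic_strength,
                 pKa = pKa,
                 polyanion_monomer_concentration =
                   polyanion_monomer_concentration,
                 box_length = box_length,
                 seed = seed),
            class = "system_composition")
}

#' @export
print.system_composition <- function(x, ...) {
  cat(sprintf(paste0("System: %d polyanion chain(s) of %d monomers + %d ",
                     "oligocation chain(s) of %d monomers\n"),
              x$n_polyanion_chains, x$m, x$n_oligocation_chains, x$n))
  cat(sprintf("  pH = %g, pKa = %g, I = %g mol/L, box = %.2f nm\n",
              x$pH, x$pKa, x$ionic_strength, x$box_length))
  invisible(x)
}

# ---------------------------------------------------------------------------
# initial-configuration helpers

random_unit_vector <- function() {
  repeat {
    v <- rnorm(3)
    nv <- sqrt(sum(v^2))
    if (nv > 1e-8) return(v / nv)
  }
}

min_image_vec <- function(d, L) d - L * round(d / L)

# smallest minimum-image distance from point p to the rows of mat
min_dist_to <- function(p, mat, L) {
  if (is.null(mat) || nrow(mat) == 0L) return(Inf)
  d <- sweep(mat, 2, p)
  d <- d - L * round(d / L)
  sqrt(min(rowSums(d * d)))
}

# Self-avoiding placement of one chain (backbone random walk with fixed bond
# length, pendant side beads), avoiding `existing` coordinates.
place_chain <- function(topo, existing, L, r0, min_sep, start = NULL,
                        max_tries = 2000L) {
  n_beads <- nrow(topo$beads)
  for (attempt in seq_len(50L)) {
    pos <- matrix(NA_real_, n_beads, 3)
    origin <- if (is.null(start)) runif(3, 0, L) else start
    ok <- TRUE
    prev_bb <- NULL
    for (mono in seq_len(topo$n_monomers)) {
      ib <- 2L * mono - 1L
      is <- 2L * mono
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        bb <- if (is.null(prev_bb)) origin else
          prev_bb + r0 * random_unit_vector()
        if (min_dist_to(bb, existing, L) < min_sep) next
        if (mono > 1L &&
            min_dist_to(bb, pos[seq_len(is - 2L), , drop = FALSE], L) <
              min_sep) next
        sc <- bb + r0 * random_unit_vector()
        if (min_dist_to(sc, existing, L) < min_sep) next
        if (min_dist_to(sc, pos[seq_len(is - 2L), , drop = FALSE], L) <
              min_sep) next
        pos[ib, ] <- bb
        pos[is, ] <- sc
        prev_bb <- bb
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pos)
  }
  stop("failed to place chain without overlaps; box too crowded?",
       call. = FALSE)
}

# Random non-overlapping point positions (explicit ions).
place_points <- function(n, existing, L, min_sep, max_tries = 20000L) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  pos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      p <- runif(3, 0, L)
      if (min_dist_to(p, existing, L) < min_sep) next
      if (i > 1L &&
          min_dist_to(p, pos[seq_len(i - 1L), , drop = FALSE], L) < min_sep)
        next
      pos[i, ] <- p
      placed <- TRUE
      break
    }
    if (!placed) stop("failed to place ions without overlaps", call. = FALSE)
  }
  pos
}

#' Build an initial system state
#'
#' Places the polyanion chain(s) as self-avoiding walks, the oligocations
#' uniformly at random with overlap rejection, initializes oligocation
#' ionization states at the ideal Henderson-Hasselbalch level for the given
#' pH, and neutralizes the box exactly through counterion bookkeeping
#' (implicit counts in Debye-Hueckel mode, real particles in explicit-ion
#' mode).  A short capped steepest-descent relaxation removes any residual
#' strain so the initial energy is finite and moderate.
#'
#' @param comp a [system_composition()].
#' @param ff a [force_field()].
#' @param minimize logical; relax the initial configuration (default TRUE).
#' @return An object of class `"cg_state"`: `$positions`, `$velocities`
#'   (N x 3, nm and reduced units), `$charges`, `$topology` (per-bead table
#'   with `molecule` and `chain_kind` columns), `$box_length`,
#'   `$implicit_cations` / `$implicit_anions`, `$n_polymer_beads`.
#' @export
#' @examples
#' comp <- system_composition(m = 48, n = 8, pH = 10, seed = 1)
#' ff <- force_field()
#' st <- build_system(comp, ff)
#' total_charge(st)  # 0
build_system <- function(comp, ff, minimize = TRUE) {
  stopifnot(inherits(comp, "system_composition"),
            inherits(ff, "force_field"))
  if (!is.null(comp$seed)) set.seed(comp$seed)
  L <- comp$box_length
  contour <- (comp$m - 1) * ff$bond_r0
  if (L <= contour)
    stop(sprintf(paste0("box length %.2f nm does not exceed the polyanion ",
                        "contour length %.2f nm; lower the monomer ",
                        "concentration"), L, contour), call. = FALSE)
  explicit <- ff$electrostatics_mode == "coulomb_explicit_ions"
  min_sep <- 0.9 * ff$sigma

  chains <- c(
    replicate(comp$n_polyanion_chains,
              build_topology("polyanion", comp$m,
                             default_bead_specs("polyanion",
                                                sigma = ff$sigma)),
              simplify = FALSE),
    replicate(comp$n_oligocation_chains,
              build_topology("oligocation", comp$n,
                             default_bead_specs("oligocation", pKa = comp$pKa,
                                                sigma = ff$sigma)),
              simplify = FALSE))

  topo_list <- list()
  bond_list <- list()
  pos_list <- list()
  offset <- 0L
  existing <- NULL
  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    start <- if (ch$kind == "polyanion") rep(L / 2, 3) else NULL
    p <- place_chain(ch, existing, L, ff$bond_r0, min_sep, start = start)
    existing <- rbind(existing, p)
    b <- ch$beads
    b$molecule <- ci
    b$chain_kind <- ch$kind
    topo_list[[ci]] <- b
    bond_list[[ci]] <- ch$bonds + offset
    pos_list[[ci]] <- p
    offset <- offset + nrow(b)
  }
  topology <- do.call(rbind, topo_list)
  rownames(topology) <- NULL
  bonds <- do.call(rbind, bond_list)
  positions <- do.call(rbind, pos_list)
  n_polymer <- nrow(topology)

  # charges: polyanion side chains permanently ionized; oligocation side
  # chains Bernoulli at the ideal HH degree of ionization for this pH
  charges <- numeric(n_polymer)
  fixed <- !topology$titratable & topology$valence_when_ionized != 0
  charges[fixed] <- topology$valence_when_ionized[fixed]
  tit <- which(topology$titratable)
  a0 <- alpha_mean_field(comp$pH, comp$pKa)
  ionized0 <- rbinom(length(tit), 1L, a0) == 1L
  charges[tit] <- ifelse(ionized0, topology$valence_when_ionized[tit], 0)

  # exact electroneutrality via counterions; salt pairs from ionic strength
  V <- L^3
  n_salt <- as.integer(round(comp$ionic_strength * .NA_PER_NM3 * V))
  net <- sum(charges)
  n_cat <- n_salt + max(0L, as.integer(round(-net)))
  n_an <- n_salt + max(0L, as.integer(round(net)))

  if (explicit) {
    ion_pos <- place_points(n_cat + n_an, existing, L, min_sep)
    ion_topo <- data.frame(
      label = rep(c("CAT", "ANI"), c(n_cat, n_an)),
      role = "ion",
      valence_when_ionized = rep(c(1L, -1L), c(n_cat, n_an)),
      titratable = FALSE, pKa = NA_real_, sigma = ff$sigma,
      molecule = length(chains) + seq_len(n_cat + n_an),
      chain_kind = "ion", stringsAsFactors = FALSE)
    topology <- rbind(topology, ion_topo)
    positions <- rbind(positions, ion_pos)
    charges <- c(charges, rep(c(1, -1), c(n_cat, n_an)))
    implicit_cations <- 0L
    implicit_anions <- 0L
  } else {
    implicit_cations <- n_cat
    implicit_anions <- n_an
  }

  ffr <- resolve_ff(ff, L)
  if (minimize) {
    positions <- cpp_minimize(positions, charges,
                              bonds_for_cpp(bonds), L, ffr,
                              500L, 0.02, 50)
  }
  velocities <- matrix(rnorm(length(positions)), ncol = 3)

  state <- structure(
    list(positions = positions, velocities = velocities, charges = charges,
         topology = topology, bonds = bonds, box_length = L,
         implicit_cations = implicit_cations,
         implicit_anions = implicit_anions,
         n_polymer_beads = n_polymer,
         composition = comp),
    class = "cg_state")
  stopifnot(abs(total_charge(state)) < 1e-9)
  state
}

bonds_for_cpp <- function(bonds) {
  storage.mode(bonds) <- "integer"
  bonds - 1L
}

#' Total charge of a system state
#'
#' Sum of bead charges, explicit-ion charges and the implicit counterion
#' balance; exactly zero for any state produced by [build_system()] and
#' conserved by every constant-pH move.
#'
#' @param state a `"cg_state"`.
#' @return net charge in elementary charges.
#' @export
total_charge <- function(state) {
  stopifnot(inherits(state, "cg_state"))
  sum(state$charges) + state$implicit_cations - state$implicit_anions
}

#' @export
print.cg_state <- function(x, ...) {
  cat(sprintf("cg_state: %d beads (%d polymer), box %.2f nm, net charge %g\n",
              nrow(x$positions), x$n_polymer_beads, x$box_length,
              total_charge(x)))
  invisible(x)
}

# indices (1-based) of titratable beads
titratable_sites <- function(state) which(state$topology$titratable)
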