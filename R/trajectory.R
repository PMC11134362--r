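#' Trajectory container
#'
#' Ordered frames of bead coordinates and charges recorded by
#' [run_cph_ld()] (or generated by [generate_mixture_trajectory()]), plus
#' per-frame scalars and run metadata.  Positions are unwrapped; the cubic
#' periodic box enters all analyses through the minimum image.
#'
#' @param topology per-bead table for the polymer beads (label, role,
#'   valence_when_ionized, titratable, pKa, molecule, chain_kind).
#' @param frames list; each element has `$pos` (n x 3 matrix, possibly more
#'   rows than polymer beads in explicit-ion mode) and `$q` (charges).
#' @param scalars data frame of per-frame scalars (cycle, alpha, energy, ...).
#' @param box_length box edge, nm.
#' @param n_polymer_beads rows of `topology` present in every frame.
#' @param metadata named list (pH, pKa, force field, parameters, seed, ...).
#' @return An object of class `"cg_trajectory"`.
#' @export
new_trajectory <- function(topology, frames, scalars, box_length,
                           n_polymer_beads = nrow(topology),
                           metadata = list()) {
  stopifnot(is.data.frame(topology), is.list(frames),
            is.data.frame(scalars), box_length > 0)
  if (length(frames) == 0L)
    stop("a trajectory needs at least one frame", call. = FALSE)
  structure(list(topology = topology, frames = frames, scalars = scalars,
                 box_length = box_length,
                 n_polymer_beads = n_polymer_beads,
                 metadata = metadata),
            class = "cg_trajectory")
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf("cg_trajectory: %d frames, %d polymer beads, box %.2f nm\n",
              length(x$frames), x$n_polymer_beads, x$box_length))
  if (!is.null(x$metadata$pH))
    cat(sprintf("  pH = %g, pKa = %g\n", x$metadata$pH, x$metadata$pKa))
  if ("alpha" %in% names(x$scalars) && nrow(x$scalars) > 0)
    cat(sprintf("  mean alpha over frames: %.4f\n",
                mean(x$scalars$alpha, na.rm = TRUE)))
  invisible(x)
}

#' @export
length.cg_trajectory <- function(x) length(x$frames)

# frames x sites matrix of 0/1 ionization states of the titratable sites
ionization_matrix <- function(traj) {
  stopifnot(inherits(traj, "cg_trajectory"))
  tit <- which(traj$topology$titratable)
  t(vapply(traj$frames,
           function(fr) as.integer(fr$q[tit] != 0),
           integer(length(tit))))
}

# standard error of the mean of a (possibly autocorrelated) series by
# block averaging over >= `n_blocks` contiguous blocks
block_se <- function(series, n_blocks = 10) {
  series <- series[is.finite(series)]
  n <- length(series)
  if (n < 2) return(NA_real_)
  nb <- min(n_blocks, n)
  idx <- cut(seq_len(n), breaks = nb, labels = FALSE)
  bm <- tapply(series, idx, mean)
  stats::sd(bm) / sqrt(nb)
}
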