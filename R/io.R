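#' Write a trajectory to disk
#'
#' Writes extended-XYZ frames (per-atom columns: species label, x, y, z,
#' charge, ionization flag; comment line with `Lattice`, `Properties` and
#' frame metadata) plus sidecar files: `scalars.csv` (per-frame scalars),
#' `topology.csv` (per-bead table) and `meta.yaml` (box, pH, parameters).
#' Positions are written with 1e-6 nm precision; the round trip through
#' [read_trajectory()] is lossless to that precision.
#'
#' @param traj a `"cg_trajectory"`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written (named character vector).
#' @export
write_trajectory <- function(traj, dir) {
  stopifnot(inherits(traj, "cg_trajectory"))
  if (length(traj$frames) == 0L)
    stop("refusing to write an empty trajectory", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  L <- traj$box_length
  labels_poly <- traj$topology$label
  lines <- vector("list", length(traj$frames))
  for (fi in seq_along(traj$frames)) {
    fr <- traj$frames[[fi]]
    n <- nrow(fr$pos)
    lab <- c(labels_poly,
             ifelse(fr$q[-seq_len(traj$n_polymer_beads)] > 0, "CAT",
                    "ANI"))[seq_len(n)]
    header <- sprintf(
      paste0('Lattice="%.6f 0.0 0.0 0.0 %.6f 0.0 0.0 0.0 %.6f" ',
             'Properties=species:S:1:pos:R:3:charge:R:1:ionization:I:1 ',
             'frame=%d pH=%g'),
      L, L, L, fi, traj$metadata$pH %||% NA)
    rows <- sprintf("%s %.6f %.6f %.6f %g %d",
                    lab, fr$pos[, 1], fr$pos[, 2], fr$pos[, 3],
                    fr$q, as.integer(fr$q != 0))
    lines[[fi]] <- c(as.character(n), header, rows)
  }
  xyz_path <- file.path(dir, "trajectory.extxyz")
  writeLines(unlist(lines), xyz_path)

  scalars_path <- file.path(dir, "scalars.csv")
  write.csv(traj$scalars, scalars_path, row.names = FALSE)
  topo_path <- file.path(dir, "topology.csv")
  write.csv(traj$topology, topo_path, row.names = FALSE)
  meta_path <- file.path(dir, "meta.yaml")
  md <- traj$metadata
  md$final_state <- NULL
  md$composition <- NULL
  md$fixture_spec <- NULL
  yaml::write_yaml(c(list(box_length = L,
                          n_polymer_beads = traj$n_polymer_beads),
                     md), meta_path)
  invisible(c(trajectory = xyz_path, scalars = scalars_path,
              topology = topo_path, meta = meta_path))
}

parse_extxyz <- function(path, default_box = NULL) {
  txt <- readLines(path)
  if (length(txt) == 0L) stop("empty trajectory file: ", path, call. = FALSE)
  frames <- list()
  boxes <- numeric(0)
  i <- 1L
  warned_ion <- FALSE
  while (i <= length(txt)) {
    if (!nzchar(trimws(txt[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(txt[i])))
    if (is.na(n) || n < 1)
      stop(sprintf("malformed frame header at line %d of %s", i, path),
           call. = FALSE)
    if (i + 1L + n > length(txt))
      stop(sprintf("truncated frame starting at line %d of %s", i, path),
           call. = FALSE)
    header <- txt[i + 1L]
    lat <- regmatches(header,
                      regexpr('Lattice="[^"]*"', header))
    box <- if (length(lat) == 1L) {
      v <- as.numeric(strsplit(gsub('Lattice="|"', "", lat), "\\s+")[[1]])
      v[1]
    } else default_box
    has_ion <- grepl("ionization", header, fixed = TRUE)
    rows <- txt[i + 1L + seq_len(n)]
    parts <- strsplit(trimws(rows), "\\s+")
    ncol_row <- lengths(parts)
    if (any(ncol_row < 4))
      stop(sprintf("malformed atom line at line %d of %s",
                   i + 1L + which(ncol_row < 4)[1], path), call. = FALSE)
    lab <- vapply(parts, `[[`, character(1), 1L)
    num <- function(k) vapply(parts, function(p)
      suppressWarnings(as.numeric(p[k])), numeric(1))
    pos <- cbind(num(2), num(3), num(4))
    if (any(!is.finite(pos)))
      stop(sprintf("non-numeric coordinates in frame starting at line %d ",
                   i), call. = FALSE)
    q <- if (all(ncol_row >= 5)) num(5) else rep(0, n)
    ion <- if (has_ion && all(ncol_row >= 6)) as.integer(num(6)) else NULL
    if (is.null(ion)) {
      if (!warned_ion) {
        warning("no ionization column; flags defaulted to charge != 0",
                call. = FALSE)
        warned_ion <- TRUE
      }
      ion <- as.integer(q != 0)
    }
    frames[[length(frames) + 1L]] <- list(pos = pos, q = q,
                                          labels = lab, ionization = ion)
    boxes <- c(boxes, box %||% NA_real_)
    i <- i + 2L + n
  }
  list(frames = frames, box = boxes)
}

#' Read a trajectory from disk
#'
#' Reads a directory written by [write_trajectory()] (extended-XYZ plus
#' sidecars), or a bare extended-XYZ file.  For foreign extended-XYZ files
#' without the ionization column, flags default to `charge != 0` with a
#' warning, and a minimal topology is inferred from the species labels of
#' the first frame.
#'
#' @param path directory (or single `.extxyz` file).
#' @return a `"cg_trajectory"`.
#' @export
read_trajectory <- function(path) {
  if (dir.exists(path)) {
    xyz <- file.path(path, "trajectory.extxyz")
    meta <- yaml::read_yaml(file.path(path, "meta.yaml"))
    topology <- read.csv(file.path(path, "topology.csv"),
                         stringsAsFactors = FALSE)
    scalars <- read.csv(file.path(path, "scalars.csv"))
    parsed <- parse_extxyz(xyz, default_box = meta$box_length)
    frames <- lapply(parsed$frames, function(fr)
      list(pos = fr$pos, q = fr$q))
    meta_rest <- meta[setdiff(names(meta),
                              c("box_length", "n_polymer_beads"))]
    return(new_trajectory(topology, frames, scalars,
                          meta$box_length, meta$n_polymer_beads,
                          metadata = meta_rest))
  }
  if (!file.exists(path)) stop("no such trajectory: ", path, call. = FALSE)
  parsed <- parse_extxyz(path)
  fr1 <- parsed$frames[[1]]
  box <- parsed$box[1]
  if (!is.finite(box)) {
    warning("no Lattice information; box length set from coordinate span",
            call. = FALSE)
    box <- max(fr1$pos) - min(fr1$pos) + 1
  }
  known_kind <- c(PAB = "polyanion", PAS = "polyanion",
                  OLB = "oligocation", OLS = "oligocation",
                  CAT = "ion", ANI = "ion")
  kind <- unname(known_kind[fr1$labels])
  kind[is.na(kind)] <- "unknown"
  topology <- data.frame(
    label = fr1$labels, role = "unknown",
    valence_when_ionized = as.integer(sign(fr1$q)),
    titratable = fr1$labels == "OLS",
    pKa = NA_real_, sigma = NA_real_,
    molecule = NA_integer_, chain_kind = kind,
    stringsAsFactors = FALSE)
  frames <- lapply(parsed$frames, function(fr) list(pos = fr$pos, q = fr$q))
  scalars <- data.frame(cycle = seq_along(frames))
  new_trajectory(topology, frames, scalars, box, nrow(topology),
                 metadata = list(source = path))
}
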