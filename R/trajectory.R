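#' Trajectory ensemble container
#'
#' Bundles one shared [topology()] with one or more coordinate trajectories
#' sampled at a uniform frame interval.  Coordinates are always in nanometres;
#' readers convert from the Angstrom-based formats (PDB, DCD).
#'
#' @param topology a [topology()] object.
#' @param coords list of numeric arrays, one per trajectory, each of dimension
#'   `n_frames x n_atoms x 3` (nm).
#' @param frame_interval time between consecutive frames, in picoseconds.
#' @return An object of class `"traj_ensemble"`.
#' @export
traj_ensemble <- function(topology, coords, frame_interval) {
  if (!inherits(topology, "topology")) stop2("topology must be a topology object")
  if (!is.list(coords) || length(coords) == 0L)
    stop2("coords must be a non-empty list of n_frames x n_atoms x 3 arrays")
  for (t in seq_along(coords)) {
    d <- dim(coords[[t]])
    if (length(d) != 3L || d[3L] != 3L)
      stop2("trajectory ", t, " is not an n_frames x n_atoms x 3 array")
    if (d[2L] != topology$n_atoms)
      stop2("trajectory ", t, " has ", d[2L], " atoms; topology has ",
            topology$n_atoms)
  }
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop2("frame_interval must be a positive time in ps")
  structure(list(topology = topology, coords = coords,
                 frame_interval = frame_interval),
            class = "traj_ensemble")
}

#' @export
print.traj_ensemble <- function(x, ...) {
  nf <- vapply(x$coords, function(a) dim(a)[1L], integer(1))
  cat("traj_ensemble:", length(x$coords), "trajectories,",
      sum(nf), "frames total (", paste(nf, collapse = ", "), "),",
      x$topology$n_atoms, "atoms, frame interval", x$frame_interval, "ps\n")
  invisible(x)
}

n_frames <- function(ensemble) {
  vapply(ensemble$coords, function(a) dim(a)[1L], integer(1))
}

# One frame as an n_atoms x 3 matrix.
frame_coords <- function(ensemble, traj, frame) {
  a <- ensemble$coords[[traj]]
  matrix(a[frame, , ], ncol = 3L)
}

#' Write an ensemble to disk as plain-text files
#'
#' The topology goes to a PDB file (via \pkg{bio3d}; coordinates of the first
#' frame, in Angstrom).  Each trajectory goes to a CSV file with columns
#' `frame`, `atom`, `x`, `y`, `z` (nm).  The formats round-trip through
#' [read_ensemble()].
#'
#' @param ensemble a [traj_ensemble()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix for the trajectory CSVs.
#' @return Invisibly, a list with `topology` (PDB path) and `trajectories`
#'   (CSV paths).
#' @export
write_ensemble <- function(ensemble, dir, prefix = "traj") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  top <- ensemble$topology
  pdb_path <- file.path(dir, "topology.pdb")
  xyz0 <- as.numeric(t(frame_coords(ensemble, 1L, 1L))) * 10  # nm -> Angstrom
  bio3d::write.pdb(file = pdb_path, xyz = xyz0,
                   chain = top$atoms$chain, resno = top$atoms$resno,
                   resid = top$atoms$resname, elety = top$atoms$name,
                   elesy = top$atoms$elem)
  paths <- character(length(ensemble$coords))
  for (t in seq_along(ensemble$coords)) {
    a <- ensemble$coords[[t]]
    nf <- dim(a)[1L]; na <- dim(a)[2L]
    df <- data.frame(frame = rep(seq_len(nf), each = na),
                     atom = rep(seq_len(na), times = nf),
                     x = as.numeric(t(a[, , 1L])),
                     y = as.numeric(t(a[, , 2L])),
                     z = as.numeric(t(a[, , 3L])))
    paths[t] <- file.path(dir, sprintf("%s_%d.csv", prefix, t))
    utils::write.csv(df, paths[t], row.names = FALSE)
  }
  invisible(list(topology = pdb_path, trajectories = paths))
}

read_topology_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  chain <- a$chain
  chain[is.na(chain) | chain == ""] <- "A"
  topology(data.frame(chain = chain, resno = a$resno, resname = a$resid,
                      name = a$elety, elem = a$elesy,
                      stringsAsFactors = FALSE))
}

read_traj_csv <- function(path, n_atoms) {
  df <- utils::read.csv(path)
  if (!all(c("frame", "atom", "x", "y", "z") %in% names(df)))
    stop2("trajectory CSV ", path, " must have columns frame, atom, x, y, z")
  frames <- sort(unique(df$frame))
  cnt <- table(df$frame)
  bad <- names(cnt)[cnt != n_atoms]
  if (length(bad) > 0L)
    stop2("atom-count mismatch in ", path, " at frame ", bad[1L], ": ",
          cnt[bad[1L]], " atoms, expected ", n_atoms)
  df <- df[order(df$frame, df$atom), ]
  nf <- length(frames)
  arr <- array(NA_real_, c(nf, n_atoms, 3L))
  arr[, , 1L] <- matrix(df$x, nrow = nf, byrow = TRUE)
  arr[, , 2L] <- matrix(df$y, nrow = nf, byrow = TRUE)
  arr[, , 3L] <- matrix(df$z, nrow = nf, byrow = TRUE)
  arr
}

xyz_to_array <- function(xyz, n_atoms, scale) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * n_atoms)
    stop2("coordinate record has ", ncol(xyz) / 3, " atoms, expected ", n_atoms)
  nf <- nrow(xyz)
  arr <- array(NA_real_, c(nf, n_atoms, 3L))
  arr[, , 1L] <- xyz[, seq(1L, 3L * n_atoms, by = 3L), drop = FALSE] * scale
  arr[, , 2L] <- xyz[, seq(2L, 3L * n_atoms, by = 3L), drop = FALSE] * scale
  arr[, , 3L] <- xyz[, seq(3L, 3L * n_atoms, by = 3L), drop = FALSE] * scale
  arr
}

#' Read a trajectory ensemble from disk
#'
#' @param topology_path PDB file defining the shared topology.
#' @param trajectory_paths character vector of coordinate files; `.csv`
#'   (columns `frame`, `atom`, `x`, `y`, `z`, nm), `.dcd` (Angstrom, read via
#'   \pkg{bio3d}) and multi-model `.pdb` are supported.  When empty, the
#'   topology PDB's own model(s) form a single trajectory.
#' @param frame_interval frame spacing in ps.
#' @return A [traj_ensemble()], coordinates in nm.
#' @export
read_ensemble <- function(topology_path, trajectory_paths = character(),
                          frame_interval = 10) {
  top <- read_topology_pdb(topology_path)
  coords <- list()
  if (length(trajectory_paths) == 0L) {
    pdb <- bio3d::read.pdb(topology_path, multi = TRUE, verbose = FALSE)
    coords[[1L]] <- xyz_to_array(pdb$xyz, top$n_atoms, 0.1)
  } else {
    for (p in trajectory_paths) {
      ext <- tolower(tools::file_ext(p))
      coords[[length(coords) + 1L]] <- switch(
        ext,
        csv = read_traj_csv(p, top$n_atoms),
        dcd = xyz_to_array(bio3d::read.dcd(p, verbose = FALSE), top$n_atoms, 0.1),
        pdb = xyz_to_array(bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)$xyz,
                           top$n_atoms, 0.1),
        stop2("unreadable trajectory format: .", ext, " (", p, ")")
      )
    }
  }
  traj_ensemble(top, coords, frame_interval)
}

#' Pairwise C-alpha distance features
#'
#' Computes, for every frame, the Euclidean distances between the alpha
#' carbons of a residue selection.  These distances are the input features of
#' the slow-mode analysis ([fit_ivac()]): for `n` selected residues there are
#' `n(n-1)/2` feature columns, ordered lexicographically by residue pair
#' (chain letter, then residue number).
#'
#' @param ensemble a [traj_ensemble()].
#' @param residue_selection data frame with columns `chain` and `resno`, or a
#'   character vector of site labels like `"A1"`.
#' @return A `"feature_matrix"`: list with `values` (total frames x d matrix,
#'   nm), `labels` (pair labels like `"A1-A6"`), and `boundaries` (frames per
#'   trajectory, in order).
#' @export
pairwise_ca_distances <- function(ensemble, residue_selection) {
  sel <- parse_selection(residue_selection)
  # lexicographic order of (chain, residue number)
  sel <- sel[order(sel$chain, sel$resno), , drop = FALSE]
  n <- nrow(sel)
  if (n < 2L) stop2("need at least two residues for pairwise distances")
  idx <- ca_indices(ensemble$topology, sel$chain, sel$resno)
  labs <- site_label(sel$chain, sel$resno)
  pairs <- utils::combn(n, 2L)
  d <- ncol(pairs)
  col_labels <- paste0(labs[pairs[1L, ]], "-", labs[pairs[2L, ]])

  nf <- n_frames(ensemble)
  values <- matrix(NA_real_, nrow = sum(nf), ncol = d)
  off <- 0L
  for (t in seq_along(ensemble$coords)) {
    a <- ensemble$coords[[t]]
    rows <- off + seq_len(nf[t])
    for (p in seq_len(d)) {
      i <- idx[pairs[1L, p]]; j <- idx[pairs[2L, p]]
      dx <- a[, i, 1L] - a[, j, 1L]
      dy <- a[, i, 2L] - a[, j, 2L]
      dz <- a[, i, 3L] - a[, j, 3L]
      values[rows, p] <- sqrt(dx * dx + dy * dy + dz * dz)
    }
    off <- off + nf[t]
  }
  structure(list(values = values, labels = col_labels, boundaries = nf),
            class = "feature_matrix")
}

parse_selection <- function(residue_selection) {
  if (is.character(residue_selection)) {
    m <- regmatches(residue_selection,
                    regexec("^([A-Za-z]+)([0-9]+)$", residue_selection))
    bad <- vapply(m, length, integer(1)) != 3L
    if (any(bad))
      stop2("cannot parse site label(s): ",
            paste(residue_selection[bad], collapse = ", "))
    data.frame(chain = vapply(m, `[`, "", 2L),
               resno = as.integer(vapply(m, `[`, "", 3L)),
               stringsAsFactors = FALSE)
  } else if (is.data.frame(residue_selection)) {
    if (!all(c("chain", "resno") %in% names(residue_selection)))
      stop2("residue_selection needs columns chain and resno")
    data.frame(chain = as.character(residue_selection$chain),
               resno = as.integer(residue_selection$resno),
               stringsAsFactors = FALSE)
  } else stop2("residue_selection must be a data frame or character vector")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$values), "frames x", ncol(x$values),
      "distances,", length(x$boundaries), "trajectories\n")
  invisible(x)
}

# Accept a feature_matrix or a list of them; return one combined.
combine_features <- function(features) {
  if (inherits(features, "feature_matrix")) return(features)
  if (is.list(features) && all(vapply(features, inherits, TRUE, "feature_matrix"))) {
    labs <- features[[1L]]$labels
    for (f in features) if (!identical(f$labels, labs))
      stop2("feature matrices have different feature labels")
    return(structure(list(
      values = do.call(rbind, lapply(features, `[[`, "values")),
      labels = labs,
      boundaries = unlist(lapply(features, `[[`, "boundaries"))),
      class = "feature_matrix"))
  }
  stop2("features must be a feature_matrix or a list of feature_matrix objects")
}
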