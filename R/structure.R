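#' channelgauge: structural analysis of ion-channel simulation ensembles
#'
#' Tools for analysing molecular-dynamics ensembles of tetrameric ion
#' channels: pore-radius profiling, superposition/RMSD/RMSF, average-linkage
#' conformational clustering, hydrogen-bond based helix assignment,
#' center-of-mass domain angles, solvent accessibility of linear motifs,
#' accelerated-MD boost-potential mathematics, and synthetic channel-like
#' trajectory generators with ground-truth manifests.
#'
#' @docType package
#' @name channelgauge
#' @keywords internal
"_PACKAGE"

.cg_env <- new.env(parent = emptyenv())

#' Element property table (van der Waals radii and masses)
#'
#' Returns the packaged element table used to assign per-atom van der
#' Waals radii (Bondi set: C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 A)
#' and atomic masses.  A user table with the same columns
#' (`element`, `vdw_radius`, `mass`) may be supplied to any reader.
#'
#' @param path optional path to a CSV with columns `element`,
#'   `vdw_radius`, `mass`; defaults to the packaged table.
#' @return data.frame with one row per element symbol (upper case).
#' @export
element_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.cg_env$elements)) return(.cg_env$elements)
    path <- system.file("extdata", "element_properties.csv",
                        package = "channelgauge", mustWork = TRUE)
    tab <- utils::read.csv(path, colClasses = c("character", "numeric", "numeric"),
                           na.strings = character())
    tab$element <- toupper(tab$element)
    .cg_env$elements <- tab
    return(tab)
  }
  tab <- utils::read.csv(path, colClasses = c("character", "numeric", "numeric"),
                         na.strings = character())
  tab$element <- toupper(tab$element)
  tab
}

#' Construct a molecular structure
#'
#' The central container: an ordered atom table with coordinates (in
#' Angstrom), van der Waals radii and masses.  Atom identity is the
#' triple (chain, residue id, atom name), which must be unique, and
#' residues within a chain must appear in non-decreasing `resid` order.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`, `x`, `y`, `z`, `vdw`, `mass`.
#' @return an object of class `cg_structure`.
#' @export
cg_structure <- function(atoms) {
  req <- c("serial", "name", "element", "resname", "resid", "chain",
           "x", "y", "z", "vdw", "mass")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atoms table is missing columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms[, req], stringsAsFactors = FALSE)
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z) ||
      !all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z)))
    stop("coordinates must be finite")
  if (any(atoms$vdw <= 0)) stop("vdw_radius must be > 0 for every atom")
  if (any(atoms$mass <= 0)) stop("mass must be > 0 for every atom")
  key <- paste(atoms$chain, atoms$resid, atoms$name, sep = "|")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate atom identity (chain|resid|name): ", d)
  }
  for (ch in unique(atoms$chain)) {
    r <- atoms$resid[atoms$chain == ch]
    if (is.unsorted(r)) stop("residues out of order in chain ", ch)
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "cg_structure")
}

#' Number of atoms in a structure or trajectory
#' @param x a `cg_structure` or `cg_trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) UseMethod("n_atoms")

#' @export
n_atoms.cg_structure <- function(x) nrow(x$atoms)

#' @export
n_atoms.cg_trajectory <- function(x) nrow(x$topology$atoms)

#' Coordinates of a structure as an n x 3 matrix (Angstrom)
#' @param x a `cg_structure`.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(x) UseMethod("coords")

#' @export
coords.cg_structure <- function(x)
  cbind(x = x$atoms$x, y = x$atoms$y, z = x$atoms$z)

#' Replace the coordinates of a structure
#' @param x a `cg_structure`.
#' @param value n x 3 numeric matrix.
#' @return the modified structure.
#' @export
`coords<-` <- function(x, value) {
  stopifnot(inherits(x, "cg_structure"))
  value <- as.matrix(value)
  if (nrow(value) != n_atoms(x) || ncol(value) != 3L)
    stop("replacement coordinates must be ", n_atoms(x), " x 3")
  x$atoms$x <- value[, 1L]
  x$atoms$y <- value[, 2L]
  x$atoms$z <- value[, 3L]
  x
}

#' @export
print.cg_structure <- function(x, ...) {
  a <- x$atoms
  cat("cg_structure:", nrow(a), "atoms,",
      length(unique(a$chain)), "chain(s) [",
      paste(unique(a$chain), collapse = " "), "]\n")
  invisible(x)
}

#' Construct a trajectory
#'
#' Frames share one topology.  Coordinates are stored as a frames x (3 *
#' n_atoms) matrix in the `x1 y1 z1 x2 ...` layout used throughout the
#' MD-analysis ecosystem, so individual frames are cheap to extract.
#'
#' @param topology a `cg_structure`.
#' @param xyz numeric matrix, one row per frame, `3 * n_atoms` columns; or
#'   a list of n_atoms x 3 matrices.
#' @param frame_interval_ns time between stored frames in nanoseconds
#'   (default 0.01, i.e. one snapshot every 10 ps).
#' @return an object of class `cg_trajectory`.
#' @export
cg_trajectory <- function(topology, xyz, frame_interval_ns = 0.01) {
  stopifnot(inherits(topology, "cg_structure"))
  if (is.list(xyz) && !is.matrix(xyz))
    xyz <- do.call(rbind, lapply(xyz, function(m) as.numeric(t(m))))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * n_atoms(topology))
    stop("frame width ", ncol(xyz), " does not match 3 * n_atoms = ",
         3L * n_atoms(topology))
  if (!is.numeric(frame_interval_ns) || frame_interval_ns <= 0)
    stop("frame_interval_ns must be > 0")
  structure(list(topology = topology, xyz = xyz,
                 frame_interval_ns = frame_interval_ns),
            class = "cg_trajectory")
}

#' Number of frames in a trajectory
#' @param traj a `cg_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "cg_trajectory"))
  nrow(traj$xyz)
}

#' Extract one frame of a trajectory as an n x 3 coordinate matrix
#' @param traj a `cg_trajectory`.
#' @param i frame index (1-based).
#' @return n_atoms x 3 numeric matrix.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(inherits(traj, "cg_trajectory"))
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Extract one frame of a trajectory as a structure
#' @param traj a `cg_trajectory`.
#' @param i frame index (1-based).
#' @return `cg_structure` with the topology's atom table and frame i coordinates.
#' @export
frame_structure <- function(traj, i) {
  s <- traj$topology
  coords(s) <- frame_coords(traj, i)
  s
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("cg_trajectory:", n_frames(x), "frames x", n_atoms(x), "atoms,",
      "interval", x$frame_interval_ns, "ns\n")
  invisible(x)
}

#' Times (ns) of the frames of a trajectory
#' @param traj a `cg_trajectory`.
#' @return numeric vector, `frame_interval_ns * (0:(n-1))`.
#' @export
frame_times <- function(traj) {
  traj$frame_interval_ns * (seq_len(n_frames(traj)) - 1L)
}
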