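#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records (via bio3d), collapses alternate locations
#' to the highest-occupancy copy, and assigns van der Waals radii and
#' masses from an element table.  The element is taken from the PDB
#' element column when present, otherwise inferred from the atom name.
#'
#' @param path PDB file.
#' @param elements element table (see [element_table()]).
#' @param model model number to extract from a multi-model file (default 1).
#' @return a [cg_structure()].
#' @export
read_structure <- function(path, elements = element_table(), model = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  .validate_pdb_text(path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = model > 1L, verbose = FALSE)),
    error = function(e) stop("cannot parse PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (model > 1L) {
    xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
    at$x <- xyz[, 1L]; at$y <- xyz[, 2L]; at$z <- xyz[, 3L]
  }
  .atoms_from_bio3d(at, elements, path)
}

# Light line-level validation so malformed records fail with a line number
# instead of a downstream reshape error.
.validate_pdb_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54L)
      stop("malformed PDB record at line ", i, " (too short): ", ln)
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop("malformed PDB record at line ", i, " (bad coordinates)")
  }
  invisible(TRUE)
}

.atoms_from_bio3d <- function(at, elements, path) {
  # collapse altlocs: keep the highest-occupancy copy of each atom identity
  alt <- at$alt
  if (!is.null(alt) && any(!is.na(alt) & alt != "")) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$chain, at$resno, at$elety, sep = "|")
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
      idx[which.max(occ[idx])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  ele <- at$elesy
  if (is.null(ele)) ele <- rep(NA_character_, nrow(at))
  bad <- is.na(ele) | ele == ""
  if (any(bad))
    ele[bad] <- suppressWarnings(bio3d::atom2ele(at$elety[bad]))
  ele <- toupper(trimws(ele))
  hit <- match(ele, elements$element)
  if (anyNA(hit)) {
    i <- which(is.na(hit))[1L]
    stop("unknown element '", ele[i], "' for atom ", at$elety[i],
         " (residue ", at$resid[i], " ", at$resno[i], ", chain ",
         at$chain[i], ") in ", path)
  }
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- "A"
  cg_structure(data.frame(
    serial = at$eleno, name = at$elety, element = ele,
    resname = at$resid, resid = at$resno, chain = chain,
    x = at$x, y = at$y, z = at$z,
    vdw = elements$vdw_radius[hit], mass = elements$mass[hit],
    stringsAsFactors = FALSE))
}

#' Write a structure to a PDB file
#' @param s a `cg_structure`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "cg_structure"))
  a <- s$atoms
  bio3d::write.pdb(file = path, xyz = as.numeric(t(coords(s))),
                   resno = a$resid, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   elesy = a$element)
  invisible(path)
}

#' Read a trajectory from a DCD file or a multi-model PDB
#'
#' The file format is chosen by extension (`.dcd` binary, anything else
#' is treated as multi-model PDB with MODEL/ENDMDL delimiting frames).
#' The frame atom count must equal the topology atom count.
#'
#' @param path trajectory file.
#' @param topology a `cg_structure` providing the atom table.
#' @param frame_interval_ns time between snapshots in ns (default 0.01).
#' @return a [cg_trajectory()].
#' @export
read_trajectory <- function(path, topology, frame_interval_ns = 0.01) {
  stopifnot(inherits(topology, "cg_structure"))
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    xyz <- tryCatch(suppressMessages(bio3d::read.dcd(path, verbose = FALSE)),
                    error = function(e) stop("cannot read DCD ", path, ": ",
                                             conditionMessage(e), call. = FALSE))
    xyz <- unclass(xyz)
  } else {
    xyz <- .read_multimodel_pdb(path)
  }
  if (anyNA(xyz)) stop("trajectory ", path, " contains missing coordinates ",
                       "(truncated file?)")
  if (ncol(xyz) != 3L * n_atoms(topology))
    stop("atom-count mismatch: trajectory has ", ncol(xyz) / 3,
         " atoms per frame, topology has ", n_atoms(topology))
  cg_trajectory(topology, xyz, frame_interval_ns)
}

.read_multimodel_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) {            # single-model file: one frame
    s <- read_structure(path)
    return(matrix(as.numeric(t(coords(s))), nrow = 1L))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts))
    stop("truncated multi-model PDB ", path, ": ", length(starts),
         " MODEL records but ", length(ends), " ENDMDL records")
  frames <- vector("list", length(starts))
  n_ref <- NA_integer_
  for (k in seq_along(starts)) {
    block <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    rec <- block[grepl("^(ATOM  |HETATM)", block)]
    if (is.na(n_ref)) n_ref <- length(rec)
    if (length(rec) != n_ref)
      stop("truncated multi-model PDB ", path, ": model ", k, " has ",
           length(rec), " atoms, expected ", n_ref)
    xyz <- cbind(as.numeric(substr(rec, 31, 38)),
                 as.numeric(substr(rec, 39, 46)),
                 as.numeric(substr(rec, 47, 54)))
    frames[[k]] <- as.numeric(t(xyz))
  }
  do.call(rbind, frames)
}

#' Write a trajectory
#'
#' Multi-model PDB (MODEL/ENDMDL per frame) is the canonical text dialect;
#' DCD (CHARMM/X-PLOR, 32-bit) the binary one.  Chosen by `format` or by
#' the path extension.
#'
#' @param traj a `cg_trajectory`.
#' @param path output file.
#' @param format "pdb" or "dcd"; default inferred from `path`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path,
                             format = if (grepl("\\.dcd$", path,
                                                ignore.case = TRUE)) "dcd" else "pdb") {
  stopifnot(inherits(traj, "cg_trajectory"))
  format <- match.arg(format, c("pdb", "dcd"))
  if (format == "dcd") return(.write_dcd(traj$xyz, path))
  a <- traj$topology$atoms
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (i in seq_len(n_frames(traj))) {
    bio3d::write.pdb(file = tmp, xyz = traj$xyz[i, ],
                     resno = a$resid, resid = a$resname, eleno = a$serial,
                     elety = a$name, chain = a$chain,
                     o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                     elesy = a$element)
    body <- readLines(tmp, warn = FALSE)
    body <- body[!grepl("^END", body)]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(body, con)
    writeLines(c("TER", "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

# Minimal CHARMM-dialect DCD encoder (32-bit Fortran records); the reader
# side is bio3d::read.dcd, which also serves as an independent check on
# the byte layout.
.write_dcd <- function(xyz, path) {
  natom <- ncol(xyz) / 3L
  nframes <- nrow(xyz)
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x) writeBin(as.integer(x), con, size = 4L,
                               endian = .Platform$endian)
  # header record: "CORD" + 20 control integers (CHARMM version slot = 24)
  wint(84L)
  writeBin(charToRaw("CORD"), con)
  wint(c(nframes, 0L, 1L, nframes, 0L, 0L, 0L, 0L, 0L))
  writeBin(1.0, con, size = 4L, endian = .Platform$endian)   # delta (AKMA)
  wint(c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 24L))
  wint(84L)
  title <- formatC("written by channelgauge", width = -80L)
  wint(84L); wint(1L); writeBin(charToRaw(title), con); wint(84L)
  wint(4L); wint(natom); wint(4L)
  for (i in seq_len(nframes)) {
    fr <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
    for (d in 1:3) {
      wint(4L * natom)
      writeBin(as.numeric(fr[, d]), con, size = 4L,
               endian = .Platform$endian)
      wint(4L * natom)
    }
  }
  invisible(path)
}
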