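#' Shrake-Rupley solvent-accessible surface area
#'
#' Deterministic golden-spiral (Fibonacci) points on each atom's solvent
#' sphere of radius `r + probe`; a point is accessible when it lies
#' outside every neighbour's solvent sphere.  Per-atom SASA is
#' `4 * pi * (r + probe)^2` times the accessible fraction.
#'
#' @param frame a `cg_structure`, or a list with `xyz` (n x 3) and
#'   `radii`.
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sphere points per atom (>= 92; default 92).
#' @param subset optional atom indices to compute SASA for (occlusion
#'   still uses all atoms).
#' @return numeric vector of per-atom SASA (A^2) for `subset` (or all
#'   atoms).
#' @export
sasa <- function(frame, probe = 1.4, n_points = 92L, subset = NULL) {
  if (n_points < 92L) stop("n_points must be >= 92")
  if (inherits(frame, "cg_structure")) {
    xyz <- coords(frame); radii <- frame$atoms$vdw
  } else {
    xyz <- as.matrix(frame$xyz); radii <- frame$radii
  }
  n <- nrow(xyz)
  if (is.null(subset)) subset <- seq_len(n)
  pts <- .golden_spiral(n_points)
  rs <- radii + probe
  out <- numeric(length(subset))
  maxr <- max(rs)
  for (k in seq_along(subset)) {
    i <- subset[k]
    d2 <- (xyz[, 1L] - xyz[i, 1L])^2 + (xyz[, 2L] - xyz[i, 2L])^2 +
      (xyz[, 3L] - xyz[i, 3L])^2
    nb <- which(d2 < (rs[i] + rs)^2 & seq_len(n) != i)
    if (length(nb) == 0L) {
      out[k] <- 4 * pi * rs[i]^2
      next
    }
    sp <- sweep(pts * rs[i], 2L, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (sp[, 1L] - xyz[j, 1L])^2 + (sp[, 2L] - xyz[j, 2L])^2 +
        (sp[, 3L] - xyz[j, 3L])^2
      acc <- acc & dj2 >= rs[j]^2
      if (!any(acc)) break
    }
    out[k] <- 4 * pi * rs[i]^2 * mean(acc)
  }
  out
}

.golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Linear-motif definition
#' @param id motif identifier.
#' @param chain chain the motif lives on (NULL = every chain).
#' @param res_range inclusive residue range `c(lo, hi)`.
#' @param class motif class, `"KFERQ-related"` or `"tyrosine-based"`.
#' @return object of class `cg_motif`.
#' @export
cg_motif <- function(id, chain = NULL, res_range,
                     class = c("KFERQ-related", "tyrosine-based")) {
  class <- match.arg(class)
  if (length(res_range) != 2L || res_range[2L] < res_range[1L])
    stop("invalid motif res_range")
  structure(list(id = id, chain = chain, res_range = res_range,
                 class = class), class = "cg_motif")
}

#' Built-in hERG internalization-signal motifs
#'
#' The four linear sorting signals of the hERG intracellular domains:
#' the KFERQ-related chaperone-mediated-autophagy signal K21-Q25 and
#' the tyrosine-based signal Y54-A57 in the PAS domain, and the
#' tyrosine-based signals Y827-L830 and Y845-F848 in the CNBD.
#' Residue numbers follow hERG (Kv11.1) numbering.
#'
#' @return list of four [cg_motif()] objects.
#' @export
builtin_herg_motifs <- function() {
  list(cg_motif("K21-Q25", NULL, c(21L, 25L), "KFERQ-related"),
       cg_motif("Y54-A57", NULL, c(54L, 57L), "tyrosine-based"),
       cg_motif("Y827-L830", NULL, c(827L, 830L), "tyrosine-based"),
       cg_motif("Y845-F848", NULL, c(845L, 848L), "tyrosine-based"))
}

#' Motif exposure over a trajectory
#'
#' The motif SASA per frame (sum over its residues' atoms, occlusion by
#' every non-excluded atom) normalised by the same residues' SASA in a
#' generated extended conformation — so `relative` is 1 for a fully
#' solvent-exposed motif and near 0 for one buried at a domain
#' interface.  A frame is `exposed` when `relative > threshold`.
#'
#' @param traj a `cg_trajectory`.
#' @param motif a [cg_motif()].
#' @param threshold relative-exposure threshold (default 0.25).
#' @param probe,n_points passed to [sasa()].
#' @param exclude optional selection of atoms (e.g. membrane lipids)
#'   removed from the occluder set.
#' @return object of class `cg_motif_exposure`: data.frame `frame`,
#'   `time_ns`, `sasa_A2`, `relative`, `exposed`; attributes `motif`,
#'   `reference_sasa`, `exposed_fraction`.
#' @export
motif_exposure <- function(traj, motif, threshold = 0.25, probe = 1.4,
                           n_points = 92L, exclude = NULL) {
  stopifnot(inherits(traj, "cg_trajectory"), inherits(motif, "cg_motif"))
  top <- traj$topology
  msel <- cg_selection(chains = motif$chain, res_range = motif$res_range)
  midx <- suppressWarnings(resolve_selection(top, msel))
  if (length(midx) == 0L)
    stop("motif ", motif$id, " residues ", motif$res_range[1L], "-",
         motif$res_range[2L], " not present in the topology")
  present <- unique(top$atoms$resid[midx])
  missing <- setdiff(seq(motif$res_range[1L], motif$res_range[2L]), present)
  if (length(missing))
    stop("motif ", motif$id, " is missing residues: ",
         paste(missing, collapse = ", "))
  occ <- seq_len(n_atoms(top))
  if (!is.null(exclude))
    occ <- setdiff(occ, suppressWarnings(resolve_selection(top, exclude)))
  occ <- sort(union(occ, midx))
  mpos <- match(midx, occ)
  radii <- top$atoms$vdw[occ]
  ref <- .extended_reference_sasa(top, midx, probe, n_points)
  nf <- n_frames(traj)
  sasa_t <- vapply(seq_len(nf), function(i) {
    xyz <- frame_coords(traj, i)[occ, , drop = FALSE]
    sum(sasa(list(xyz = xyz, radii = radii), probe, n_points, subset = mpos))
  }, numeric(1))
  rel <- sasa_t / ref
  out <- data.frame(frame = seq_len(nf), time_ns = frame_times(traj),
                    sasa_A2 = sasa_t, relative = rel,
                    exposed = rel > threshold)
  attr(out, "motif") <- motif
  attr(out, "reference_sasa") <- ref
  attr(out, "exposed_fraction") <- mean(out$exposed)
  class(out) <- c("cg_motif_exposure", "data.frame")
  out
}

# Reference SASA of the motif residues in a generated extended
# conformation.  Residues with a full backbone are rebuilt as an
# extended peptide; pseudo-residue motifs (coarse fixtures) are laid
# out along a line, residues 4 A apart, keeping intra-residue geometry.
.extended_reference_sasa <- function(top, midx, probe, n_points) {
  at <- top$atoms[midx, , drop = FALSE]
  resids <- sort(unique(at$resid))
  has_bb <- all(vapply(resids, function(r)
    all(c("N", "CA", "C", "O") %in% at$name[at$resid == r]), logical(1)))
  if (has_bb) {
    ext <- make_extended_chain(length(resids))
    return(sum(sasa(ext, probe, n_points)))
  }
  xyz <- cbind(at$x, at$y, at$z)
  out_xyz <- xyz
  for (k in seq_along(resids)) {
    rows <- which(at$resid == resids[k])
    ctr <- colMeans(xyz[rows, , drop = FALSE])
    out_xyz[rows, ] <- sweep(xyz[rows, , drop = FALSE], 2L, ctr) +
      matrix(rep(c(4 * (k - 1L), 0, 0), each = length(rows)), ncol = 3L)
  }
  sum(sasa(list(xyz = out_xyz, radii = at$vdw), probe, n_points))
}
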