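#' Per-frame RMSD of a trajectory against a reference structure
#'
#' Each frame is superposed on the reference over `fit_sel` (Kabsch,
#' mass-weighted by default) and the RMSD is then measured over
#' `measure_sel` without re-fitting.  With `measure_sel = fit_sel` this
#' is the classical fitted backbone RMSD; with a domain fit and a ligand
#' measure it is the docked-pose drift.
#'
#' @param traj a `cg_trajectory`.
#' @param ref reference `cg_structure` (defaults to frame 1).
#' @param fit_sel selection used for the superposition.
#' @param measure_sel selection the RMSD is measured over (default:
#'   `fit_sel`).
#' @param mass_weighted use atomic masses as fit/measure weights
#'   (default TRUE).
#' @param label free-text series label stored with the result.
#' @return object of class `cg_rmsd_series`: data.frame columns `frame`,
#'   `time_ns`, `rmsd`, plus `label` and `reference` attributes.
#' @export
rmsd_series <- function(traj, ref = NULL, fit_sel = NULL,
                        measure_sel = fit_sel, mass_weighted = TRUE,
                        label = "rmsd") {
  stopifnot(inherits(traj, "cg_trajectory"))
  if (is.null(ref)) ref <- frame_structure(traj, 1L)
  fi <- resolve_selection(traj$topology, fit_sel)
  mi <- if (is.null(measure_sel)) fi else resolve_selection(traj$topology, measure_sel)
  if (length(fi) == 0L || length(mi) == 0L) stop("empty selection")
  rf <- resolve_selection(ref, fit_sel)
  rm_ <- if (is.null(measure_sel)) rf else resolve_selection(ref, measure_sel)
  if (length(rf) != length(fi) || length(rm_) != length(mi))
    stop("selection resolves to different atom counts in trajectory and reference")
  wfit <- if (mass_weighted) traj$topology$atoms$mass[fi] else NULL
  wms  <- if (mass_weighted) traj$topology$atoms$mass[mi] else NULL
  refxyz <- coords(ref)
  out <- vapply(seq_len(n_frames(traj)), function(i) {
    fr <- frame_coords(traj, i)
    fit <- kabsch_superpose(fr[fi, , drop = FALSE],
                            refxyz[rf, , drop = FALSE], wfit)
    .wrmsd(apply_transform(fit, fr[mi, , drop = FALSE]),
           refxyz[rm_, , drop = FALSE], wms)
  }, numeric(1))
  res <- data.frame(frame = seq_len(n_frames(traj)),
                    time_ns = frame_times(traj), rmsd = out)
  attr(res, "label") <- label
  attr(res, "reference") <- "reference structure"
  class(res) <- c("cg_rmsd_series", "data.frame")
  res
}

#' Per-domain RMSD averaged over the channel monomers
#'
#' Runs [rmsd_series()] for a domain chain-by-chain (fitting and
#' measuring on that chain's domain backbone) and averages the per-frame
#' values over the monomers.
#'
#' @param traj a `cg_trajectory`.
#' @param ref reference structure (default frame 1).
#' @param domain a `cg_domain`.
#' @param chains monomer chain ids (default: all chains the domain spans).
#' @param backbone_only measure on backbone atoms only (default TRUE).
#' @param ... passed to [rmsd_series()].
#' @return `cg_rmsd_series` of the monomer-averaged RMSD.
#' @export
domain_rmsd <- function(traj, ref = NULL, domain, chains = NULL,
                        backbone_only = TRUE, ...) {
  stopifnot(inherits(domain, "cg_domain"))
  if (is.null(chains)) chains <- unique(traj$topology$atoms$chain)
  per <- lapply(chains, function(ch) {
    sel <- domain_selection(domain, chain = ch, backbone_only = backbone_only)
    rmsd_series(traj, ref, fit_sel = sel, ...)$rmsd
  })
  res <- data.frame(frame = seq_len(n_frames(traj)),
                    time_ns = frame_times(traj),
                    rmsd = Reduce(`+`, per) / length(per))
  attr(res, "label") <- paste0(domain$name, " (monomer mean)")
  class(res) <- c("cg_rmsd_series", "data.frame")
  res
}

#' Ligand RMSD from a docked reference pose
#'
#' Frames are superposed on the protein (`protein_fit_sel`); the RMSD is
#' measured over the ligand atoms with no ligand re-fit, so a ligand that
#' rides rigidly with the protein scores 0 and a ligand drifting in a
#' fixed binding site scores its true displacement.  Ligand atoms are
#' matched between trajectory and reference by (chain, resid, name).
#'
#' @param traj a `cg_trajectory`.
#' @param ligand_sel selection of the ligand atoms.
#' @param docked_ref `cg_structure` holding the docked pose.
#' @param protein_fit_sel selection of protein atoms used for the fit.
#' @param mass_weighted mass-weight the fit (default TRUE).
#' @return `cg_rmsd_series`.
#' @export
ligand_rmsd <- function(traj, ligand_sel, docked_ref, protein_fit_sel,
                        mass_weighted = TRUE) {
  top <- traj$topology
  li <- resolve_selection(top, ligand_sel)
  if (length(li) == 0L) stop("empty ligand selection")
  lr <- resolve_selection(docked_ref, ligand_sel)
  key <- function(a, idx) paste(a$atoms$chain[idx], a$atoms$resid[idx],
                                a$atoms$name[idx], sep = "|")
  kt <- key(top, li); kr <- key(docked_ref, lr)
  if (!setequal(kt, kr)) {
    un <- union(setdiff(kt, kr), setdiff(kr, kt))
    stop("ligand atom-name mismatch between trajectory and docked pose: ",
         paste(un, collapse = ", "))
  }
  lr <- lr[match(kt, kr)]
  fi <- resolve_selection(top, protein_fit_sel)
  fr_ <- resolve_selection(docked_ref, protein_fit_sel)
  if (length(fi) == 0L) stop("empty protein fit selection")
  wfit <- if (mass_weighted) top$atoms$mass[fi] else NULL
  refxyz <- coords(docked_ref)
  out <- vapply(seq_len(n_frames(traj)), function(i) {
    fr <- frame_coords(traj, i)
    fit <- kabsch_superpose(fr[fi, , drop = FALSE],
                            refxyz[fr_, , drop = FALSE], wfit)
    .wrmsd(apply_transform(fit, fr[li, , drop = FALSE]),
           refxyz[lr, , drop = FALSE])
  }, numeric(1))
  res <- data.frame(frame = seq_len(n_frames(traj)),
                    time_ns = frame_times(traj), rmsd = out)
  attr(res, "label") <- "ligand vs docked pose"
  class(res) <- c("cg_rmsd_series", "data.frame")
  res
}

#' Per-residue RMSF averaged over channel monomers
#'
#' Frames are first aligned to the time-average structure (computed
#' after an initial alignment to frame 1, then refined once).  The RMSF
#' of a residue is the root-mean-square deviation of its backbone
#' centroid from the mean position over frames.  Profiles of the
#' monomer chains are then averaged residue-by-residue (chains are
#' matched on their shared residue ids).
#'
#' @param traj a `cg_trajectory` with at least 2 frames.
#' @param sel selection defining the atoms used for alignment and
#'   profiling (default: all backbone atoms).
#' @param monomer_chains chains to average over (default: all).
#' @param mass_weighted mass-weight the alignment (default TRUE).
#' @return object of class `cg_rmsf_profile`: data.frame `resid`,
#'   `rmsf` (Angstrom, monomer mean), with the per-chain matrix in
#'   `attr(, "per_chain")`.
#' @export
rmsf_profile <- function(traj, sel = cg_selection(backbone_only = TRUE),
                         monomer_chains = NULL, mass_weighted = TRUE) {
  stopifnot(inherits(traj, "cg_trajectory"))
  if (n_frames(traj) < 2L) stop("RMSF needs at least 2 frames")
  top <- traj$topology
  idx <- resolve_selection(top, sel)
  if (length(idx) == 0L) stop("empty selection")
  w <- if (mass_weighted) top$atoms$mass[idx] else NULL
  ref <- frame_coords(traj, 1L)[idx, , drop = FALSE]
  aligned <- lapply(seq_len(n_frames(traj)), function(i) {
    fr <- frame_coords(traj, i)[idx, , drop = FALSE]
    apply_transform(kabsch_superpose(fr, ref, w), fr)
  })
  avg <- Reduce(`+`, aligned) / length(aligned)
  aligned <- lapply(aligned, function(fr)
    apply_transform(kabsch_superpose(fr, avg, w), fr))
  avg <- Reduce(`+`, aligned) / length(aligned)

  at <- top$atoms[idx, , drop = FALSE]
  if (is.null(monomer_chains)) monomer_chains <- unique(at$chain)
  grp <- paste(at$chain, at$resid, sep = "|")
  groups <- split(seq_along(idx), grp)
  # per-(chain,residue) centroid fluctuation
  cent <- function(fr, g) colMeans(fr[g, , drop = FALSE])
  res_info <- do.call(rbind, lapply(names(groups), function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1L]]
    data.frame(chain = parts[1L], resid = as.integer(parts[2L]),
               stringsAsFactors = FALSE)
  }))
  mean_cent <- lapply(groups, function(g) cent(avg, g))
  msd <- vapply(seq_along(groups), function(j) {
    g <- groups[[j]]; m <- mean_cent[[j]]
    mean(vapply(aligned, function(fr) sum((cent(fr, g) - m)^2), numeric(1)))
  }, numeric(1))
  res_info$rmsf <- sqrt(msd)

  res_info <- res_info[res_info$chain %in% monomer_chains, , drop = FALSE]
  shared <- Reduce(intersect, split(res_info$resid, res_info$chain))
  per_chain <- vapply(monomer_chains, function(ch) {
    sub <- res_info[res_info$chain == ch, ]
    sub$rmsf[match(shared, sub$resid)]
  }, numeric(length(shared)))
  per_chain <- matrix(per_chain, nrow = length(shared),
                      dimnames = list(NULL, monomer_chains))
  out <- data.frame(resid = shared, rmsf = rowMeans(per_chain))
  attr(out, "per_chain") <- per_chain
  class(out) <- c("cg_rmsf_profile", "data.frame")
  out
}

#' Low-RMSF anchor segments
#'
#' Selects the quantile of residues with the lowest RMSF (ties broken by
#' residue order) and keeps contiguous runs of at least `min_length`
#' residues.  These are the anchor points used to superpose
#' representative conformations without letting mobile loops dominate
#' the fit.
#'
#' @param profile a `cg_rmsf_profile`.
#' @param quantile fraction of residues to consider (0 < q < 1).
#' @param min_length minimal segment length (default 5).
#' @return a [cg_selection()] over the anchor residues, with the segment
#'   table in `attr(, "segments")`.  Empty (with a warning) when no run
#'   reaches `min_length`.
#' @export
low_rmsf_anchors <- function(profile, quantile, min_length = 5L) {
  stopifnot(inherits(profile, "cg_rmsf_profile"))
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  n <- nrow(profile)
  ord <- order(profile$rmsf, profile$resid)
  take <- ord[seq_len(max(1L, floor(quantile * n)))]
  resids <- sort(profile$resid[take])
  if (length(resids)) {
    brk <- c(0L, which(diff(resids) != 1L), length(resids))
    segs <- do.call(rbind, lapply(seq_len(length(brk) - 1L), function(j) {
      run <- resids[(brk[j] + 1L):brk[j + 1L]]
      data.frame(from = run[1L], to = run[length(run)], length = length(run))
    }))
    segs <- segs[segs$length >= min_length, , drop = FALSE]
  } else segs <- data.frame(from = integer(), to = integer(), length = integer())
  if (nrow(segs) == 0L) {
    warning("no contiguous low-RMSF segment of length >= ", min_length)
    sel <- cg_selection(resids = integer(0))
  } else {
    sel <- cg_selection(res_range = lapply(seq_len(nrow(segs)), function(j)
      c(segs$from[j], segs$to[j])))
  }
  attr(sel, "segments") <- segs
  sel
}
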