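#' Mass-weighted center of mass of a selection
#' @param frame a `cg_structure`.
#' @param sel a [cg_selection()] (NULL = all atoms).
#' @return 3-vector (Angstrom).
#' @export
center_of_mass <- function(frame, sel = NULL) {
  idx <- if (is.null(sel)) seq_len(n_atoms(frame))
         else suppressWarnings(resolve_selection(frame, sel))
  if (length(idx) == 0L) stop("empty selection for center of mass")
  m <- frame$atoms$mass[idx]
  as.numeric(colSums(coords(frame)[idx, , drop = FALSE] * m) / sum(m))
}

#' Domain angle at a hinge
#'
#' The angle, at the hinge's center of mass, between the vectors to the
#' domain COM and to the TMD COM — the "PAS domain angle" / "CNBD
#' domain angle" descriptor.  Vertex = middle point of the (domain,
#' hinge, TMD) triple.
#'
#' @param frame a `cg_structure`.
#' @param dom,hinge,tmd `cg_domain` objects (or [cg_selection()]s);
#'   must resolve to disjoint non-empty atom sets.
#' @param chain restrict domain/hinge (and, per-monomer convention, the
#'   TMD) to one chain.
#' @return angle in degrees, in `[0, 180]`.
#' @export
domain_angle <- function(frame, dom, hinge, tmd, chain = NULL) {
  as_sel <- function(d) {
    if (inherits(d, "cg_domain")) domain_selection(d, chain = chain) else d
  }
  ia <- suppressWarnings(resolve_selection(frame, as_sel(dom)))
  ih <- suppressWarnings(resolve_selection(frame, as_sel(hinge)))
  it <- suppressWarnings(resolve_selection(frame, as_sel(tmd)))
  if (!length(ia) || !length(ih) || !length(it))
    stop("domain/hinge/TMD selection resolved to no atoms")
  if (length(intersect(ia, ih)) || length(intersect(ih, it)) ||
      length(intersect(ia, it)))
    stop("domain, hinge and TMD selections must be disjoint")
  com <- function(idx) {
    m <- frame$atoms$mass[idx]
    as.numeric(colSums(coords(frame)[idx, , drop = FALSE] * m) / sum(m))
  }
  .vertex_angle(com(ia), com(ih), com(it))
}

.vertex_angle <- function(a, vertex, b) {
  u <- a - vertex; v <- b - vertex
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-6 || nv < 1e-6) stop("degenerate angle: coincident centers of mass")
  cosang <- sum(u * v) / (nu * nv)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Domain-angle time series over a trajectory
#'
#' Computes the COM-hinge-COM angle per frame for each requested triple,
#' per monomer chain, plus the monomer-averaged series and the drift
#' (mean over the last `window` fraction of frames minus mean over the
#' first `window` fraction).
#'
#' @param traj a `cg_trajectory`.
#' @param triples list of lists with elements `dom`, `hinge`, `tmd`
#'   (`cg_domain`s) and `label`.
#' @param chains monomer chains (default: all chains in the topology).
#' @param per_monomer_tmd use each monomer's own TMD atoms as the third
#'   COM (default TRUE); FALSE uses the whole-tetramer TMD COM.
#' @param window drift window fraction at each end (default 0.1).
#' @return list of `cg_angle_series` objects, one per triple: each has
#'   `label`, `per_monomer` (frames x chains matrix, degrees), `mean`
#'   (monomer-averaged series), `time_ns`, `drift` (monomer-mean
#'   drift), `drift_per_monomer`.
#' @export
angle_timeseries <- function(traj, triples, chains = NULL,
                             per_monomer_tmd = TRUE, window = 0.1) {
  stopifnot(inherits(traj, "cg_trajectory"))
  if (is.null(chains)) chains <- unique(traj$topology$atoms$chain)
  nf <- n_frames(traj)
  top <- traj$topology
  mass <- top$atoms$mass
  lapply(triples, function(tr) {
    per <- vapply(chains, function(ch) {
      tmd_chain <- if (per_monomer_tmd) ch else NULL
      as_sel <- function(d, c2) {
        if (inherits(d, "cg_domain")) domain_selection(d, chain = c2) else d
      }
      ia <- suppressWarnings(resolve_selection(top, as_sel(tr$dom, ch)))
      ih <- suppressWarnings(resolve_selection(top, as_sel(tr$hinge, ch)))
      it <- suppressWarnings(resolve_selection(top, as_sel(tr$tmd, tmd_chain)))
      if (!length(ia) || !length(ih) || !length(it))
        stop("domain/hinge/TMD selection resolved to no atoms")
      if (length(intersect(ia, ih)) || length(intersect(ih, it)) ||
          length(intersect(ia, it)))
        stop("domain, hinge and TMD selections must be disjoint")
      # COM series for a fixed selection across all frames at once
      com_series <- function(idx) {
        w <- mass[idx] / sum(mass[idx])
        matrix(vapply(0:2, function(d)
          as.numeric(traj$xyz[, 3L * idx - 2L + d, drop = FALSE] %*% w),
          numeric(nf)), nrow = nf)
      }
      A <- com_series(ia); H <- com_series(ih); B <- com_series(it)
      u <- A - H; v <- B - H
      nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
      if (any(nu < 1e-6) || any(nv < 1e-6))
        stop("degenerate angle: coincident centers of mass")
      acos(pmax(-1, pmin(1, rowSums(u * v) / (nu * nv)))) * 180 / pi
    }, numeric(nf))
    per <- matrix(per, nrow = nf, dimnames = list(NULL, chains))
    avg <- rowMeans(per)
    w <- max(1L, floor(window * nf))
    drift_of <- function(x) mean(x[(nf - w + 1L):nf]) - mean(x[seq_len(w)])
    structure(list(label = tr$label, per_monomer = per, mean = avg,
                   time_ns = frame_times(traj),
                   drift = drift_of(avg),
                   drift_per_monomer = apply(per, 2L, drift_of)),
              class = "cg_angle_series")
  })
}

#' @export
print.cg_angle_series <- function(x, ...) {
  cat(sprintf("cg_angle_series '%s': %d frames, mean %.1f deg, drift %+.1f deg\n",
              x$label, length(x$mean), mean(x$mean), x$drift))
  invisible(x)
}

#' Replica consistency of angle drifts
#'
#' For independent replicas of the same system, reports each replica's
#' drift and the maximum absolute pairwise difference — the "replicas
#' agree to within about X degrees" statement.
#'
#' @param series_list list of `cg_angle_series` (>= 2), one per replica.
#' @return list: `drifts` (per replica), `max_deviation` (degrees).
#' @export
replica_consistency <- function(series_list) {
  if (length(series_list) < 2L) stop("need at least 2 replicas")
  drifts <- vapply(series_list, function(s) {
    if (inherits(s, "cg_angle_series")) s$drift else as.numeric(s)
  }, numeric(1))
  dev <- max(abs(outer(drifts, drifts, "-")))
  list(drifts = drifts, max_deviation = dev)
}
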