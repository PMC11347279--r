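#' Pore axis definition
#'
#' By membrane convention the pore axis is the z-axis of the input
#' frame; an arbitrary axis may be given as a point plus direction, or
#' derived from two center-of-mass anchors with [pore_axis_from_anchors()].
#'
#' @param point a point on the axis (Angstrom).
#' @param direction axis direction (normalised internally).
#' @param z_range `c(z_lo, z_hi)` span of the profile along the axis,
#'   measured from `point`.
#' @param dz slice spacing in Angstrom (default 0.5).
#' @return object of class `cg_pore_axis`.
#' @export
cg_pore_axis <- function(point = c(0, 0, 0), direction = c(0, 0, 1),
                         z_range = c(-15, 15), dz = 0.5) {
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("axis direction must be non-zero")
  if (z_range[2L] <= z_range[1L]) stop("z_range must satisfy z_hi > z_lo")
  if (dz <= 0) stop("dz must be > 0")
  structure(list(point = as.numeric(point), direction = direction / nrm,
                 z_range = as.numeric(z_range), dz = dz),
            class = "cg_pore_axis")
}

#' Pore axis through two center-of-mass anchors
#' @param frame a `cg_structure`.
#' @param sel_a,sel_b selections whose mass centers define the axis
#'   (direction from a to b).
#' @param z_range,dz as in [cg_pore_axis()].
#' @return `cg_pore_axis`.
#' @export
pore_axis_from_anchors <- function(frame, sel_a, sel_b,
                                   z_range = c(-15, 15), dz = 0.5) {
  a <- center_of_mass(frame, sel_a)
  b <- center_of_mass(frame, sel_b)
  cg_pore_axis(point = (a + b) / 2, direction = b - a,
               z_range = z_range, dz = dz)
}

# orthonormal basis with the axis direction as the third column
.axis_basis <- function(direction) {
  w <- direction / sqrt(sum(direction^2))
  seed <- if (abs(w[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- seed - sum(seed * w) * w
  u <- u / sqrt(sum(u^2))
  v <- c(w[2L] * u[3L] - w[3L] * u[2L],
         w[3L] * u[1L] - w[1L] * u[3L],
         w[1L] * u[2L] - w[2L] * u[1L])
  cbind(u, v, w)
}

#' Largest inscribed sphere in one pore slice
#'
#' HOLE-style per-slice search: the sphere center is constrained to the
#' plane normal to the axis at height `z`, within `search_radius`
#' laterally of the axis, and the objective
#' \eqn{f(c) = \min_i (|c - a_i| - r_i)} is maximised — a deterministic
#' coarse lateral grid (default 0.25 A) followed by Nelder-Mead
#' refinement from the best cell, so results are seed-free.
#'
#' Negative radii are reported as occlusion depth rather than clamped to
#' zero (they preserve the collapse signal).  Two degenerate outcomes
#' are flagged: slices with no atoms in reach, or where the optimum runs
#' away laterally, are `"open"` (radius capped at `search_radius`) and
#' `"escaped"` (the lumen is not enclosed at this height; the on-axis
#' occlusion value is reported) respectively.
#'
#' @param xyz n x 3 atom coordinates.
#' @param radii per-atom van der Waals radii.
#' @param axis a `cg_pore_axis`.
#' @param z slice height along the axis (Angstrom, relative to
#'   `axis$point`).
#' @param search_radius lateral search window (default 10 A).
#' @param grid_spacing coarse grid step (default 0.25 A).
#' @return list: `radius` (A), `center` (lateral 2-vector in the axis
#'   frame), `status` ("ok", "open" or "escaped"), `radius_max` (the raw
#'   constrained optimum before capping/escape handling).
#' @export
slice_radius <- function(xyz, radii, axis, z, search_radius = 10,
                         grid_spacing = 0.25) {
  stopifnot(inherits(axis, "cg_pore_axis"))
  B <- .axis_basis(axis$direction)
  loc <- sweep(as.matrix(xyz), 2L, axis$point) %*% B   # axis frame
  .slice_radius_local(loc, radii, z, search_radius, grid_spacing)
}

# core slice search on axis-frame coordinates (reused per frame so the
# axis transform is done once per frame, not once per slice)
.slice_radius_local <- function(loc, radii, z, search_radius = 10,
                                grid_spacing = 0.25) {
  near <- abs(loc[, 3L] - z) <= search_radius + max(radii)
  if (!any(near)) {
    return(list(radius = search_radius, center = c(0, 0), status = "open",
                radius_max = search_radius))
  }
  ax <- loc[near, 1L]; ay <- loc[near, 2L]
  adz2 <- (loc[near, 3L] - z)^2
  r <- radii[near]
  fobj <- function(cx, cy)
    min(sqrt((cx - ax)^2 + (cy - ay)^2 + adz2) - r)
  g <- seq(-search_radius, search_radius, by = grid_spacing)
  ng <- length(g)
  gx <- rep(g, times = ng); gy <- rep(g, each = ng)
  # f over all grid points: accumulate atoms in order of their best
  # possible contribution (|dz| - r); once that exceeds the current
  # grid maximum (plus slack) no further atom can bind anywhere useful
  key <- sqrt(adz2) - r
  ord <- order(key)
  if (diff(range(r)) < 1e-12) {
    # uniform radii: the min of (dist - r) is monotone in squared
    # distance, so accumulate squared distances and take one sqrt
    r0 <- r[1L]
    md2 <- rep(Inf, length(gx))
    for (i in ord) {
      cur <- max(md2)
      if (is.finite(cur) && key[i] >= sqrt(cur) - r0 + grid_spacing + 0.1)
        break
      di2 <- (gx - ax[i])^2 + (gy - ay[i])^2 + adz2[i]
      md2 <- pmin(md2, di2)
    }
    fgrid <- sqrt(md2) - r0
  } else {
    fgrid <- rep(Inf, length(gx))
    for (i in ord) {
      cur <- max(fgrid)
      if (is.finite(cur) && key[i] >= cur + grid_spacing + 0.1) break
      di <- sqrt((gx - ax[i])^2 + (gy - ay[i])^2 + adz2[i]) - r[i]
      fgrid <- pmin(fgrid, di)
    }
  }
  fgrid[gx^2 + gy^2 > search_radius^2] <- -Inf
  F <- matrix(fgrid, ng, ng)            # [ix, iy]
  # hill-climb on the grid from the cell nearest the axis: the sphere is
  # grown inside the lumen's own basin, not teleported across the wall
  ix <- which.min(abs(g)); iy <- ix
  repeat {
    nb <- expand.grid(dx = -1:1, dy = -1:1)
    bi <- ix; bj <- iy; bf <- F[ix, iy]
    for (kk in seq_len(nrow(nb))) {
      ii <- ix + nb$dx[kk]; jj <- iy + nb$dy[kk]
      if (ii < 1L || ii > ng || jj < 1L || jj > ng) next
      if (F[ii, jj] > bf) { bf <- F[ii, jj]; bi <- ii; bj <- jj }
    }
    if (bi == ix && bj == iy) break
    ix <- bi; iy <- bj
  }
  start <- c(g[ix], g[iy])
  opt <- stats::optim(start, function(p) {
    pen <- max(0, sqrt(sum(p^2)) - search_radius)
    -(fobj(p[1L], p[2L]) - 1e6 * pen^2)
  }, method = "Nelder-Mead",
  control = list(reltol = 1e-10, maxit = 500L))
  ctr <- opt$par
  fmax <- fobj(ctr[1L], ctr[2L])
  if (fmax < F[ix, iy]) { ctr <- start; fmax <- F[ix, iy] }
  if (fmax >= search_radius)
    return(list(radius = search_radius, center = ctr, status = "open",
                radius_max = fmax))
  if (sqrt(sum(ctr^2)) >= search_radius - 1e-3) {
    # optimum on the window boundary: the wall does not enclose the
    # center here; report the occlusion value at the nominal axis point
    return(list(radius = fobj(0, 0), center = c(0, 0), status = "escaped",
                radius_max = fmax))
  }
  list(radius = fmax, center = ctr, status = "ok", radius_max = fmax)
}

#' Pore-radius profile of a single frame
#'
#' [slice_radius()] evaluated on the z grid of the axis; slices are
#' independent (no continuity constraint).
#'
#' @param frame a `cg_structure`, or a list with `xyz` and `radii`.
#' @param axis a `cg_pore_axis`.
#' @param sel optional selection restricting the occluding atoms.
#' @param ... passed to [slice_radius()].
#' @return object of class `cg_pore_profile`: data.frame `z`, `radius`,
#'   `status`, `cx`, `cy`; attributes `min_radius`, `z_at_min`.
#' @export
pore_profile <- function(frame, axis, sel = NULL, ...) {
  if (inherits(frame, "cg_structure")) {
    idx <- if (is.null(sel)) seq_len(n_atoms(frame)) else resolve_selection(frame, sel)
    xyz <- coords(frame)[idx, , drop = FALSE]
    radii <- frame$atoms$vdw[idx]
  } else {
    xyz <- frame$xyz; radii <- frame$radii
  }
  zs <- seq(axis$z_range[1L], axis$z_range[2L], by = axis$dz)
  loc <- sweep(xyz, 2L, axis$point) %*% .axis_basis(axis$direction)
  rows <- lapply(zs, function(z) {
    s <- .slice_radius_local(loc, radii, z, ...)
    data.frame(z = z, radius = s$radius, status = s$status,
               cx = s$center[1L], cy = s$center[2L])
  })
  out <- do.call(rbind, rows)
  i <- which.min(out$radius)
  attr(out, "min_radius") <- out$radius[i]
  attr(out, "z_at_min") <- out$z[i]
  class(out) <- c("cg_pore_profile", "data.frame")
  out
}

#' Pore radius along the axis over a trajectory
#'
#' Per-frame profiles stacked with their mean and standard deviation
#' over frames at each z — the mean +/- SD pore-radius curve — plus the
#' per-frame minimum radius (optionally restricted to a z window, e.g.
#' just beneath the selectivity filter).
#'
#' @param traj a `cg_trajectory`.
#' @param axis a `cg_pore_axis`.
#' @param sel optional occluder selection.
#' @param min_z_window optional `c(lo, hi)` window for the per-frame
#'   minimum (default: whole profile).
#' @param ... passed to [slice_radius()].
#' @return object of class `cg_pore_timeseries`: list with `z`,
#'   `radius` (frames x z matrix), `mean`, `sd`, `min_radius`
#'   (per frame), `min_z` (per frame), `frame_interval_ns`.
#' @export
pore_timeseries <- function(traj, axis, sel = NULL, min_z_window = NULL, ...) {
  stopifnot(inherits(traj, "cg_trajectory"))
  top <- traj$topology
  idx <- if (is.null(sel)) seq_len(n_atoms(top)) else resolve_selection(top, sel)
  radii <- top$atoms$vdw[idx]
  zs <- seq(axis$z_range[1L], axis$z_range[2L], by = axis$dz)
  nz <- length(zs)
  nf <- n_frames(traj)
  rad <- matrix(NA_real_, nf, nz)
  B <- .axis_basis(axis$direction)
  for (i in seq_len(nf)) {
    xyz <- frame_coords(traj, i)[idx, , drop = FALSE]
    loc <- sweep(xyz, 2L, axis$point) %*% B
    rad[i, ] <- vapply(zs, function(z)
      .slice_radius_local(loc, radii, z, ...)$radius, numeric(1))
  }
  win <- if (is.null(min_z_window)) rep(TRUE, nz)
         else zs >= min_z_window[1L] & zs <= min_z_window[2L]
  mi <- apply(rad[, win, drop = FALSE], 1L, which.min)
  structure(list(z = zs, radius = rad,
                 mean = colMeans(rad),
                 sd = apply(rad, 2L, stats::sd),
                 min_radius = rad[cbind(seq_len(nf), which(win)[mi])],
                 min_z = zs[win][mi],
                 frame_interval_ns = traj$frame_interval_ns),
            class = "cg_pore_timeseries")
}

#' @export
print.cg_pore_timeseries <- function(x, ...) {
  cat("cg_pore_timeseries:", nrow(x$radius), "frames x", length(x$z),
      "slices; mean minimum radius",
      sprintf("%.2f A\n", mean(x$min_radius)))
  invisible(x)
}

#' Mean/SD pore profile as a data.frame
#' @param x a `cg_pore_timeseries`.
#' @param ... unused.
#' @return data.frame `z`, `mean_radius`, `sd_radius`.
#' @export
as.data.frame.cg_pore_timeseries <- function(x, ...) {
  data.frame(z = x$z, mean_radius = x$mean, sd_radius = x$sd)
}
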