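# Synthetic channel-like fixtures with known ground truth.  Pseudo-atom
# geometry (no chemistry) keeps every target quantity analytic: pore
# rings realise a prescribed radius profile, rigid intracellular blobs
# hang from hinges whose center-of-mass angle follows a programmed
# schedule, and a real-backbone peptide covers the chemistry-dependent
# stages (secondary structure, hydrogen reconstruction).

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.fib_sphere <- function(n, radius = 1) .golden_spiral(n) * radius

#' Specification of a synthetic tetrameric channel
#'
#' Defaults describe the study system the analyses are exercised on: a
#' four-fold symmetric pseudo-atom channel with a z-axis pore of
#' prescribed radius profile (atom centers placed on rings of radius
#' `R(z)`, so the measured pore radius is `R(z) - atom_vdw`), and per
#' monomer a PAS-like and a CNBD-like blob connected to the pore stack
#' through hinge blobs.  Three five-residue motifs are planted in each
#' PAS blob: one on the outward surface, one buried inside the shell,
#' and one at the PAS/CNBD interface.
#'
#' @param n_chains number of monomers (4; the generator assumes 4-fold
#'   symmetry about z).
#' @param radius pore ring radius: a constant (Angstrom) or a function
#'   of z.
#' @param z_range pore span along z.
#' @param ring_dz ring spacing (default 1 A).
#' @param atoms_per_ring atoms per full ring (multiple of `n_chains`).
#' @param atom_vdw van der Waals radius given to every pseudo-atom.
#' @return object of class `cg_channel_spec` (a list).
#' @export
channel_spec <- function(n_chains = 4L, radius = 5, z_range = c(-15, 15),
                         ring_dz = 1, atoms_per_ring = 40L, atom_vdw = 1.5) {
  if (atoms_per_ring %% n_chains != 0L)
    stop("atoms_per_ring must be a multiple of n_chains")
  Rz <- if (is.function(radius)) radius else function(z) rep(radius, length(z))
  zs <- seq(z_range[1L], z_range[2L], by = ring_dz)
  if (any(Rz(zs) <= 0)) stop("pore radius must be positive over the z span")
  structure(list(n_chains = n_chains, radius = Rz, z_range = z_range,
                 ring_dz = ring_dz, atoms_per_ring = as.integer(atoms_per_ring),
                 atom_vdw = atom_vdw),
            class = "cg_channel_spec")
}

#' Domain definitions matching [make_channel()] residue numbering
#' @return named list of [cg_domain()] objects: PAS, hinge_PAS, CNBD,
#'   hinge_CNBD, TMD.
#' @export
synthetic_channel_domains <- function() {
  list(PAS = cg_domain("PAS", c(1L, 35L)),
       hinge_PAS = cg_domain("hinge_PAS", c(41L, 52L)),
       CNBD = cg_domain("CNBD", c(61L, 85L)),
       hinge_CNBD = cg_domain("hinge_CNBD", c(91L, 100L)),
       TMD = cg_domain("TMD", c(201L, 999L)))
}

#' Motif definitions planted by [make_channel()]
#' @return named list of [cg_motif()]: `surface` (PAS residues 21-25,
#'   outward face), `buried` (26-30, inside the PAS shell), `interface`
#'   (31-35, facing the CNBD blob).
#' @export
synthetic_channel_motifs <- function() {
  list(surface = cg_motif("surface", "A", c(21L, 25L), "KFERQ-related"),
       buried = cg_motif("buried", "A", c(26L, 30L), "tyrosine-based"),
       interface = cg_motif("interface", "A", c(31L, 35L), "tyrosine-based"))
}

#' Build the synthetic tetrameric channel
#'
#' @param spec a [channel_spec()].
#' @return a [cg_structure()] carrying generator metadata (used by
#'   [make_trajectory()] to realise motion schedules exactly).
#' @export
make_channel <- function(spec = channel_spec()) {
  nch <- spec$n_chains
  chains <- LETTERS[seq_len(nch)]
  per_ring <- spec$atoms_per_ring %/% nch
  zs <- seq(spec$z_range[1L], spec$z_range[2L], by = spec$ring_dz)
  et <- element_table()
  crow <- match("C", et$element)
  rows <- list(); pore_meta <- list()
  blob_shell <- .fib_sphere(20L, 2.5)
  hinge_shell <- .fib_sphere(12L, 1.5)
  hingeC_shell <- .fib_sphere(10L, 1.5)
  cnbd_shell <- rbind(.fib_sphere(24L, 2.5), c(0, 0, 0))
  mk <- function(xyz, resid, chain, role) {
    data.frame(serial = 0L, name = "C1", element = "C", resname = "DUM",
               resid = resid, chain = chain,
               x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
               vdw = spec$atom_vdw, mass = et$mass[crow],
               role = role, stringsAsFactors = FALSE)
  }
  rot_z <- function(deg) {
    a <- deg * pi / 180
    matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
  }
  geom <- list()
  for (ci in seq_len(nch)) {
    ch <- chains[ci]
    Rz45 <- rot_z(90 * (ci - 1L))
    dirv <- as.numeric(c(cos(pi / 4), sin(pi / 4), 0) %*% t(Rz45))
    tang <- as.numeric(c(-sin(pi / 4), cos(pi / 4), 0) %*% t(Rz45))
    zhat <- c(0, 0, 1)
    # pore rings: this chain's quarter arc.  Note the measured
    # inscribed-sphere profile of a sloped wall is the erosion of the
    # ring stack, min_k sqrt(R(z_k)^2 + (z_k - z)^2) - r_atom, which
    # for a cylinder reduces to R - r_atom but for a narrow waist is
    # necessarily wider than R(z) - r_atom (the sphere spans the waist)
    theta <- ((seq_len(per_ring) - 0.5) / per_ring) * 90 + 90 * (ci - 1L)
    ring <- do.call(rbind, lapply(seq_along(zs), function(k) {
      data.frame(theta = theta, z = zs[k], R0 = spec$radius(zs[k]))
    }))
    ring_xyz <- cbind(ring$R0 * cos(ring$theta * pi / 180),
                      ring$R0 * sin(ring$theta * pi / 180), ring$z)
    tmd_com <- colMeans(ring_xyz)
    # intracellular blob centers (monomer frame, azimuth 45 deg + chain offset)
    hinge_pas_c <- 14 * dirv + c(0, 0, -20)
    pas_c <- hinge_pas_c + 8 * tang - 6 * zhat
    hinge_cnbd_c <- 6 * dirv + c(0, 0, -22)
    cnbd_c <- hinge_cnbd_c + 6 * tang - 8 * zhat
    # rotation-plane frames (e1 towards the blob, e2 towards the TMD) —
    # used both to realise angle schedules and to orient the motifs
    plane_frame <- function(hinge, ctr) {
      v0 <- ctr - hinge
      u <- tmd_com - hinge
      e1 <- v0 / sqrt(sum(v0^2))
      uperp <- u - sum(u * e1) * e1
      list(hinge = hinge, len = sqrt(sum(v0^2)), e1 = e1,
           e2 = uperp / sqrt(sum(uperp^2)),
           theta0 = .vertex_angle(ctr, hinge, tmd_com))
    }
    pas_frame <- plane_frame(hinge_pas_c, pas_c)
    cnbd_frame <- plane_frame(hinge_cnbd_c, cnbd_c)
    to_cnbd <- (cnbd_c - pas_c) / sqrt(sum((cnbd_c - pas_c)^2))
    away <- -to_cnbd
    crossv <- function(a, b) c(a[2L] * b[3L] - a[3L] * b[2L],
                               a[3L] * b[1L] - a[1L] * b[3L],
                               a[1L] * b[2L] - a[2L] * b[1L])
    # strips of 5 motif pseudo-residues, 2.4 A apart, perpendicular to
    # the hinge-swing direction so a swing slides them off their occluder
    t3 <- crossv(to_cnbd, pas_frame$e2)
    t3 <- t3 / sqrt(sum(t3^2))
    strip <- function(dir, dist)
      t(vapply(-2:2, function(k) dist * dir + 2.4 * k * t3, numeric(3)))
    # PAS: shell (1-20), surface motif (21-25), buried motif (26-30),
    # interface motif (31-35)
    surf_pts <- strip(away, 4.2)
    buried_pts <- .fib_sphere(5L, 0.7) %*% t(Rz45)
    iface_pts <- strip(to_cnbd, 4.2)
    pas_off <- rbind(blob_shell %*% t(Rz45), surf_pts, buried_pts, iface_pts)
    pas_xyz <- sweep(pas_off, 2L, pas_c, "+")
    rows[[length(rows) + 1L]] <- mk(pas_xyz, 1L:35L, ch, "PAS")
    rows[[length(rows) + 1L]] <-
      mk(sweep(hinge_shell %*% t(Rz45), 2L, hinge_pas_c, "+"),
         41L:52L, ch, "hinge_PAS")
    rows[[length(rows) + 1L]] <-
      mk(sweep(cnbd_shell %*% t(Rz45), 2L, cnbd_c, "+"), 61L:85L, ch, "CNBD")
    rows[[length(rows) + 1L]] <-
      mk(sweep(hingeC_shell %*% t(Rz45), 2L, hinge_cnbd_c, "+"),
         91L:100L, ch, "hinge_CNBD")
    # static occluder plate covering the interface motif's resting
    # position (it clears the plate when the PAS blob swings)
    plate_ctr <- pas_c + 6.4 * to_cnbd
    plate <- do.call(rbind, lapply(seq(-6, 6, by = 1.5), function(aa)
      t(vapply(seq(-3.0, 0.6, by = 1.2), function(bb)
        plate_ctr + aa * t3 + bb * pas_frame$e2, numeric(3)))))
    rows[[length(rows) + 1L]] <-
      mk(plate, 110L + seq_len(nrow(plate)) - 1L, ch, "plate")
    rows[[length(rows) + 1L]] <-
      mk(ring_xyz, 200L + seq_len(nrow(ring)), ch, "pore")
    pore_meta[[ch]] <- ring
    geom[[ch]] <- list(hinge_PAS = hinge_pas_c, pas_center = pas_c,
                       hinge_CNBD = hinge_cnbd_c, cnbd_center = cnbd_c,
                       PAS = pas_frame, CNBD = cnbd_frame)
  }
  atoms <- do.call(rbind, rows)
  atoms <- atoms[order(atoms$chain, atoms$resid), , drop = FALSE]
  atoms$serial <- seq_len(nrow(atoms))
  role <- atoms$role
  atoms$role <- NULL
  s <- cg_structure(atoms)
  s$atoms$role <- role
  attr(s, "cg_channel") <- list(chains = chains, geom = geom,
                                pore = pore_meta, spec_obj = spec)
  s
}

#' Motion schedule for synthetic trajectories
#'
#' Encodes the phenomena the analyses must detect as controllable
#' ground truth: pore constriction below a marked z (a collapse beneath
#' the "selectivity filter"), hinge-angle drift of the intracellular
#' blobs, helix unfolding of a peptide segment, and isotropic Gaussian
#' thermal noise.  Ramps: `"plateau"` (smoothstep between 20 % and 80 %
#' of the run, so the first/last 10 % windows sit on the start/end
#' values), `"linear"`, or `"step"` (switch at half time).
#'
#' @param constriction NULL or `list(z_below =, final_scale =, ramp =)`;
#'   ring radii below `z_below` are scaled towards `final_scale`.
#' @param hinge_drift NULL or `list(PAS =, CNBD =, noise_sd =, ramp =)`
#'   with drifts in degrees.
#' @param unfold NULL or `list(segment = c(lo, hi), fraction =)` for
#'   peptide trajectories.
#' @param noise_sigma per-atom, per-coordinate Gaussian noise (A).
#' @return object of class `cg_motion_schedule`.
#' @export
motion_schedule <- function(constriction = NULL, hinge_drift = NULL,
                            unfold = NULL, noise_sigma = 0.05) {
  if (!is.null(constriction)) {
    constriction <- utils::modifyList(
      list(z_below = Inf, final_scale = 0.6, ramp = "plateau"), constriction)
  }
  if (!is.null(hinge_drift)) {
    hinge_drift <- utils::modifyList(
      list(PAS = 0, CNBD = 0, noise_sd = 0, ramp = "plateau"), hinge_drift)
  }
  if (!is.null(unfold)) {
    if (is.null(unfold$segment)) stop("unfold needs a segment")
    unfold <- utils::modifyList(list(fraction = 0.5), unfold)
  }
  structure(list(constriction = constriction, hinge_drift = hinge_drift,
                 unfold = unfold, noise_sigma = noise_sigma),
            class = "cg_motion_schedule")
}

.ramp <- function(frac, kind) {
  switch(kind,
         linear = frac,
         step = as.numeric(frac >= 0.5),
         plateau = {
           s <- pmin(1, pmax(0, (frac - 0.2) / 0.6))
           3 * s^2 - 2 * s^3
         },
         stop("unknown ramp: ", kind))
}

#' Generate a synthetic trajectory from a structure and a schedule
#'
#' Channel structures (from [make_channel()]) realise pore-constriction
#' and hinge-drift schedules exactly — ring radii are rescaled and each
#' monomer's blob is moved so its COM-hinge-COM angle equals the
#' programmed value — before i.i.d. Gaussian noise is added.  Peptide
#' structures realise unfolding schedules by swapping the flagged
#' frames to a conformation whose segment torsions are randomised (the
#' rest of the chain keeps ideal helix torsions).  All randomness flows
#' from `seed`; the programmed ground truth is attached as a manifest.
#'
#' @param structure a [make_channel()] or [make_ideal_helix()] output.
#' @param schedule a [motion_schedule()].
#' @param n_frames number of frames.
#' @param seed integer seed fixing all randomness.
#' @param frame_interval_ns snapshot interval (default 0.01 ns).
#' @return a [cg_trajectory()] with `attr(, "manifest")`.
#' @export
make_trajectory <- function(structure, schedule = motion_schedule(),
                            n_frames = 100L, seed = 1L,
                            frame_interval_ns = 0.01) {
  stopifnot(inherits(structure, "cg_structure"),
            inherits(schedule, "cg_motion_schedule"))
  meta <- attr(structure, "cg_channel")
  .with_seed(seed, {
    if (!is.null(meta)) {
      xyz <- .channel_frames(structure, meta, schedule, n_frames)
    } else if (!is.null(schedule$unfold)) {
      xyz <- .unfold_frames(structure, schedule, n_frames)
    } else {
      base <- as.numeric(t(coords(structure)))
      xyz <- matrix(rep(base, each = n_frames), nrow = n_frames)
    }
    if (schedule$noise_sigma > 0)
      xyz <- xyz + stats::rnorm(length(xyz), 0, schedule$noise_sigma)
    traj <- cg_trajectory(structure, xyz, frame_interval_ns)
  })
  manifest <- list(seed = seed, n_frames = n_frames,
                   noise_sigma = schedule$noise_sigma,
                   constriction = schedule$constriction,
                   hinge_drift = schedule$hinge_drift,
                   unfold = schedule$unfold)
  if (!is.null(meta)) {
    manifest$base_angles <- lapply(meta$geom, function(g)
      list(PAS = g$PAS$theta0, CNBD = g$CNBD$theta0))
  }
  attr(traj, "manifest") <- manifest
  traj
}

.channel_frames <- function(structure, meta, schedule, n_frames) {
  a <- structure$atoms
  base <- coords(structure)
  nat <- nrow(base)
  out <- matrix(NA_real_, n_frames, 3L * nat)
  spec <- meta$spec_obj
  # pre-draw per-frame angle noise so the draw order is stable
  ang_noise <- if (!is.null(schedule$hinge_drift) &&
                   schedule$hinge_drift$noise_sd > 0) {
    matrix(stats::rnorm(n_frames * 2L * length(meta$chains), 0,
                        schedule$hinge_drift$noise_sd),
           nrow = n_frames)
  } else matrix(0, n_frames, 2L * length(meta$chains))
  for (i in seq_len(n_frames)) {
    frac <- (i - 0.5) / n_frames
    xyz <- base
    if (!is.null(schedule$constriction)) {
      cs <- schedule$constriction
      g <- .ramp(frac, cs$ramp)
      scale <- 1 - (1 - cs$final_scale) * g
      for (ch in meta$chains) {
        rowsel <- which(a$chain == ch & a$role == "pore")
        ring <- meta$pore[[ch]]
        sel <- ring$z < cs$z_below
        if (any(sel)) {
          R <- ring$R0[sel] * scale
          th <- ring$theta[sel] * pi / 180
          xyz[rowsel[sel], 1L] <- R * cos(th)
          xyz[rowsel[sel], 2L] <- R * sin(th)
        }
      }
    }
    if (!is.null(schedule$hinge_drift)) {
      hd <- schedule$hinge_drift
      g <- .ramp(frac, hd$ramp)
      col <- 0L
      for (ch in meta$chains) for (dm in c("PAS", "CNBD")) {
        col <- col + 1L
        delta <- hd[[dm]] * g + ang_noise[i, col]
        if (abs(delta) < 1e-12) next
        gg <- meta$geom[[ch]][[dm]]
        # v(phi) = len * (cos(phi) e1 + sin(phi) e2); angle = theta0 - phi
        phi <- -delta * pi / 180
        newc <- gg$hinge + gg$len * (cos(phi) * gg$e1 + sin(phi) * gg$e2)
        rowsel <- which(a$chain == ch & a$role == dm)
        oldc <- meta$geom[[ch]][[paste0(tolower(dm), "_center")]]
        xyz[rowsel, ] <- sweep(xyz[rowsel, , drop = FALSE], 2L,
                               newc - oldc, "+")
      }
    }
    out[i, ] <- as.numeric(t(xyz))
  }
  out
}

.unfold_frames <- function(structure, schedule, n_frames) {
  uf <- schedule$unfold
  resids <- sort(unique(structure$atoms$resid))
  n_res <- length(resids)
  seg <- which(resids >= uf$segment[1L] & resids <= uf$segment[2L])
  if (!length(seg)) stop("unfold segment matches no residues")
  phi <- rep(-57, n_res); psi <- rep(-47, n_res)
  phi[seg] <- stats::runif(length(seg), -180, 180)
  psi[seg] <- stats::runif(length(seg), -180, 180)
  unfolded <- build_backbone(n_res, phi, psi,
                             chain = structure$atoms$chain[1L],
                             resid_start = resids[1L])
  n_unf <- round(uf$fraction * n_frames)
  flags <- rep(FALSE, n_frames)
  if (n_unf > 0L) flags[sample.int(n_frames, n_unf)] <- TRUE
  folded_xyz <- as.numeric(t(coords(structure)))
  unfolded_xyz <- as.numeric(t(coords(unfolded)))
  out <- matrix(NA_real_, n_frames, length(folded_xyz))
  for (i in seq_len(n_frames))
    out[i, ] <- if (flags[i]) unfolded_xyz else folded_xyz
  attr(out, "unfolded_frames") <- which(flags)
  out
}

#' Synthetic Gaussian energy series
#'
#' Seeded Gaussian draws emulating the per-frame total and dihedral
#' potential energies of an equilibration run.
#'
#' @param mu_total,sigma_total,mu_dihedral,sigma_dihedral Gaussian
#'   parameters (kcal/mol).
#' @param n number of frames.
#' @param seed RNG seed.
#' @param frame_interval_ns snapshot interval.
#' @return a [cg_energy_series()] with `attr(, "manifest")` recording
#'   the parameters.
#' @export
make_energy_series <- function(mu_total, sigma_total, mu_dihedral,
                               sigma_dihedral, n, seed = 1L,
                               frame_interval_ns = 0.01) {
  if (n < 1L || sigma_total < 0 || sigma_dihedral < 0)
    stop("need n >= 1 and non-negative sigmas")
  es <- .with_seed(seed, cg_energy_series(
    stats::rnorm(n, mu_total, sigma_total),
    stats::rnorm(n, mu_dihedral, sigma_dihedral),
    frame_interval_ns))
  attr(es, "manifest") <- list(mu_total = mu_total, sigma_total = sigma_total,
                               mu_dihedral = mu_dihedral,
                               sigma_dihedral = sigma_dihedral,
                               n = n, seed = seed)
  es
}

#' Write a trajectory's ground-truth manifest as JSON
#' @param x an object carrying a `manifest` attribute.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  m <- attr(x, "manifest")
  if (is.null(m)) stop("object has no manifest")
  jsonlite::write_json(m, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Synthetic study presets
#'
#' Pre-wired condition pairs for the wildtype-vs-mutant comparison:
#' `"null"` (both conditions static apart from thermal noise),
#' `"collapse"`, `"hinge"`, `"unfold"` (one phenomenon each in the
#' mutant condition), and `"collapse+hinge+unfold"` (all three,
#' mirroring the trafficking-deficient phenotype: pore collapse below
#' the filter, -20 deg PAS / +10 deg CNBD hinge drift, and a linker
#' helix unfolded in half the frames).
#'
#' @param preset preset name.
#' @param seed integer seed; condition-specific streams are derived
#'   from it.
#' @param n_frames frames per trajectory (default 60).
#' @param n_res_peptide peptide length for the unfolding fixture
#'   (default 40; the unfolded segment is residues 10-34).
#' @return list with `conditions` (each: `channel`, `peptide`,
#'   `energies`) and `manifest`.
#' @export
synth_preset <- function(preset = c("null", "collapse", "hinge", "unfold",
                                    "collapse+hinge+unfold"),
                         seed = 1L, n_frames = 60L, n_res_peptide = 40L) {
  preset <- match.arg(preset)
  want <- function(x) grepl(x, preset, fixed = TRUE)
  base <- make_channel()
  helix <- make_ideal_helix(n_res_peptide)
  wt_sched <- motion_schedule(noise_sigma = 0.05)
  mut_parts <- list(noise_sigma = 0.05)
  if (want("collapse"))
    mut_parts$constriction <- list(z_below = 8, final_scale = 0.5,
                                   ramp = "plateau")
  if (want("hinge"))
    mut_parts$hinge_drift <- list(PAS = -20, CNBD = 10, noise_sd = 2,
                                  ramp = "plateau")
  mut_sched <- do.call(motion_schedule, mut_parts)
  unfold_sched <- if (want("unfold"))
    motion_schedule(unfold = list(segment = c(10L, 34L), fraction = 0.5),
                    noise_sigma = 0.02)
  else motion_schedule(noise_sigma = 0.02)
  conditions <- list(
    wildtype = list(
      channel = make_trajectory(base, wt_sched, n_frames, seed = seed),
      peptide = make_trajectory(helix, motion_schedule(noise_sigma = 0.02),
                                n_frames, seed = seed + 1L),
      energies = make_energy_series(-120000, 300, -1500, 40, 2000,
                                    seed = seed + 2L)),
    mutant = list(
      channel = make_trajectory(base, mut_sched, n_frames, seed = seed + 3L),
      peptide = make_trajectory(helix, unfold_sched, n_frames,
                                seed = seed + 4L),
      energies = make_energy_series(-119000, 300, -1450, 40, 2000,
                                    seed = seed + 5L)))
  list(conditions = conditions,
       manifest = list(preset = preset, seed = seed, n_frames = n_frames,
                       mutant_schedule = unclass(mut_sched),
                       unfold_schedule = unclass(unfold_sched)))
}
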