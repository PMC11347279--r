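test_that("Kabsch superposition recovers exact rigid motions", {
  set.seed(1)
  P <- matrix(rnorm(30), 10)
  fit0 <- kabsch_superpose(P, P)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  for (s in 1:5) {
    tf <- random_rigid(s)
    Q <- apply_rigid(P, tf)
    fit <- kabsch_superpose(Q, P)
    expect_lt(fit$rmsd, 1e-8)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
})

test_that("Kabsch equals a brute-force rotation search on displaced points", {
  set.seed(7)
  for (s in 1:4) {
    A <- matrix(rnorm(12, sd = 3), 4)
    B <- A
    B[1, ] <- B[1, ] + rnorm(3)
    tf <- random_rigid(s + 10)
    B <- apply_rigid(B, tf)
    expect_equal(kabsch_superpose(B, A)$rmsd, oracle_superpose_rmsd(B, A),
                 tolerance = 1e-6)
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line + rnorm(15, sd = 1e-12), line),
               "collinear")
})

test_that("rmsd_series: zeros on static input and d/sqrt(N) closed form", {
  top <- make_ideal_helix(10)
  tr <- traj_from_frames(top, rep(list(coords(top)), 4))
  r <- rmsd_series(tr, fit_sel = cg_selection(backbone_only = TRUE))
  expect_equal(r$rmsd, rep(0, 4), tolerance = 1e-9)
  # displace one atom by d without refitting: measure-only selection
  d <- 1.7
  x2 <- coords(top)
  x2[5, 1] <- x2[5, 1] + d
  n <- n_atoms(top)
  tr2 <- traj_from_frames(top, list(coords(top), x2))
  # fit on the untouched atoms so the fit is exactly identity
  fit_sel <- cg_selection(res_range = c(4, 10))
  all_sel <- cg_selection()
  stopifnot(!(5 %in% resolve_selection(top, fit_sel)))
  r2 <- rmsd_series(tr2, fit_sel = fit_sel, measure_sel = all_sel,
                    mass_weighted = FALSE)
  expect_equal(r2$rmsd[2], d / sqrt(n), tolerance = 1e-9)
})

test_that("rmsd_series equals per-frame Kabsch rmsd when fit = measure", {
  top <- make_ideal_helix(12)
  set.seed(3)
  frames <- lapply(1:5, function(i)
    coords(top) + matrix(rnorm(n_atoms(top) * 3, sd = 0.3), ncol = 3))
  tr <- traj_from_frames(top, frames)
  r <- rmsd_series(tr, ref = top, fit_sel = cg_selection(), mass_weighted = FALSE)
  direct <- vapply(frames, function(fr)
    kabsch_superpose(fr, coords(top))$rmsd, numeric(1))
  expect_equal(r$rmsd, direct, tolerance = 1e-10)
})

test_that("ligand RMSD isolates pose drift from global motion", {
  prot <- make_ideal_helix(10)
  lig_at <- data.frame(serial = 0L, name = paste0("L", 1:4), element = "C",
                       resname = "LIG", resid = 500L, chain = "X",
                       x = c(20, 22, 20, 22), y = c(0, 0, 2, 2), z = 0,
                       vdw = 1.7, mass = 12.011)
  full <- cg_structure(rbind(prot$atoms, lig_at))
  lig_sel <- cg_selection(chains = "X")
  fit_sel <- cg_selection(chains = "A")
  # unmoved ligand
  tr <- traj_from_frames(full, list(coords(full)))
  expect_equal(ligand_rmsd(tr, lig_sel, full, fit_sel)$rmsd, 0,
               tolerance = 1e-9)
  # ligand translated 2 A while protein fixed
  x2 <- coords(full)
  li <- resolve_selection(full, lig_sel)
  x2[li, 3] <- x2[li, 3] + 2
  tr2 <- traj_from_frames(full, list(x2))
  expect_equal(ligand_rmsd(tr2, lig_sel, full, fit_sel)$rmsd, 2,
               tolerance = 1e-9)
  # whole complex rotated rigidly: fit removes it
  tf <- random_rigid(4)
  tr3 <- traj_from_frames(full, list(apply_rigid(coords(full), tf)))
  expect_lt(ligand_rmsd(tr3, lig_sel, full, fit_sel)$rmsd, 1e-8)
  # name mismatch is reported
  bad <- full
  bad$atoms$name[li[1]] <- "LX"
  trb <- traj_from_frames(bad, list(coords(bad)))
  expect_error(ligand_rmsd(trb, lig_sel, full, fit_sel), "mismatch")
})

test_that("RMSF: zeros when static, closed form for antiphase oscillation", {
  top <- make_ideal_helix(8)
  tr <- traj_from_frames(top, rep(list(coords(top)), 5))
  pr <- rmsf_profile(tr)
  expect_equal(pr$rmsf, rep(0, 8), tolerance = 1e-10)
  # two single-atom residues oscillating in antiphase about a symmetric
  # frame: no net translation or rotation, RMSF exactly the amplitude
  a <- 0.8
  base <- rbind(c(5, 0, 0), c(-5, 0, 0), c(0, 5, 0), c(0, -5, 0))
  top2 <- pseudo_structure(base)
  mk <- function(s) {
    x <- base
    x[1, 1] <- x[1, 1] + s * a
    x[2, 1] <- x[2, 1] - s * a
    x
  }
  tr2 <- traj_from_frames(top2, list(mk(1), mk(-1), mk(1), mk(-1)))
  pr2 <- rmsf_profile(tr2, sel = cg_selection())
  expect_equal(pr2$rmsf, c(a, a, 0, 0), tolerance = 1e-9)
})

test_that("RMSF is invariant to rigid motion injected into every frame", {
  set.seed(11)
  base <- matrix(rnorm(60, sd = 3), 20)
  top <- pseudo_structure(base)
  frames <- lapply(1:30, function(i) base + matrix(rnorm(60, sd = 0.2), 20))
  tr <- traj_from_frames(top, frames)
  pr <- rmsf_profile(tr, sel = cg_selection())
  frames_moved <- lapply(seq_along(frames), function(i)
    apply_rigid(frames[[i]], random_rigid(100 + i)))
  pr2 <- rmsf_profile(traj_from_frames(top, frames_moved), sel = cg_selection())
  expect_equal(pr$rmsf, pr2$rmsf, tolerance = 1e-6)
})

test_that("monomer-averaged RMSF recovers per-chain noise scale", {
  # 4 chains, 10 one-atom residues each, chain-specific noise sigma;
  # residue RMSF expectation is sigma * sqrt(3) (3 coordinates)
  sig <- c(A = 0.2, B = 0.3, C = 0.4, D = 0.5)
  at <- do.call(rbind, lapply(names(sig), function(ch) {
    set.seed(match(ch, names(sig)))
    xyz <- matrix(rnorm(30, sd = 8), 10)
    data.frame(serial = 0L, name = "C1", element = "C", resname = "DUM",
               resid = 1:10, chain = ch, x = xyz[, 1], y = xyz[, 2],
               z = xyz[, 3], vdw = 1.5, mass = 12)
  }))
  at$serial <- seq_len(nrow(at))
  top <- cg_structure(at)
  set.seed(99)
  sd_per_atom <- rep(sig, each = 10)
  frames <- lapply(1:500, function(i)
    coords(top) + matrix(rnorm(120, sd = sd_per_atom), ncol = 3))
  pr <- rmsf_profile(traj_from_frames(top, frames), sel = cg_selection())
  expected <- mean(sig) * sqrt(3)
  expect_equal(mean(pr$rmsf), expected, tolerance = 0.1 * expected)
})

test_that("low-RMSF anchors select the engineered valley and obey ties", {
  prof <- data.frame(resid = 1:100, rmsf = 2 + 0.01 * (1:100))
  prof$rmsf[31:50] <- 0.5          # one deep flat 20-residue valley
  class(prof) <- c("cg_rmsf_profile", "data.frame")
  sel <- low_rmsf_anchors(prof, quantile = 0.2)
  segs <- attr(sel, "segments")
  expect_equal(nrow(segs), 1L)
  expect_equal(c(segs$from, segs$to), c(31L, 50L))
  # uniform profile: ties resolved towards low residue numbers
  prof2 <- data.frame(resid = 1:40, rmsf = rep(1, 40))
  class(prof2) <- c("cg_rmsf_profile", "data.frame")
  sel2 <- low_rmsf_anchors(prof2, quantile = 0.25)
  expect_equal(attr(sel2, "segments")$from, 1L)
  expect_equal(attr(sel2, "segments")$to, 10L)
  # quantile too small for the minimum segment length: empty + warning
  prof3 <- data.frame(resid = 1:100, rmsf = sin(1:100))
  class(prof3) <- c("cg_rmsf_profile", "data.frame")
  expect_warning(sel3 <- low_rmsf_anchors(prof3, quantile = 0.02),
                 "no contiguous")
  expect_equal(nrow(attr(sel3, "segments")), 0L)
})
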