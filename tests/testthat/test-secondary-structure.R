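test_that("amide H reconstruction follows the bisector geometry", {
  h <- make_ideal_helix(10)
  hh <- reconstruct_amide_H(h)
  Hs <- hh$atoms[hh$atoms$name == "H", ]
  expect_equal(nrow(Hs), 9L)          # no H on the chain start
  for (rid in Hs$resid) {
    res <- hh$atoms[hh$atoms$resid == rid, ]
    prev <- hh$atoms[hh$atoms$resid == rid - 1, ]
    N <- unlist(res[res$name == "N", c("x", "y", "z")])
    H <- unlist(res[res$name == "H", c("x", "y", "z")])
    CA <- unlist(res[res$name == "CA", c("x", "y", "z")])
    Cp <- unlist(prev[prev$name == "C", c("x", "y", "z")])
    expect_equal(sqrt(sum((H - N)^2)), 1.01, tolerance = 1e-9)
    u1 <- (Cp - N) / sqrt(sum((Cp - N)^2))
    u2 <- (CA - N) / sqrt(sum((CA - N)^2))
    bis <- (u1 + u2) / sqrt(sum((u1 + u2)^2))
    nh <- (H - N) / 1.01
    ang <- acos(max(-1, min(1, sum(-bis * nh)))) * 180 / pi
    expect_lt(ang, 5)
  }
})

test_that("prolines and chain starts receive no amide H", {
  h <- build_backbone(6, -57, -47, resname = "ALA")
  h$atoms$resname[h$atoms$resid == 3] <- "PRO"
  hh <- reconstruct_amide_H(h)
  got <- hh$atoms$resid[hh$atoms$name == "H"]
  expect_false(1 %in% got)
  expect_false(3 %in% got)
  expect_true(all(c(2, 4, 5, 6) %in% got))
})

test_that("Kabsch-Sander energies: helix bond, long-range decay, cancellation", {
  hh <- reconstruct_amide_H(make_ideal_helix(12))
  geta <- function(rid, nm) {
    a <- hh$atoms
    unlist(a[a$resid == rid & a$name == nm, c("x", "y", "z")])
  }
  e <- hbond_energy(donor = list(N = geta(8, "N"), H = geta(8, "H")),
                    acceptor = list(C = geta(4, "C"), O = geta(4, "O")))
  expect_lt(e, -0.5)
  # 40 A apart: the 1/r terms cancel to within 0.05 kcal/mol
  far <- hbond_energy(donor = list(N = c(40, 0, 0), H = c(40.9, 0, 0.4)),
                      acceptor = list(C = c(0, 0, 0), O = c(0, 1.2, 0)))
  expect_lt(abs(far), 0.05)
  # degenerate square: r_ON = r_CH = r_OH = r_CN -> exactly 0
  d <- 2
  sq <- hbond_energy(donor = list(N = c(0, 0, 0), H = c(1, 0, 0)),
                     acceptor = list(O = c(0.5, d, 0), C = c(0.5, -d, 0)))
  expect_equal(sq, 0, tolerance = 1e-12)
  # clash clamp
  cl <- hbond_energy(donor = list(N = c(0, 0, 0), H = c(0.1, 0, 0)),
                     acceptor = list(O = c(0.2, 0, 0), C = c(1.4, 0, 0)))
  expect_equal(as.numeric(cl), -9.9)
})

test_that("ideal helix is assigned H in the interior, extended strand is coil", {
  ss <- assign_ss(make_ideal_helix(20))
  helical <- ss$resid[ss$ss == "H"]
  expect_true(all(3:15 %in% helical))
  expect_false(1 %in% helical)
  expect_false(any(c(19, 20) %in% helical))
  ss2 <- assign_ss(make_extended_chain(15))
  expect_true(all(ss2$ss == "C"))
})

test_that("a randomised middle segment loses its helix assignment", {
  set.seed(12)
  n <- 24
  phi <- rep(-57, n); psi <- rep(-47, n)
  seg <- 10:15
  phi[seg] <- runif(6, -180, 180)
  psi[seg] <- runif(6, -180, 180)
  ss <- assign_ss(build_backbone(n, phi, psi))
  expect_true(all(ss$ss[seg] == "C"))
  # helix persists where the i -> i+4 pattern is untouched: turns up to
  # residue 5 only involve residues 1..9
  expect_true(all(ss$ss[3:6] == "H"))
  expect_true(all(ss$ss[17:19] == "H"))  # downstream run re-forms
})

test_that("secondary structure is invariant under rigid motion", {
  h <- make_ideal_helix(15)
  ss <- assign_ss(h)
  h2 <- h
  coords(h2) <- apply_rigid(coords(h), random_rigid(3))
  expect_identical(assign_ss(h2)$ss, ss$ss)
})

test_that("helix propensity recovers a 50% unfolding schedule", {
  helix <- make_ideal_helix(40)
  sched <- motion_schedule(unfold = list(segment = c(10, 34), fraction = 0.5),
                           noise_sigma = 0.02)
  tr <- make_trajectory(helix, sched, n_frames = 60, seed = 17)
  hp <- helix_propensity(tr)
  interior <- hp$resid >= 14 & hp$resid <= 30
  expect_equal(mean(hp$propensity[interior]), 0.5, tolerance = 0.05)
  # propensities are proportions of frames
  expect_true(all(hp$propensity >= 0 & hp$propensity <= 1))
  expect_true(all(abs(hp$propensity * 60 - round(hp$propensity * 60)) < 1e-9))
  # untouched flank (whose turn context stays inside residues 1..9)
  expect_gt(mean(hp$propensity[hp$resid %in% 3:6]), 0.9)
})

test_that("static helix gives unit interior propensity", {
  helix <- make_ideal_helix(20)
  tr <- make_trajectory(helix, motion_schedule(noise_sigma = 0),
                        n_frames = 10, seed = 1)
  hp <- helix_propensity(tr)
  expect_equal(hp$propensity[hp$resid %in% 4:14], rep(1, 11))
})

test_that("per-residue delta localises helix loss to the unfolded linker", {
  helix <- make_ideal_helix(40)
  wt <- make_trajectory(helix, motion_schedule(noise_sigma = 0.02),
                        n_frames = 20, seed = 5)
  mut <- make_trajectory(helix,
                         motion_schedule(unfold = list(segment = c(10, 34),
                                                       fraction = 1),
                                         noise_sigma = 0.02),
                         n_frames = 20, seed = 6)
  hp_wt <- helix_propensity(wt)
  hp_mut <- helix_propensity(mut, reference = hp_wt)
  lost <- hp_mut$resid[!is.na(hp_mut$delta) & hp_mut$delta < -0.5]
  # helix loss concentrates in the programmed segment plus the <= 4
  # residues of turn context the helix pattern needs on each side
  expect_true(all(lost >= 10 - 4 & lost <= 34 + 4))
  expect_true(all(12:32 %in% lost))
})
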