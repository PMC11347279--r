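ring_xyz <- function(R, z, n = 24, phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(R * cos(th), R * sin(th), z)
}

test_that("slice radius: analytic ring, on-axis occlusion, open window", {
  ax <- cg_pore_axis()
  ring <- ring_xyz(5, 0, n = 12)
  s <- slice_radius(ring, rep(1.5, 12), ax, 0)
  expect_equal(s$radius, 3.5, tolerance = 0.02)
  expect_equal(s$status, "ok")
  # single atom sitting on the axis: occlusion depth -vdw, flagged escaped
  s2 <- slice_radius(matrix(c(0, 0, 0), 1), 1.7, ax, 0)
  expect_equal(s2$radius, -1.7)
  expect_equal(s2$status, "escaped")
  # nothing anywhere near the slice: open, capped at the search radius
  s3 <- slice_radius(matrix(c(0, 0, 50), 1), 1.7, ax, 0)
  expect_equal(s3$radius, 10)
  expect_equal(s3$status, "open")
})

test_that("hourglass profile matches its analytic target within 0.1 A", {
  # the exact inscribed-sphere profile of a ring stack is the erosion
  # min_k sqrt(R(z_k)^2 + (z_k - z)^2) - r_atom: near a narrow waist it
  # is wider than the naive R(z) - r_atom because the sphere spans the
  # waist shoulders
  Rz <- function(z) 6 - 3 * exp(-z^2 / 8)
  ring_z <- seq(-7, 7, by = 0.5)
  ch <- make_channel(channel_spec(radius = Rz, z_range = c(-7, 7),
                                  ring_dz = 0.5, atoms_per_ring = 48))
  ax <- cg_pore_axis(z_range = c(-5, 5), dz = 1)
  pp <- pore_profile(ch, ax, sel = cg_selection(res_range = c(201, 9999)),
                     search_radius = 8)
  target <- vapply(pp$z, function(z)
    min(sqrt(Rz(ring_z)^2 + (ring_z - z)^2)) - 1.5, numeric(1))
  expect_lt(max(abs(pp$radius - target)), 0.1)
  expect_true(all(pp$status == "ok"))
  # the waist itself, where the sphere sits inside its own ring, does
  # meet the naive R(0) - r target
  expect_equal(pp$radius[pp$z == 0], Rz(0) - 1.5, tolerance = 0.05)
})

test_that("uniform cylinder gives a flat profile; empty mouths read open", {
  zs <- seq(-5, 5, by = 1)
  xyz <- do.call(rbind, lapply(zs, function(z) ring_xyz(4, z, n = 36)))
  ax <- cg_pore_axis(z_range = c(-4, 4), dz = 0.5)
  pp <- pore_profile(list(xyz = xyz, radii = rep(1.5, nrow(xyz))), ax,
                     search_radius = 8)
  expect_lt(stats::sd(pp$radius), 0.05)
  ax2 <- cg_pore_axis(z_range = c(-30, 30), dz = 10)
  pp2 <- pore_profile(list(xyz = xyz, radii = rep(1.5, nrow(xyz))), ax2,
                      search_radius = 8)
  expect_equal(pp2$status[c(1, length(pp2$status))], c("open", "open"))
})

test_that("slice search is equivariant under joint rigid transforms", {
  set.seed(5)
  xyz <- do.call(rbind, lapply(c(-2, 0, 2), function(z)
    ring_xyz(4 + runif(1), z, n = 20, phase = runif(1))))
  radii <- rep(1.5, nrow(xyz))
  base <- slice_radius(xyz, radii, cg_pore_axis(), 1)$radius
  for (s in 1:3) {
    tf <- random_rigid(s + 40)
    ax2 <- cg_pore_axis(point = as.numeric(tf$t),
                        direction = as.numeric(c(0, 0, 1) %*% t(tf$R)))
    moved <- slice_radius(apply_rigid(xyz, tf), radii, ax2, 1)$radius
    expect_equal(moved, base, tolerance = 1e-6)
  }
})

test_that("deleting an atom never decreases the slice radius", {
  set.seed(9)
  xyz <- do.call(rbind, lapply(c(-1, 0, 1), function(z)
    ring_xyz(3.5, z, n = 24)))
  radii <- rep(1.5, nrow(xyz))
  ax <- cg_pore_axis()
  full <- slice_radius(xyz, radii, ax, 0)$radius
  for (drop in sample(nrow(xyz), 5)) {
    red <- slice_radius(xyz[-drop, ], radii[-drop], ax, 0)$radius
    expect_gte(red + 1e-9, full)
  }
})

test_that("refined optimum dominates a fine brute-force grid on enclosed slices", {
  for (s in 1:5) {
    set.seed(s)
    n <- 50
    th <- runif(n, 0, 2 * pi)
    lat <- runif(n, 3.5, 5.5)
    xyz <- cbind(lat * cos(th), lat * sin(th), rnorm(n, sd = 0.5))
    radii <- runif(n, 1.2, 1.8)
    mine <- slice_radius(xyz, radii, cg_pore_axis(), 0,
                         search_radius = 6)$radius_max
    orc <- oracle_slice_radius(xyz, radii, 0, search_radius = 6)
    expect_gte(mine, orc - 0.05)
  }
})

test_that("pore timeseries tracks a programmed linear constriction", {
  # ring radius 6.5 -> 4.5 linearly, so the measured pore radius runs
  # 5 -> 3 with mean 4
  spec <- channel_spec(radius = 6.5, z_range = c(-6, 6), atoms_per_ring = 40)
  ch <- make_channel(spec)
  sched <- motion_schedule(constriction = list(z_below = Inf,
                                               final_scale = 4.5 / 6.5,
                                               ramp = "linear"),
                           noise_sigma = 0)
  tr <- make_trajectory(ch, sched, n_frames = 25, seed = 2)
  ax <- cg_pore_axis(z_range = c(-5, 5), dz = 1)
  ts <- pore_timeseries(tr, ax, sel = cg_selection(res_range = c(201, 999)),
                        search_radius = 8)
  expect_equal(mean(ts$mean), 4, tolerance = 0.1)
  frac <- (seq_len(25) - 0.5) / 25
  expected_min <- 6.5 * (1 - (1 - 4.5 / 6.5) * frac) - 1.5
  expect_lt(max(abs(ts$min_radius - expected_min)), 0.1)
  # static trajectory: sd identically zero
  tr2 <- make_trajectory(ch, motion_schedule(noise_sigma = 0),
                         n_frames = 3, seed = 2)
  ts2 <- pore_timeseries(tr2, ax, sel = cg_selection(res_range = c(201, 999)),
                         search_radius = 8)
  expect_equal(max(ts2$sd), 0, tolerance = 1e-9)
})

test_that("two-regime constriction localises below the marked filter z", {
  ch <- make_channel(channel_spec(z_range = c(-10, 10)))
  sched <- motion_schedule(constriction = list(z_below = 0, final_scale = 0.5,
                                               ramp = "step"),
                           noise_sigma = 0)
  tr <- make_trajectory(ch, sched, n_frames = 2, seed = 1)
  ax <- cg_pore_axis(z_range = c(-8, 8), dz = 2)
  ts <- pore_timeseries(tr, ax, sel = cg_selection(res_range = c(201, 999)),
                        search_radius = 8)
  below <- ts$z <= -2
  above <- ts$z >= 4   # beyond the reach of the collapsed rings' spheres
  expect_lt(max(ts$radius[2, below]), 1.5)   # collapsed half
  expect_equal(ts$radius[2, above],
               ts$radius[1, above], tolerance = 0.05)  # untouched half
})
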