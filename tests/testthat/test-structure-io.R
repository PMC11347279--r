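test_that("glycan composition parsing handles counts, implicit counts and errors", {
  g <- parse_glycan_composition("Glc3Man9GlcNAc2")
  expect_equal(unname(g$counts[c("Glc", "Man", "GlcNAc")]), c(3L, 9L, 2L))
  expect_equal(g$total, 14L)
  expect_equal(parse_glycan_composition("Man")$counts[["Man"]], 1L)
  expect_equal(parse_glycan_composition("Man")$total, 1L)
  expect_error(parse_glycan_composition("Xyz5"), "unparseable")
  # property: total is the sum of per-token counts for random strings
  vocab <- c("Glc", "Man", "GlcNAc", "Fuc", "NeuAc", "Xyl")
  for (s in 1:10) {
    set.seed(s)
    k <- sample(2:5, 1)
    toks <- sample(vocab, k)
    cnt <- sample(1:9, k, replace = TRUE)
    str <- paste0(toks, cnt, collapse = "")
    expect_equal(parse_glycan_composition(str)$total, sum(cnt))
  }
})

test_that("single-record PDB reads with Bondi radius and element lookup", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  s <- read_structure(f)
  expect_equal(n_atoms(s), 1L)
  expect_equal(s$atoms$vdw, 1.7)
  expect_equal(s$atoms$mass, 12.011)
})

test_that("synthetic tetramer round-trips through PDB with 4 equal chains", {
  ch <- make_channel()
  f <- tempfile(fileext = ".pdb")
  write_structure(ch, f)
  s2 <- read_structure(f)
  expect_equal(length(unique(s2$atoms$chain)), 4L)
  expect_equal(unname(table(s2$atoms$chain)), rep(n_atoms(ch) / 4, 4),
               ignore_attr = TRUE)
  expect_lt(max(abs(coords(s2) - coords(ch))), 1e-3 + 1e-9)
})

test_that("duplicate atom identity and malformed records are rejected", {
  at <- data.frame(serial = 1:2, name = "CA", element = "C", resname = "ALA",
                   resid = 1L, chain = "A", x = 0, y = 0, z = c(0, 1),
                   vdw = 1.7, mass = 12)
  expect_error(cg_structure(at), "duplicate atom identity")
  f <- tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  C1  LIG A   1       0.000   0.000",
               "END"), f)
  expect_error(read_structure(f), "line 1")
})

test_that("multi-model PDB trajectories round-trip and truncation errors", {
  top <- make_ideal_helix(6)
  frames <- lapply(1:3, function(i) coords(top) + i * 0.5)
  tr <- traj_from_frames(top, frames)
  f <- tempfile(fileext = ".pdb")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f, top)
  expect_equal(n_frames(tr2), 3L)
  expect_lt(max(abs(tr2$xyz - tr$xyz)), 1e-3 + 1e-9)
  # same structure repeated three times reads as identical frames
  tr3 <- traj_from_frames(top, rep(list(coords(top)), 3))
  f3 <- tempfile(fileext = ".pdb")
  write_trajectory(tr3, f3)
  tr3r <- read_trajectory(f3, top)
  expect_equal(tr3r$xyz[1, ], tr3r$xyz[3, ])
  # truncated file: drop everything after the second MODEL's 10th atom
  lines <- readLines(f)
  cut <- grep("^MODEL", lines)[2] + 10
  f4 <- tempfile(fileext = ".pdb")
  writeLines(lines[1:cut], f4)
  expect_error(read_trajectory(f4, top), "truncated")
})

test_that("DCD writing is read back exactly (float32) by an independent reader", {
  top <- make_ideal_helix(8)
  set.seed(42)
  frames <- lapply(1:5, function(i)
    coords(top) + matrix(rnorm(n_atoms(top) * 3), ncol = 3))
  tr <- traj_from_frames(top, frames)
  f <- tempfile(fileext = ".dcd")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f, top)   # via bio3d::read.dcd
  expect_equal(n_frames(tr2), 5L)
  expect_lt(max(abs(tr2$xyz - tr$xyz)), 1e-5)  # float32 quantisation
  # second round trip is bitwise stable
  f2 <- tempfile(fileext = ".dcd")
  write_trajectory(tr2, f2)
  tr3 <- read_trajectory(f2, top)
  expect_identical(tr3$xyz, tr2$xyz)
})

test_that("trajectory atom-count mismatches report both counts", {
  top <- make_ideal_helix(8)
  small <- make_ideal_helix(6)
  tr <- traj_from_frames(small, list(coords(small)))
  f <- tempfile(fileext = ".pdb")
  write_trajectory(tr, f)
  expect_error(read_trajectory(f, top), "24.*32|32.*24")
})

test_that("selection resolution is deterministic, composable and warns when empty", {
  pep <- make_ideal_helix(5)
  expect_length(resolve_selection(pep, cg_selection(backbone_only = TRUE)), 20L)
  seg <- cg_selection(res_range = c(2, 4))
  expect_length(resolve_selection(pep, seg), 12L)
  expect_warning(idx <- resolve_selection(pep, cg_selection(atom_names = "ZZ")),
                 "no atoms")
  expect_length(idx, 0L)
  # idempotent / order-independent: same criteria, same result
  a <- resolve_selection(pep, cg_selection(chains = "A", res_range = c(1, 3),
                                           backbone_only = TRUE))
  b <- resolve_selection(pep, cg_selection(res_range = c(1, 3), chains = "A",
                                           backbone_only = TRUE))
  expect_identical(a, b)
  expect_identical(a, sort(a))
})

test_that("domain/hinge overlap is detected", {
  h <- cg_domain("hinge", c(30, 40))
  a <- cg_domain("PAS", c(1, 29))
  b <- cg_domain("TMD", c(41, 100))
  expect_true(check_domain_disjoint(h, a, b))
  expect_error(check_domain_disjoint(cg_domain("hinge", c(25, 40)), a, b),
               "overlaps")
})
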