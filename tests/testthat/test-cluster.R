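test_that("pairwise RMSD: zeros for identical or rigidly-moved frames", {
  top <- pseudo_structure(matrix(rnorm(30, sd = 3), 10))
  base <- coords(top)
  tr <- traj_from_frames(top, rep(list(base), 3))
  expect_true(all(pairwise_rmsd(tr)$D < 1e-10))
  moved <- lapply(1:3, function(i) apply_rigid(base, random_rigid(i)))
  expect_true(all(pairwise_rmsd(traj_from_frames(top, moved))$D < 1e-8))
})

test_that("pairwise RMSD matches frame-pair Kabsch oracle", {
  set.seed(21)
  top <- pseudo_structure(matrix(rnorm(36, sd = 3), 12))
  frames <- lapply(1:6, function(i)
    coords(top) + matrix(rnorm(36, sd = 0.8), 12))
  tr <- traj_from_frames(top, frames)
  dm <- pairwise_rmsd(tr)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(dm$D[i, j],
                 kabsch_superpose(frames[[i]], frames[[j]])$rmsd,
                 tolerance = 1e-10)
  }
})

test_that("average linkage separates two tight blobs and handles edge k", {
  D <- matrix(10, 10, 10)
  D[1:5, 1:5] <- 0.5; D[6:10, 6:10] <- 0.5
  diag(D) <- 0
  lab <- average_linkage(D, 2)
  expect_equal(lab[1:5], rep(1L, 5))
  expect_equal(lab[6:10], rep(2L, 5))
  expect_equal(average_linkage(D, 10), 1:10)
  expect_error(average_linkage(D, 0), "k must be")
  expect_error(average_linkage(D, 11), "k must be")
})

test_that("average linkage agrees with a naive O(n^3) reference", {
  for (s in 1:20) {
    n <- sample(8:12, 1)
    D <- random_distmat(n, seed = 300 + s)
    for (k in c(2, 3, max(2, n %/% 2))) {
      expect_identical(average_linkage(D, k), oracle_upgma(D, k))
    }
  }
})

test_that("average linkage is invariant to frame order up to relabelling", {
  D <- random_distmat(12, seed = 77)
  lab <- average_linkage(D, 3)
  set.seed(78)
  perm <- sample(12)
  lab_p <- average_linkage(D[perm, perm], 3)
  # memberships must agree after undoing the permutation
  expect_equal(length(unique(paste(lab[perm], lab_p))), 3L)
})

test_that("Davies-Bouldin closed forms and degeneracies", {
  # two 3-member clusters, S1 = S2 = 1, medoid separation 10 -> DBI 0.2
  D <- matrix(10, 6, 6)
  D[1:3, 1:3] <- matrix(c(0, 1.5, 1.5, 1.5, 0, 2.9, 1.5, 2.9, 0), 3)
  D[4:6, 4:6] <- matrix(c(0, 1.5, 1.5, 1.5, 0, 2.9, 1.5, 2.9, 0), 3)
  lab <- c(1, 1, 1, 2, 2, 2)
  expect_equal(davies_bouldin(D, lab), 0.2, tolerance = 1e-12)
  # perfectly tight clusters: S = 0 -> DBI 0
  D0 <- matrix(5, 4, 4); D0[1:2, 1:2] <- 0; D0[3:4, 3:4] <- 0; diag(D0) <- 0
  expect_equal(davies_bouldin(D0, c(1, 1, 2, 2)), 0)
  expect_error(davies_bouldin(D0, rep(1, 4)), "at least 2")
  Dd <- matrix(0, 4, 4)
  expect_error(davies_bouldin(Dd, c(1, 1, 2, 2)), "degenerate")
})

test_that("DBI and SSR/SST match independent formula evaluations", {
  for (s in 1:5) {
    D <- random_distmat(20, seed = 400 + s)
    set.seed(500 + s)
    lab <- sample(1:4, 20, replace = TRUE)
    lab <- match(lab, sort(unique(lab)))   # compact labels
    if (length(unique(lab)) < 2) next
    expect_equal(davies_bouldin(D, lab), oracle_dbi(D, lab),
                 tolerance = 1e-10)
    expect_equal(percent_variance(D, lab), oracle_ssr_sst(D, lab),
                 tolerance = 1e-10)
  }
})

test_that("percent variance spans [0, 1] between the trivial clusterings", {
  D <- random_distmat(9, seed = 9)
  expect_equal(percent_variance(D, rep(1, 9)), 0, tolerance = 1e-12)
  expect_equal(percent_variance(D, 1:9), 1, tolerance = 1e-12)
  # two-blob fixture against the independent oracle
  D2 <- matrix(8, 6, 6); D2[1:3, 1:3] <- 1; D2[4:6, 4:6] <- 1; diag(D2) <- 0
  lab <- c(1, 1, 1, 2, 2, 2)
  expect_equal(percent_variance(D2, lab), oracle_ssr_sst(D2, lab),
               tolerance = 1e-12)
})

test_that("choose_k finds the engineered elbow and flags featureless scans", {
  frames <- basin_frames(3, 12, seed = 31)
  top <- pseudo_structure(frames[[1]])
  dm <- pairwise_rmsd(traj_from_frames(top, frames))
  metrics <- scan_k(dm, 2:8)
  ch <- choose_k(metrics)
  expect_equal(ch$chosen_k, 3L)
  expect_equal(ch$status, "ok")
  # monotone featureless metrics: no plateau status
  m2 <- data.frame(k = 2:8, dbi = seq(1, 0.4, length.out = 7),
                   ssr_sst = seq(0.1, 0.9, length.out = 7))
  expect_equal(choose_k(m2)$status, "no plateau")
})

test_that("representatives are medoids with deterministic ties", {
  D <- matrix(0, 4, 4)
  D[1, 2] <- D[2, 1] <- 1; D[1, 3] <- D[3, 1] <- 1; D[2, 3] <- D[3, 2] <- 1
  D[4, 1:3] <- D[1:3, 4] <- 9
  rep_ <- representative_frames(D, c(1, 1, 1, 2))
  # symmetric 3-cycle: smallest index wins; singleton is its own medoid
  expect_equal(rep_$representative[rep_$cluster == 1], 1L)
  expect_equal(rep_$representative[rep_$cluster == 2], 4L)
  expect_equal(rep_$population, c(3L, 1L))
  # constructed known medoid
  D2 <- as.matrix(stats::dist(c(0, 1, 1.5, 3, 4)))
  rep2 <- representative_frames(D2, rep(1, 5))
  expect_equal(rep2$representative, 3L)
})
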