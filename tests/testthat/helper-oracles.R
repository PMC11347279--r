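# Independent oracles: deliberately naive implementations used only to
# check the package's optimised paths.

# Brute-force optimal-superposition RMSD: optimal translation via
# centroids, rotation by multi-start Nelder-Mead over Euler angles.
oracle_superpose_rmsd <- function(mobile, reference, weights = NULL) {
  n <- nrow(mobile)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  P <- sweep(mobile, 2, colSums(mobile * w))
  Q <- sweep(reference, 2, colSums(reference * w))
  rotmat <- function(a) {
    Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3)
    Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3)
    Rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3)
    Rz %*% Ry %*% Rx
  }
  obj <- function(a) {
    R <- rotmat(a)
    sqrt(sum(w * rowSums((P %*% t(R) - Q)^2)))
  }
  starts <- as.matrix(expand.grid(a1 = c(0, pi / 2, pi, 3 * pi / 2),
                                  a2 = c(0, pi / 2, pi),
                                  a3 = c(0, pi / 2, pi, 3 * pi / 2)))
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
    if (o$value < best) best <- o$value
  }
  best
}

# Exhaustive lateral-grid slice oracle (full window, no refinement).
oracle_slice_radius <- function(xyz, radii, z, search_radius = 6,
                                spacing = 0.05) {
  g <- seq(-search_radius, search_radius, by = spacing)
  gx <- rep(g, times = length(g)); gy <- rep(g, each = length(g))
  keep <- gx^2 + gy^2 <= search_radius^2
  gx <- gx[keep]; gy <- gy[keep]
  f <- rep(Inf, length(gx))
  for (i in seq_len(nrow(xyz))) {
    di <- sqrt((gx - xyz[i, 1])^2 + (gy - xyz[i, 2])^2 + (z - xyz[i, 3])^2) -
      radii[i]
    f <- pmin(f, di)
  }
  max(f)
}

# Naive O(n^3) UPGMA cut at k: recompute every inter-cluster average
# from the original matrix at each merge.
oracle_upgma <- function(D, k) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- NULL; bd <- Inf
    for (p in seq_len(length(clusters) - 1)) for (q in (p + 1):length(clusters)) {
      d <- mean(D[clusters[[p]], clusters[[q]]])
      tie_cand <- sort(c(min(clusters[[p]]), min(clusters[[q]])))
      if (d < bd - 1e-12) { bd <- d; best <- c(p, q); tie_best <- tie_cand
      } else if (abs(d - bd) <= 1e-12) {
        if (tie_cand[1] < tie_best[1] ||
            (tie_cand[1] == tie_best[1] && tie_cand[2] < tie_best[2])) {
          best <- c(p, q); tie_best <- tie_cand
        }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heads <- vapply(clusters, min, numeric(1))
  clusters <- clusters[order(heads)]
  lab <- integer(n)
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}

# Direct-formula Davies-Bouldin (medoid variant), written independently.
oracle_dbi <- function(D, labels) {
  labs <- sort(unique(labels))
  med <- S <- numeric(length(labs))
  for (i in seq_along(labs)) {
    m <- which(labels == labs[i])
    costs <- sapply(m, function(j) mean(D[j, m]))
    med[i] <- m[which.min(costs)]
    S[i] <- mean(D[m, med[i]])
  }
  k <- length(labs)
  mean(sapply(seq_len(k), function(i)
    max(sapply(seq_len(k)[-i], function(j) (S[i] + S[j]) / D[med[i], med[j]]))))
}

oracle_ssr_sst <- function(D, labels) {
  n <- nrow(D)
  sst <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) sst <- sst + D[i, j]^2
  sst <- sst / n
  sse <- 0
  for (l in unique(labels)) {
    m <- which(labels == l)
    if (length(m) > 1)
      for (i in seq_along(m)[-length(m)]) for (j in (i + 1):length(m))
        sse <- sse + D[m[i], m[j]]^2 / length(m)
  }
  if (sst == 0) return(0)
  (sst - sse) / sst
}

# random symmetric RMSD-like matrix
random_distmat <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(rnorm(n * 2, sd = 2), n)
  as.matrix(stats::dist(pts))
}

# small random rigid transform
random_rigid <- function(seed) {
  set.seed(seed)
  a <- runif(3, -pi, pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3)
  Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3)
  Rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3)
  list(R = Rz %*% Ry %*% Rx, t = runif(3, -10, 10))
}

apply_rigid <- function(xyz, tf) sweep(xyz %*% t(tf$R), 2, tf$t, "+")

# quick pseudo-atom structure with one atom per residue
pseudo_structure <- function(xyz, chain = "A", vdw = 1.5, mass = 12,
                             resid = seq_len(nrow(xyz))) {
  cg_structure(data.frame(
    serial = seq_len(nrow(xyz)), name = "C1", element = "C",
    resname = "DUM", resid = resid, chain = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], vdw = vdw, mass = mass,
    stringsAsFactors = FALSE))
}

# trajectory from a list of coordinate matrices over one topology
traj_from_frames <- function(top, frames, dt = 0.01) {
  cg_trajectory(top, do.call(rbind, lapply(frames, function(m)
    as.numeric(t(m)))), dt)
}

# synthetic frame ensemble with c conformational basins; returns the
# trajectory-free distance matrix inputs (frame coordinate list)
basin_frames <- function(n_basins, frames_per, n_atoms = 30, seed = 1,
                         basin_sd = 2, noise_sd = 0.2) {
  set.seed(seed)
  base <- matrix(rnorm(n_atoms * 3, sd = 4), n_atoms)
  lapply(seq_len(n_basins), function(b) {
    centre <- base + matrix(rnorm(n_atoms * 3, sd = basin_sd), n_atoms)
    lapply(seq_len(frames_per), function(i)
      centre + matrix(rnorm(n_atoms * 3, sd = noise_sd), n_atoms))
  }) |> unlist(recursive = FALSE)
}
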