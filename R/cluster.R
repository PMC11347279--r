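#' Pairwise superposed RMSD matrix of trajectory frames
#'
#' For every frame pair the first frame is Kabsch-superposed onto the
#' second over the selection (fit = measure = selection, uniform
#' weights as in the cpptraj clustering convention) and the RMSD is
#' recorded.  A frame stride keeps the O(n^2) matrix tractable for long
#' trajectories; the stride and the retained frame indices are stored
#' with the result.
#'
#' @param traj a `cg_trajectory`.
#' @param sel selection clustered on (e.g. the S6 backbone).
#' @param stride keep every stride-th frame (default 1).
#' @return object of class `cg_distmat`: `D` (full symmetric matrix, A),
#'   `frames` (original frame indices), `stride`.
#' @export
pairwise_rmsd <- function(traj, sel = NULL, stride = 1L) {
  stopifnot(inherits(traj, "cg_trajectory"))
  idx <- if (is.null(sel)) seq_len(n_atoms(traj)) else
    resolve_selection(traj$topology, sel)
  if (length(idx) == 0L) stop("empty selection")
  frames <- seq(1L, n_frames(traj), by = as.integer(stride))
  fr <- lapply(frames, function(i) frame_coords(traj, i)[idx, , drop = FALSE])
  n <- length(fr)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- kabsch_superpose(fr[[i]], fr[[j]])$rmsd
  }
  structure(list(D = D, frames = frames, stride = as.integer(stride)),
            class = "cg_distmat")
}

#' Construct a distance matrix object from a plain matrix
#' @param D symmetric matrix with zero diagonal.
#' @return `cg_distmat`.
#' @export
cg_distmat <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-9) || any(diag(D) != 0))
    stop("D must be symmetric with zero diagonal")
  structure(list(D = D, frames = seq_len(nrow(D)), stride = 1L),
            class = "cg_distmat")
}

.as_D <- function(x) if (inherits(x, "cg_distmat")) x$D else as.matrix(x)

#' Average-linkage (UPGMA) clustering cut at k clusters
#'
#' Agglomerative merging by unweighted average inter-cluster distance.
#' Ties are broken by the lexicographically smallest pair of cluster
#' labels (a cluster is labelled by its smallest member index), so the
#' result is deterministic.  Output labels are 1..k, numbered by each
#' cluster's smallest member.
#'
#' @param D a `cg_distmat` or symmetric matrix.
#' @param k number of clusters, 1 <= k <= n.
#' @return integer vector of cluster labels.
#' @export
average_linkage <- function(D, k) {
  D <- .as_D(D)
  n <- nrow(D)
  if (k < 1L || k > n) stop("k must be in 1..", n)
  members <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  heads <- seq_len(n)            # smallest member index per active cluster
  A <- D                          # average inter-cluster distances
  active <- rep(TRUE, n)
  n_active <- n
  while (n_active > k) {
    best <- NULL; bd <- Inf
    ai <- which(active)
    for (p in seq_len(length(ai) - 1L)) for (q in (p + 1L):length(ai)) {
      i <- ai[p]; j <- ai[q]
      d <- A[i, j]
      if (d < bd - 1e-12) { bd <- d; best <- c(i, j)
      } else if (abs(d - bd) <= 1e-12) {
        cand <- sort(c(heads[i], heads[j]))
        cur <- sort(c(heads[best[1L]], heads[best[2L]]))
        if (cand[1L] < cur[1L] ||
            (cand[1L] == cur[1L] && cand[2L] < cur[2L])) best <- c(i, j)
      }
    }
    i <- best[1L]; j <- best[2L]
    # unweighted-average (UPGMA) update into slot i
    for (m in ai) {
      if (m == i || m == j) next
      A[i, m] <- A[m, i] <-
        (sizes[i] * A[i, m] + sizes[j] * A[j, m]) / (sizes[i] + sizes[j])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    heads[i] <- min(heads[i], heads[j])
    active[j] <- FALSE
    n_active <- n_active - 1L
  }
  out <- integer(n)
  cl <- which(active)
  cl <- cl[order(heads[cl])]
  for (lab in seq_along(cl)) out[members[[cl[lab]]]] <- lab
  out
}

.medoids <- function(D, labels) {
  vapply(sort(unique(labels)), function(l) {
    m <- which(labels == l)
    if (length(m) == 1L) return(m)
    within <- rowMeans(D[m, m, drop = FALSE])
    m[which.min(within)]          # ties: lowest index via which.min
  }, integer(1))
}

#' Davies-Bouldin index (medoid formulation)
#'
#' Frames live in RMSD space, which has no coordinates, so cluster
#' scatter and separation are taken through medoids: S_i is the mean
#' distance of cluster members to their medoid, M_ij the medoid-medoid
#' distance, and DBI = mean_i max_{j != i} (S_i + S_j) / M_ij.
#' Singleton clusters contribute S = 0.  Lower is better.
#'
#' @param D a `cg_distmat` or symmetric matrix.
#' @param labels cluster labels (k >= 2 clusters).
#' @return the index (non-negative scalar).
#' @export
davies_bouldin <- function(D, labels) {
  D <- .as_D(D)
  labs <- sort(unique(labels))
  k <- length(labs)
  if (k < 2L) stop("DBI needs at least 2 clusters")
  med <- .medoids(D, labels)
  S <- vapply(seq_len(k), function(i) {
    m <- which(labels == labs[i])
    mean(D[m, med[i]])
  }, numeric(1))
  M <- D[med, med, drop = FALSE]
  if (any(M[upper.tri(M)] < 1e-12))
    stop("degenerate clusters: coincident medoids")
  ratios <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j)
      (S[i] + S[j]) / M[i, j], numeric(1)))
  }, numeric(1))
  mean(ratios)
}

#' Percentage of variance explained by a clustering (SSR/SST)
#'
#' Using pairwise distances only: SST is the total pairwise
#' sum-of-squares `sum(d^2) / n` over all frame pairs, SSE the
#' within-cluster analogue (each cluster's pair sum divided by its
#' size), and SSR = SST - SSE.  Returns SSR/SST in `[0, 1]`; 0 for a
#' single cluster, 1 for all-singletons.
#'
#' @param D a `cg_distmat` or symmetric matrix.
#' @param labels cluster labels.
#' @return SSR/SST fraction.
#' @export
percent_variance <- function(D, labels) {
  D <- .as_D(D)
  n <- nrow(D)
  sst <- sum(D[upper.tri(D)]^2) / n
  if (sst == 0) return(0)
  sse <- 0
  for (l in unique(labels)) {
    m <- which(labels == l)
    if (length(m) > 1L) {
      Dm <- D[m, m, drop = FALSE]
      sse <- sse + sum(Dm[upper.tri(Dm)]^2) / length(m)
    }
  }
  (sst - sse) / sst
}

#' Two-stage cluster-count choice (DBI local minimum + variance plateau)
#'
#' Scans k, computing DBI and SSR/SST for each, and chooses the
#' smallest k that is simultaneously a local DBI minimum and at which
#' the SSR/SST gain to the next k drops below `plateau` (default 0.01
#' absolute).  The full per-k trace is returned so a custom k can be
#' imposed per system, mirroring the two-stage protocol used with MD
#' ensembles.  If no k satisfies both rules the best-DBI k is returned
#' with status `"no plateau"`.
#'
#' @param metrics data.frame with columns `k`, `dbi`, `ssr_sst`
#'   (as produced by [scan_k()]), sorted by k.
#' @param plateau SSR/SST gain threshold (default 0.01).
#' @return list: `chosen_k`, `status` ("ok" or "no plateau"), `trace`
#'   (metrics with `local_min` and `gain` columns).
#' @export
choose_k <- function(metrics, plateau = 0.01) {
  m <- metrics[order(metrics$k), , drop = FALSE]
  nk <- nrow(m)
  if (nk < 2L) stop("need metrics for at least 2 values of k")
  loc <- logical(nk)
  for (i in seq_len(nk)) {
    lo <- if (i > 1L) m$dbi[i] <= m$dbi[i - 1L] + 1e-12 else TRUE
    hi <- if (i < nk) m$dbi[i] <= m$dbi[i + 1L] + 1e-12 else TRUE
    loc[i] <- lo && hi
  }
  gain <- c(diff(m$ssr_sst), NA_real_)
  ok <- loc & !is.na(gain) & gain < plateau
  m$local_min <- loc; m$gain <- gain
  if (any(ok)) {
    list(chosen_k = m$k[which(ok)[1L]], status = "ok", trace = m)
  } else {
    list(chosen_k = m$k[which.min(m$dbi)], status = "no plateau", trace = m)
  }
}

#' Per-k clustering metrics over a scan range
#' @param D a `cg_distmat` or symmetric matrix.
#' @param k_scan integer vector of cluster counts (default
#'   `2:min(100, n - 1)`).
#' @return data.frame `k`, `dbi`, `ssr_sst`, plus the label matrix in
#'   `attr(, "labels")` (one column per k).
#' @export
scan_k <- function(D, k_scan = NULL) {
  Dm <- .as_D(D)
  n <- nrow(Dm)
  if (is.null(k_scan)) k_scan <- 2:min(100L, n - 1L)
  labs <- sapply(k_scan, function(k) average_linkage(Dm, k))
  labs <- matrix(labs, nrow = n, dimnames = list(NULL, paste0("k", k_scan)))
  out <- data.frame(
    k = k_scan,
    dbi = vapply(seq_along(k_scan), function(j)
      davies_bouldin(Dm, labs[, j]), numeric(1)),
    ssr_sst = vapply(seq_along(k_scan), function(j)
      percent_variance(Dm, labs[, j]), numeric(1)))
  attr(out, "labels") <- labs
  out
}

#' Representative frame of each cluster
#'
#' Per cluster, the member minimising the mean distance to its
#' co-members (the medoid; ties go to the smallest frame index).
#' Populations are reported sorted descending.
#'
#' @param D a `cg_distmat` or symmetric matrix.
#' @param labels cluster labels.
#' @return data.frame `cluster`, `representative` (index into the
#'   matrix; original frame numbers via the distmat's `frames`),
#'   `population`, sorted by population descending.
#' @export
representative_frames <- function(D, labels) {
  Dm <- .as_D(D)
  frames <- if (inherits(D, "cg_distmat")) D$frames else seq_len(nrow(Dm))
  labs <- sort(unique(labels))
  med <- .medoids(Dm, labels)
  out <- data.frame(cluster = labs,
                    representative = med,
                    frame = frames[med],
                    population = vapply(labs, function(l)
                      sum(labels == l), integer(1)))
  out[order(-out$population, out$cluster), , drop = FALSE]
}

#' Cluster a trajectory end-to-end
#'
#' Convenience wrapper: pairwise RMSD on a selection (with stride),
#' k-scan, two-stage k choice, final labels and representatives.
#'
#' @param traj a `cg_trajectory`.
#' @param sel selection (e.g. S6 backbone).
#' @param k_scan cluster counts to scan (default `2:min(100, n - 1)`).
#' @param stride frame stride for the pairwise matrix (default 10).
#' @param plateau SSR/SST plateau threshold (default 0.01).
#' @return object of class `cg_clusters`: `distmat`, `metrics`,
#'   `chosen_k`, `status`, `labels`, `representatives`, `stride`.
#' @export
cluster_trajectory <- function(traj, sel = NULL, k_scan = NULL,
                               stride = 10L, plateau = 0.01) {
  dm <- pairwise_rmsd(traj, sel, stride = stride)
  metrics <- scan_k(dm, k_scan)
  ch <- choose_k(metrics, plateau)
  labels <- attr(metrics, "labels")[, paste0("k", ch$chosen_k)]
  structure(list(distmat = dm, metrics = metrics, chosen_k = ch$chosen_k,
                 status = ch$status, labels = labels,
                 representatives = representative_frames(dm, labels),
                 stride = dm$stride),
            class = "cg_clusters")
}

#' @export
print.cg_clusters <- function(x, ...) {
  cat("cg_clusters:", length(x$labels), "frames, chosen k =", x$chosen_k,
      paste0("(", x$status, ")"), "\n")
  invisible(x)
}
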