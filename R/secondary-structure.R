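#' Reconstruct backbone amide hydrogens
#'
#' MD snapshots and pseudo-fixtures often lack hydrogens; the
#' hydrogen-bond energy model needs the amide H.  It is placed 1.01 A
#' from N, in the peptide plane, anti to the bisector of the
#' C(prev)-N and CA-N bonds.  Prolines and chain N-termini receive no
#' H; residues with missing backbone atoms are skipped with a warning.
#'
#' @param structure a `cg_structure` with backbone atoms N, CA, C.
#' @return the structure with added `H` atoms (appended per residue).
#' @export
reconstruct_amide_H <- function(structure) {
  a <- structure$atoms
  et <- element_table()
  h_row <- match("H", et$element)
  new_rows <- list()
  for (ch in unique(a$chain)) {
    ca <- a[a$chain == ch, , drop = FALSE]
    resids <- unique(ca$resid)
    for (k in seq_along(resids)[-1L]) {
      rid <- resids[k]; prev <- resids[k - 1L]
      res <- ca[ca$resid == rid, , drop = FALSE]
      if (any(res$resname == "PRO")) next
      if (res$name[1] == "" ) next
      get <- function(df, nm) {
        i <- which(df$name == nm)
        if (length(i) != 1L) return(NULL)
        c(df$x[i], df$y[i], df$z[i])
      }
      N <- get(res, "N"); CA <- get(res, "CA")
      Cp <- get(ca[ca$resid == prev, , drop = FALSE], "C")
      if (is.null(N) || is.null(CA) || is.null(Cp)) {
        warning("missing backbone atoms; skipping H for residue ",
                rid, " chain ", ch)
        next
      }
      u1 <- (Cp - N) / sqrt(sum((Cp - N)^2))
      u2 <- (CA - N) / sqrt(sum((CA - N)^2))
      d <- -(u1 + u2)
      d <- d / sqrt(sum(d^2))
      H <- N + 1.01 * d
      new_rows[[length(new_rows) + 1L]] <- data.frame(
        serial = 0L, name = "H", element = "H", resname = res$resname[1L],
        resid = rid, chain = ch, x = H[1], y = H[2], z = H[3],
        vdw = et$vdw_radius[h_row], mass = et$mass[h_row],
        stringsAsFactors = FALSE)
    }
  }
  if (length(new_rows)) {
    a <- rbind(a, do.call(rbind, new_rows))
    a <- a[order(a$chain, a$resid), , drop = FALSE]
    a$serial <- seq_len(nrow(a))
  }
  cg_structure(a)
}

#' Backbone hydrogen-bond energy (Kabsch-Sander electrostatic model)
#'
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol
#' between a donor amide (N-H) and an acceptor carbonyl (C=O); a bond
#' is called when E < -0.5 kcal/mol.  Overlapping geometries (any
#' distance < 0.5 A) are clamped to -9.9 and flagged.
#'
#' @param donor list with 3-vectors `N` and `H`.
#' @param acceptor list with 3-vectors `C` and `O`.
#' @return energy in kcal/mol, with attribute `clamped` when clamped.
#' @export
hbond_energy <- function(donor, acceptor) {
  d <- function(p, q) sqrt(sum((p - q)^2))
  r_on <- d(acceptor$O, donor$N); r_ch <- d(acceptor$C, donor$H)
  r_oh <- d(acceptor$O, donor$H); r_cn <- d(acceptor$C, donor$N)
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5) {
    e <- -9.9
    attr(e, "clamped") <- TRUE
    return(e)
  }
  0.084 * 332 * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

# Vectorised same-chain H-bond map for one chain's backbone.
# Returns a logical n x n matrix: bond[i, j] TRUE when the carbonyl of
# residue i accepts from the amide of residue j (E < cutoff).
.hbond_map <- function(bb, cutoff = -0.5) {
  n <- nrow(bb$N)
  has_h <- !is.na(bb$H[, 1L])
  E <- matrix(Inf, n, n)
  inv <- function(M) { M[M < 1e-9] <- 1e-9; 1 / M }
  dmat <- function(P, Q) {
    # cross pairwise distances of two n x 3 sets
    sqrt(pmax(outer(rowSums(P^2), rowSums(Q^2), "+") - 2 * P %*% t(Q), 0))
  }
  r_on <- dmat(bb$O, bb$N); r_cn <- dmat(bb$C, bb$N)
  r_oh <- dmat(bb$O, bb$H); r_ch <- dmat(bb$C, bb$H)
  E <- 0.084 * 332 * (inv(r_on) + inv(r_ch) - inv(r_oh) - inv(r_cn))
  clamp <- pmin(r_on, pmin(r_cn, pmin(r_oh, r_ch, na.rm = TRUE),
                           na.rm = TRUE), na.rm = TRUE) < 0.5
  E[clamp] <- -9.9
  E[, !has_h] <- Inf
  # exclude self and adjacent residues
  for (off in -1:1) {
    ix <- seq_len(n)
    jx <- ix + off
    ok <- jx >= 1L & jx <= n
    E[cbind(ix[ok], jx[ok])] <- Inf
  }
  E < cutoff
}

.chain_backbone <- function(structure, chain) {
  a <- structure$atoms[structure$atoms$chain == chain, , drop = FALSE]
  resids <- sort(unique(a$resid))
  pick <- function(nm) {
    m <- matrix(NA_real_, length(resids), 3L)
    sub <- a[a$name == nm, , drop = FALSE]
    i <- match(resids, sub$resid)
    ok <- !is.na(i)
    m[ok, ] <- cbind(sub$x[i[ok]], sub$y[i[ok]], sub$z[i[ok]])
    m
  }
  list(resids = resids, N = pick("N"), CA = pick("CA"),
       C = pick("C"), O = pick("O"), H = pick("H"))
}

#' Assign secondary structure (3-state: H / E / C)
#'
#' Simplified DSSP on the Kabsch-Sander hydrogen-bond map.  An alpha
#' turn exists at residue i when the carbonyl of i bonds the amide of
#' i+4; residue i is `H` when turns exist at both i-1 and i (two
#' consecutive turns, the minimal helix).  Residues in an isolated
#' bridge pattern (parallel or antiparallel, |i-j| > 2) are `E`; all
#' else `C`.  Amide hydrogens are reconstructed when absent.  Bonds are
#' evaluated within chains.
#'
#' @param frame a `cg_structure`.
#' @param cutoff H-bond energy cutoff in kcal/mol (default -0.5).
#' @return object of class `cg_ss`: data.frame `chain`, `resid`, `ss`.
#' @export
assign_ss <- function(frame, cutoff = -0.5) {
  if (!any(frame$atoms$name == "H"))
    frame <- suppressWarnings(reconstruct_amide_H(frame))
  out <- list()
  for (ch in unique(frame$atoms$chain)) {
    bb <- .chain_backbone(frame, ch)
    n <- length(bb$resids)
    ss <- rep("C", n)
    if (n >= 5L && !anyNA(bb$N[, 1L]) && !anyNA(bb$O[, 1L])) {
      bond <- .hbond_map(bb, cutoff)
      turn <- rep(FALSE, n)
      turn[seq_len(n - 4L)] <- bond[cbind(seq_len(n - 4L), seq_len(n - 4L) + 4L)]
      # residue i is helical when turns exist at both i-1 and i
      helix <- c(FALSE, turn[-n] & turn[-1L])
      # bridges: CO(i-1)->NH(j) & CO(j)->NH(i+1)  (antiparallel-ish)
      #          CO(i)->NH(j)   & CO(j)->NH(i)    (parallel-ish)
      bridge <- rep(FALSE, n)
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (abs(i - j) <= 2L) next
        p1 <- i > 1L && i < n && bond[i - 1L, j] && bond[j, i + 1L]
        p2 <- bond[i, j] && bond[j, i]
        if (p1 || p2) { bridge[i] <- TRUE; break }
      }
      ss[helix] <- "H"
      ss[!helix & bridge] <- "E"
    }
    out[[ch]] <- data.frame(chain = ch, resid = bb$resids, ss = ss,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("cg_ss", "data.frame")
  res
}

#' Alpha-helix propensity per residue over a trajectory
#'
#' Fraction of frames in which each residue is assigned `H`, and its
#' mean over a domain's residues.  Optionally a reference condition's
#' propensity is subtracted to give a per-residue delta (e.g. mutant
#' minus wildtype), which localises helix loss such as a linker helix
#' unfolding in one condition only.
#'
#' @param traj a `cg_trajectory` with at least 10 frames.
#' @param domain optional `cg_domain` restricting the summary.
#' @param chains chains included (default: all).
#' @param reference optional `cg_helix_propensity` from a reference
#'   condition, subtracted to produce `delta`.
#' @param cutoff H-bond cutoff (default -0.5 kcal/mol).
#' @return object of class `cg_helix_propensity`: data.frame `chain`,
#'   `resid`, `propensity` (and `delta` when a reference is given);
#'   attributes `domain_mean` and (with reference) `domain_mean_delta`.
#' @export
helix_propensity <- function(traj, domain = NULL, chains = NULL,
                             reference = NULL, cutoff = -0.5) {
  stopifnot(inherits(traj, "cg_trajectory"))
  if (n_frames(traj) < 10L) stop("helix propensity needs >= 10 frames")
  if (is.null(chains)) chains <- unique(traj$topology$atoms$chain)
  acc <- NULL
  for (i in seq_len(n_frames(traj))) {
    ss <- assign_ss(frame_structure(traj, i), cutoff)
    ss <- ss[ss$chain %in% chains, , drop = FALSE]
    h <- as.integer(ss$ss == "H")
    if (is.null(acc)) {
      acc <- ss[, c("chain", "resid")]
      acc$h <- h
    } else acc$h <- acc$h + h
  }
  acc$propensity <- acc$h / n_frames(traj)
  acc$h <- NULL
  if (!is.null(domain)) {
    keep <- rep(FALSE, nrow(acc))
    for (ch in unique(acc$chain)) {
      rr <- tryCatch(domain_selection(domain, chain = ch)$res_range,
                     error = function(e) NULL)
      if (is.null(rr)) next
      for (r in rr)
        keep <- keep | (acc$chain == ch & acc$resid >= r[1L] & acc$resid <= r[2L])
    }
    if (!any(keep)) stop("domain ", domain$name,
                         " matches no residues on chains ",
                         paste(chains, collapse = ","))
    acc <- acc[keep, , drop = FALSE]
  }
  attr(acc, "domain_mean") <- mean(acc$propensity)
  if (!is.null(reference)) {
    key <- paste(acc$chain, acc$resid)
    rkey <- paste(reference$chain, reference$resid)
    m <- match(key, rkey)
    acc$delta <- acc$propensity - reference$propensity[m]
    attr(acc, "domain_mean_delta") <-
      attr(acc, "domain_mean") - mean(reference$propensity[m], na.rm = TRUE)
  }
  rownames(acc) <- NULL
  class(acc) <- c("cg_helix_propensity", "data.frame")
  acc
}

#' Compact per-frame secondary-structure strings
#' @param traj a `cg_trajectory`.
#' @param chain chain to report.
#' @return character vector, one `HEC` string per frame.
#' @export
ss_strings <- function(traj, chain = NULL) {
  vapply(seq_len(n_frames(traj)), function(i) {
    ss <- assign_ss(frame_structure(traj, i))
    if (!is.null(chain)) ss <- ss[ss$chain == chain, , drop = FALSE]
    paste(ss$ss, collapse = "")
  }, character(1))
}
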