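#' Build a polypeptide backbone from phi/psi torsions
#'
#' Internal-coordinate (NeRF) chain construction with standard bond
#' geometry: N-CA 1.458, CA-C 1.525, C-N 1.329, C=O 1.231 A; angles
#' N-CA-C 111.2, CA-C-N 116.2, C-N-CA 121.7, CA-C-O 120.8 deg; planar
#' trans peptide (omega 180 deg).  The carbonyl O is placed anti to the
#' next amide nitrogen (torsion psi + 180).
#'
#' @param phi,psi backbone torsions in degrees, recycled to `n_res`.
#' @param n_res number of residues.
#' @param chain chain id.
#' @param resname residue name given to all residues (default "ALA").
#' @param resid_start first residue number.
#' @return a [cg_structure()] with atoms N, CA, C, O per residue.
#' @export
build_backbone <- function(n_res, phi, psi, chain = "A",
                           resname = "ALA", resid_start = 1L) {
  if (n_res < 1L) stop("n_res must be >= 1")
  phi <- rep_len(phi, n_res)
  psi <- rep_len(psi, n_res)
  d2r <- pi / 180
  # place d at bond/angle/torsion from c (with b, a as context)
  nerf <- function(a, b, c, bond, angle, torsion) {
    ang <- angle * d2r; tor <- torsion * d2r
    bc <- c - b; bc <- bc / sqrt(sum(bc^2))
    ab <- b - a
    n <- c(ab[2] * bc[3] - ab[3] * bc[2],
           ab[3] * bc[1] - ab[1] * bc[3],
           ab[1] * bc[2] - ab[2] * bc[1])
    n <- n / sqrt(sum(n^2))
    m <- c(n[2] * bc[3] - n[3] * bc[2],
           n[3] * bc[1] - n[1] * bc[3],
           n[1] * bc[2] - n[2] * bc[1])
    d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
            bond * sin(ang) * sin(tor))
    c + d2[1] * bc + d2[2] * m + d2[3] * n
  }
  N <- matrix(NA_real_, n_res, 3)
  CA <- matrix(NA_real_, n_res, 3)
  C <- matrix(NA_real_, n_res, 3)
  O <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  th <- 111.2 * d2r
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(th), sin(th), 0)
  for (i in seq_len(n_res)) {
    if (i > 1L) {
      N[i, ] <- nerf(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                     1.329, 116.2, psi[i - 1])
      CA[i, ] <- nerf(CA[i - 1, ], C[i - 1, ], N[i, ], 1.458, 121.7, 180)
      C[i, ] <- nerf(C[i - 1, ], N[i, ], CA[i, ], 1.525, 111.2, phi[i])
    }
    O[i, ] <- nerf(N[i, ], CA[i, ], C[i, ], 1.231, 120.8, psi[i] + 180)
  }
  names_per <- c("N", "CA", "C", "O")
  ele_per <- c("N", "C", "C", "O")
  et <- element_table()
  hit <- match(ele_per, et$element)
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    xyz <- rbind(N[i, ], CA[i, ], C[i, ], O[i, ])
    data.frame(serial = 0L, name = names_per, element = ele_per,
               resname = resname, resid = resid_start + i - 1L,
               chain = chain, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               vdw = et$vdw_radius[hit], mass = et$mass[hit],
               stringsAsFactors = FALSE)
  }))
  atoms$serial <- seq_len(nrow(atoms))
  cg_structure(atoms)
}

#' Ideal alpha-helical backbone
#'
#' Canonical helix torsions (phi -57, psi -47 deg) giving a rise of
#' about 1.5 A per residue, about 100 deg twist per residue and
#' consecutive CA-CA distances of 3.8 A.
#'
#' @param n_res number of residues (>= 5).
#' @param ... passed to [build_backbone()].
#' @return a [cg_structure()].
#' @export
make_ideal_helix <- function(n_res, ...) {
  if (n_res < 5L) stop("an alpha-helix fixture needs n_res >= 5")
  build_backbone(n_res, phi = -57, psi = -47, ...)
}

#' Extended (beta-strand-like) backbone
#' @param n_res number of residues.
#' @param ... passed to [build_backbone()].
#' @return a [cg_structure()].
#' @export
make_extended_chain <- function(n_res, ...) {
  build_backbone(n_res, phi = -139, psi = 135, ...)
}
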