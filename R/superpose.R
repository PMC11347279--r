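#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of `mobile` onto `reference` over proper rotations
#' (reflections are excluded by flipping the sign of the smallest
#' singular direction when needed).  With weights \eqn{w_i} (masses by
#' default elsewhere in the package) the minimised quantity is
#' \eqn{\sqrt{\sum_i w_i |x_i' - y_i|^2 / \sum_i w_i}}.
#'
#' The returned transform acts on row-vector coordinates as
#' `fitted = mobile %*% rotation + translation`.
#'
#' @param mobile n x 3 coordinates to move.
#' @param reference n x 3 target coordinates.
#' @param weights optional per-point weights (default uniform).
#' @return object of class `cg_superposition`: `rotation` (3 x 3,
#'   det +1), `translation` (length 3), `rmsd` (Angstrom, weighted).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference)) stop("point counts differ")
  if (n < 3L) stop("need at least 3 points to superpose")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop("invalid weights")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(reference, 2L, cr)
  C <- crossprod(P * w, Q)                      # 3 x 3 cross-covariance
  sv <- svd(C)
  # degenerate (collinear) sets leave the rotation about the line free
  sQ <- svd(Q * sqrt(w), nu = 0, nv = 0)$d
  if (sQ[2L] < 1e-8 * max(sQ[1L], 1))
    stop("degenerate (collinear) point set; superposition is not unique")
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  A <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- P %*% A
  rmsd <- sqrt(sum(w * rowSums((fitted - Q)^2)))
  structure(list(rotation = A, translation = cr - as.numeric(cm %*% A),
                 rmsd = rmsd),
            class = "cg_superposition")
}

#' Apply a superposition transform to coordinates
#' @param fit a `cg_superposition`.
#' @param xyz n x 3 coordinate matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(fit, xyz) {
  stopifnot(inherits(fit, "cg_superposition"))
  sweep(as.matrix(xyz) %*% fit$rotation, 2L, fit$translation, "+")
}

#' @export
print.cg_superposition <- function(x, ...) {
  cat(sprintf("cg_superposition: rmsd %.4f A\n", x$rmsd))
  invisible(x)
}

# weighted rmsd between two already-aligned coordinate sets
.wrmsd <- function(a, b, w = NULL) {
  if (is.null(w)) w <- rep(1, nrow(a))
  w <- w / sum(w)
  sqrt(sum(w * rowSums((a - b)^2)))
}
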