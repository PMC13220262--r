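#' Least-squares rigid superposition of paired C-alpha beads
#'
#' Kabsch-style optimal rotation/translation of the mobile structure onto the
#' reference, computed on the paired C-alpha positions. The returned rotation
#' is proper (determinant +1, no reflection).
#'
#' @param mobile,reference [cg_structure()] objects.
#' @param pairing Residue pairing from [pair_residues()]; defaults to pairing
#'   `mobile` against `reference` by identifier.
#' @return An object of class `cg_superposition`: list with `rotation` (3x3),
#'   `translation` (length 3, Angstrom) and `rmsd` (Angstrom). The transform
#'   maps mobile coordinates `x` to `rotation %*% x + translation`.
#' @export
superpose <- function(mobile, reference, pairing = NULL) {
  pairing <- pairing %||% pair_residues(mobile, reference)
  P <- ca_matrix(mobile)[pairing$idx_a, , drop = FALSE]
  Q <- ca_matrix(reference)[pairing$idx_b, , drop = FALSE]
  fit <- kabsch_fit(P, Q)
  structure(fit, class = "cg_superposition")
}

# core Kabsch on n x 3 matrices: returns rotation R, translation t, rmsd with
# convention x' = R x + t (column vectors), i.e. P %*% t(R) + t row-wise.
kabsch_fit <- function(P, Q) {
  if (nrow(P) < 3) abort("geometry error: need at least 3 paired positions")
  pc <- colMeans(P); qc <- colMeans(Q)
  P0 <- sweep(P, 2, pc); Q0 <- sweep(Q, 2, qc)
  # collinearity check: rank of centered mobile set
  sv_p <- svd(P0)$d
  if (sv_p[2] < 1e-8 * max(sv_p[1], 1)) {
    abort("geometry error: paired positions are collinear")
  }
  H <- crossprod(P0, Q0)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(qc - R %*% pc)
  dev <- P0 %*% t(R) - Q0
  list(rotation = R, translation = tr, rmsd = sqrt(mean(rowSums(dev^2))))
}

#' @export
print.cg_superposition <- function(x, ...) {
  cat(sprintf("<cg_superposition> rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to every bead of a structure
#'
#' @param x A [cg_structure()].
#' @param transform A `cg_superposition` (or list with `rotation` and
#'   `translation`).
#' @param move_hetero Transform hetero beads too (default `TRUE`).
#' @return The transformed [cg_structure()].
#' @export
apply_transform <- function(x, transform, move_hetero = TRUE) {
  R <- transform$rotation; tr <- transform$translation
  tf <- function(m) {
    out <- m %*% t(R)
    sweep(out, 2, tr, "+")
  }
  ca <- tf(ca_matrix(x))
  cen <- cen_matrix(x)
  has <- !is.na(cen[, 1])
  if (any(has)) cen[has, ] <- tf(cen[has, , drop = FALSE])
  x <- set_coords(x, ca = ca, cen = cen)
  het <- cg_hetero(x)
  if (move_hetero && nrow(het) > 0) {
    hxyz <- tf(as.matrix(het[, c("x", "y", "z")]))
    het$x <- hxyz[, 1]; het$y <- hxyz[, 2]; het$z <- hxyz[, 3]
    attr(x, "hetero") <- het
  }
  x
}

#' C-alpha RMSD after optimal superposition
#'
#' @inheritParams superpose
#' @return RMSD in Angstrom; symmetric in its arguments.
#' @export
rmsd_after_superposition <- function(a, b, pairing = NULL) {
  pairing <- pairing %||% pair_residues(a, b)
  superpose(a, b, pairing)$rmsd
}
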