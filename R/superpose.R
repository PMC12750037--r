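# Rigid-body least-squares superposition (Kabsch, reflection-free).

#' Optimal rigid superposition of model points onto target points
#'
#' Least-squares fit of `Q` (model) onto `P` (target) over rotations and
#' translations only; reflections are excluded, so chirality is preserved
#' even when a mirror image would fit better.
#'
#' @param P,Q Numeric n x 3 matrices of paired coordinates (Angstrom),
#'   n >= 3 and not all collinear.
#' @param support Optional integer indices recording which residues the
#'   fit was computed on (carried through for bookkeeping).
#' @return List of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd`, `support`. The fitted model
#'   coordinates are `Q %*% t(rotation) + translation` (row-wise).
#' @export
kabsch_superpose <- function(P, Q, support = seq_len(nrow(P))) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) stop("point sets differ in size")
  if (nrow(P) < 3) stop("superposition needs at least 3 points")
  pc <- colMeans(P); qc <- colMeans(Q)
  Pc <- sweep(P, 2, pc); Qc <- sweep(Q, 2, qc)
  sv_p <- svd(Pc)$d
  if (sv_p[2] < 1e-8 * max(sv_p[1], 1))
    stop("degenerate (collinear) point set: rotation is not determined")
  H <- t(Qc) %*% Pc
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Qc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Pc)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(pc - R %*% qc),
                 rmsd = rmsd, support = support),
            class = "superposition")
}

#' Apply a superposition to coordinates
#'
#' @param sup A `superposition`.
#' @param X n x 3 coordinate matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sup, X) {
  sweep(as.matrix(X) %*% t(sup$rotation), 2, sup$translation, "+")
}
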