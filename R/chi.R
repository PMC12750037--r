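# Sidechain chi-angle definitions and computation.
#
# Atom quadruples follow the conventional rotamer definitions. Terminal
# groups with twofold symmetry (Asp/Phe/Tyr chi2, Glu chi3) are flagged so
# accuracy comparisons can work modulo 180 degrees.

CHI_ATOMS <- list(
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  CYS = list(c("N", "CA", "CB", "SG")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  VAL = list(c("N", "CA", "CB", "CG1"))
)

# (residue type, chi index) pairs whose terminal group is symmetric:
# the chi value is only defined modulo 180 degrees
CHI_SYMMETRIC <- list(ASP = 2L, GLU = 3L, PHE = 2L, TYR = 2L)

chi_period <- function(resname, k) {
  sym <- CHI_SYMMETRIC[[resname]]
  if (!is.null(sym) && k == sym) 180 else 360
}

#' Sidechain chi-angles of every polymer residue
#'
#' Returns chi1..chik per residue following the conventional rotamer atom
#' quadruples. Gly and Ala (no chi-angles) give empty vectors, as do
#' residue types without a chi definition. A missing sidechain atom
#' truncates the list at the first undefined angle.
#'
#' @param s A `casp_structure`.
#' @return Named list (by residue key, in structure order) of numeric
#'   vectors of angles in degrees, each in (-180, 180].
#' @export
chi_angles <- function(s) {
  rt <- residue_table(s)
  a <- s$atoms[s$atoms$record == "ATOM", ]
  out <- vector("list", nrow(rt))
  names(out) <- rt$res_key
  for (i in seq_len(nrow(rt))) {
    res <- canonical_resname(rt$resname[i])
    quads <- CHI_ATOMS[[res]]
    if (is.null(quads)) {
      out[[i]] <- numeric(0)
      next
    }
    ra <- a[a$res_key == rt$res_key[i], ]
    coords <- function(nm) {
      j <- match(nm, ra$atom)
      if (is.na(j)) return(NULL)
      c(ra$x[j], ra$y[j], ra$z[j])
    }
    chis <- numeric(0)
    for (q in quads) {
      ps <- lapply(q, coords)
      if (any(vapply(ps, is.null, TRUE))) break
      chis <- c(chis, dihedral_angle(ps[[1]], ps[[2]], ps[[3]], ps[[4]]))
    }
    out[[i]] <- chis
  }
  out
}
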