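# Structure-comparison metrics beyond GDT: GDC, AL0_P, lDDT, ASE, AAA,
# and site-restricted aggregation of per-residue scores.

# characteristic distal sidechain atom per residue type for GDC_SC
# (Gly has no sidechain heavy atom and is excluded)
GDC_SC_ATOMS <- c(ALA = "CB", ARG = "CZ", ASN = "OD1", ASP = "OD1",
                  CYS = "SG", GLN = "OE1", GLU = "OE1", HIS = "NE2",
                  ILE = "CD1", LEU = "CD1", LYS = "NZ", MET = "CE",
                  PHE = "CZ", PRO = "CG", SER = "OG", THR = "OG1",
                  TRP = "CH2", TYR = "OH", VAL = "CG1")

GDC_THRESHOLDS <- 0.5 * (1:10)
GDC_WEIGHTS <- 11 - (1:10)  # sum = 55

# atom selection for a GDC selector: data frame of target res_key + atom
gdc_selection <- function(target, keys, selector) {
  a <- target$atoms[target$atoms$record == "ATOM" &
                      target$atoms$res_key %in% keys, ]
  a <- a[a$elem != "H", ]
  if (selector == "mc") {
    a <- a[a$atom %in% c("N", "CA", "C", "O"), ]
  } else if (selector == "sc") {
    want <- GDC_SC_ATOMS[canonical_resname(a$resname)]
    a <- a[!is.na(want) & a$atom == want, ]
  }
  a
}

#' Global Distance Calculation (GDC) score
#'
#' Threshold-weighted distance agreement over a fixed superposition:
#' `GDC = 100 * sum_k (11 - k) P_k / 55` where `P_k` is the fraction of
#' selected target atoms whose model counterpart lies within `k * 0.5`
#' Angstrom (k = 1..10) under `sup`. Conventionally `sup` is the
#' GDT-optimal CA superposition ([gdt_reference_superposition()]).
#' Missing model atoms stay in the denominator and fail every threshold.
#'
#' @param target,model `casp_structure` objects.
#' @param corr Correspondence from [map_residues()].
#' @param atom_selector `"sc"` (one characteristic distal sidechain atom
#'   per residue type), `"mc"` (N, CA, C, O) or `"all"` (all heavy atoms).
#' @param sup A `superposition` (model onto target).
#' @return List: `score` (0-100) and `per_residue` (named vector, the same
#'   formula per residue over its selected atoms).
#' @export
gdc <- function(target, model, corr, atom_selector = c("all", "mc", "sc"),
                sup) {
  atom_selector <- match.arg(atom_selector)
  sel <- gdc_selection(target, corr$pairs$target_key, atom_selector)
  if (!nrow(sel)) stop("GDC selector '", atom_selector, "' selects no atoms")
  mkey <- corr$pairs$model_key[match(sel$res_key, corr$pairs$target_key)]
  ma <- model$atoms[model$atoms$record == "ATOM", ]
  mi <- match(paste(mkey, sel$atom), paste(ma$res_key, ma$atom))
  mxyz <- cbind(ma$x[mi], ma$y[mi], ma$z[mi])
  mfit <- apply_superposition(sup, mxyz)
  d <- sqrt(rowSums((mfit - cbind(sel$x, sel$y, sel$z))^2))
  d[is.na(d)] <- Inf
  gdc_formula <- function(dd) {
    pk <- vapply(GDC_THRESHOLDS, function(t) mean(dd <= t), 0)
    100 * sum(GDC_WEIGHTS * pk) / 55
  }
  per_res <- vapply(split(d, sel$res_key), gdc_formula, 0)
  # keep residue order as in the target
  per_res <- per_res[unique(sel$res_key)]
  list(score = gdc_formula(d), per_residue = per_res)
}

#' AL0_P: percentage of correctly aligned residues
#'
#' Under the reference superposition, residue i counts as correctly
#' aligned iff the fitted model CA_i lies within 3.8 Angstrom of target
#' CA_i and target CA_i is the nearest target CA to the fitted model CA_i.
#'
#' @inheritParams gdc
#' @param sup A `superposition`, conventionally from
#'   [gdt_reference_superposition()].
#' @return Percentage 0-100.
#' @export
al0_p <- function(target, model, corr, sup) {
  if (!nrow(corr$pairs)) stop("empty correspondence")
  tca_all <- atom_coords(target, residue_table(target)$res_key, "CA")
  tidx <- match(corr$pairs$target_key, residue_table(target)$res_key)
  mca <- atom_coords(model, corr$pairs$model_key, "CA")
  ok <- stats::complete.cases(mca)
  mfit <- apply_superposition(sup, mca[ok, , drop = FALSE])
  ti <- tidx[ok]
  keep_t <- stats::complete.cases(tca_all)
  good <- 0L
  for (j in seq_len(nrow(mfit))) {
    dd <- sqrt(rowSums(sweep(tca_all[keep_t, , drop = FALSE], 2, mfit[j, ])^2))
    self <- sqrt(sum((tca_all[ti[j], ] - mfit[j, ])^2))
    if (self <= 3.8 && self <= min(dd) + 1e-9) good <- good + 1L
  }
  100 * good / nrow(corr$pairs)
}

#' Local Distance Difference Test (lDDT)
#'
#' Superposition-free agreement of local inter-atomic distances. The
#' reference set is all heavy-atom pairs from different target residues
#' closer than 15 Angstrom. A pair is preserved at threshold t in
#' {0.5, 1, 2, 4} iff the model reproduces the target distance within t;
#' pairs with either atom missing in the model are counted as not
#' preserved. Per-residue lDDT is the mean preserved fraction over
#' thresholds among pairs involving that residue (scale 0-100); the
#' global score is the mean of the per-residue values.
#'
#' @inheritParams gdc
#' @param inclusion_radius Reference-pair inclusion radius (Angstrom).
#' @param thresholds Distance-difference thresholds (Angstrom).
#' @return List: `score` (global, 0-100), `per_residue` (named vector).
#' @export
lddt <- function(target, model, corr, inclusion_radius = 15,
                 thresholds = c(0.5, 1, 2, 4)) {
  ta <- target$atoms[target$atoms$record == "ATOM", ]
  ta <- ta[ta$elem != "H", ]
  if (nrow(ta) < 2) stop("lDDT needs at least 2 target heavy atoms")
  txyz <- cbind(ta$x, ta$y, ta$z)
  dmat <- as.matrix(stats::dist(txyz))
  same_res <- outer(ta$res_key, ta$res_key, "==")
  use <- upper.tri(dmat) & !same_res & dmat < inclusion_radius
  ij <- which(use, arr.ind = TRUE)
  if (!nrow(ij)) stop("no lDDT reference pairs within the inclusion radius")
  # model counterpart coordinates by (mapped residue key, atom name)
  mkey <- corr$pairs$model_key[match(ta$res_key, corr$pairs$target_key)]
  ma <- model$atoms[model$atoms$record == "ATOM", ]
  mi <- match(paste(mkey, ta$atom), paste(ma$res_key, ma$atom))
  mxyz <- cbind(ma$x[mi], ma$y[mi], ma$z[mi])
  d_t <- dmat[ij]
  a1 <- ij[, 1]; a2 <- ij[, 2]
  d_m <- sqrt(rowSums((mxyz[a1, , drop = FALSE] - mxyz[a2, , drop = FALSE])^2))
  # per-pair score: fraction of thresholds passed (missing atoms fail all)
  dev <- abs(d_m - d_t)
  pair_score <- rowMeans(vapply(thresholds,
                                function(t) !is.na(dev) & dev <= t,
                                logical(length(dev))))
  res_of_pair <- c(ta$res_key[a1], ta$res_key[a2])
  per_res <- 100 * vapply(split(c(pair_score, pair_score), res_of_pair),
                          mean, 0)
  per_res <- per_res[unique(ta$res_key)[unique(ta$res_key) %in% names(per_res)]]
  list(score = mean(per_res), per_residue = per_res)
}

#' ASE: agreement between submitted pLDDT and realized lDDT
#'
#' Self-assessment score (the QSE of CASP rankings):
#' `100 - mean_i |pLDDT_i - lDDT_i|`, clamped to [0, 100]. pLDDT is read
#' from the model CA B-factor column on the 0-100 scale.
#'
#' @param model A `casp_structure` whose B-factors carry pLDDT.
#' @param lddt_per_res Named per-residue lDDT vector (0-100) keyed by
#'   model residue; from [lddt()] remapped, or computed directly when
#'   target and model share numbering.
#' @return Score 0-100.
#' @export
ase <- function(model, lddt_per_res) {
  rt <- residue_table(model)
  ma <- model$atoms[model$atoms$record == "ATOM" & model$atoms$atom == "CA", ]
  plddt <- ma$b[match(rt$res_key, ma$res_key)]
  names(plddt) <- rt$res_key
  if (all(is.na(plddt) | plddt == 0))
    stop("no self-estimate submitted: all model B-factors are zero/absent")
  common <- intersect(names(lddt_per_res), names(plddt)[!is.na(plddt)])
  if (!length(common)) stop("no residues with both pLDDT and lDDT")
  val <- 100 - mean(abs(plddt[common] - lddt_per_res[common]))
  min(max(val, 0), 100)
}

#' AAA: sidechain chi-angle accuracy
#'
#' Per residue, the percentage of target-defined chi-angles whose model
#' counterpart deviates by no more than 40 degrees (circular difference;
#' terminal groups with twofold symmetry compared modulo 180 degrees).
#' The comprehensive score is the unweighted mean over paired residues
#' having at least one target chi-angle.
#'
#' @inheritParams gdc
#' @param threshold Maximum allowed deviation in degrees.
#' @return List: `score` (0-100), `per_residue` (named vector over
#'   chi-bearing paired residues).
#' @export
aaa <- function(target, model, corr, threshold = 40) {
  tchi <- chi_angles(target)
  mchi <- chi_angles(model)
  trt <- residue_table(target)
  per_res <- numeric(0)
  for (i in seq_len(nrow(corr$pairs))) {
    tk <- corr$pairs$target_key[i]
    mk <- corr$pairs$model_key[i]
    tv <- tchi[[tk]]
    if (is.null(tv) || !length(tv)) next
    mv <- mchi[[mk]]
    res <- canonical_resname(trt$resname[match(tk, trt$res_key)])
    hit <- 0L
    for (k in seq_along(tv)) {
      if (!is.null(mv) && length(mv) >= k &&
          circ_diff(tv[k], mv[k], chi_period(res, k)) <= threshold)
        hit <- hit + 1L
    }
    per_res[tk] <- 100 * hit / length(tv)
  }
  if (!length(per_res)) stop("no chi-bearing paired residues for AAA")
  list(score = mean(per_res), per_residue = per_res)
}

#' Mean of per-residue scores over a residue site and its complement
#'
#' Used e.g. for functional-site accuracy: residues within 5 Angstrom of
#' metals or biologically relevant ligands versus the rest.
#'
#' @param per_res Named numeric vector of per-residue scores.
#' @param site Character vector of residue keys (members absent from
#'   `per_res` are ignored with a warning).
#' @return List: `site_mean`, `complement_mean`, `n_site`, `n_complement`.
#' @export
site_mean <- function(per_res, site) {
  absent <- setdiff(site, names(per_res))
  if (length(absent))
    warning("site members not present in per-residue scores: ",
            paste(absent, collapse = ", "))
  inside <- intersect(site, names(per_res))
  if (!length(inside)) stop("site has no members with per-residue scores")
  outside <- setdiff(names(per_res), inside)
  list(site_mean = mean(per_res[inside]),
       complement_mean = if (length(outside)) mean(per_res[outside]) else NA_real_,
       n_site = length(inside), n_complement = length(outside))
}

#' All internally computed metrics for one target/model pair
#'
#' Computes GDT_TS, GDT_HA, GDC (sc, mc, all), AL0_P, lDDT, ASE and AAA
#' in one pass, sharing the residue correspondence and the reference
#' superposition. With several target versions (alternative
#' conformations) the maximum score over versions is taken per metric.
#'
#' @param target A `casp_structure` or list of versions.
#' @param model A `casp_structure` (pLDDT in B-factors for ASE).
#' @param with_ase Compute ASE (requires non-zero B-factors).
#' @return Named numeric vector of metric values plus attribute
#'   `per_residue` (list of per-residue score vectors from the
#'   best-scoring version: `lddt`, `gdc_all`, `gdc_mc`).
#' @export
compute_metrics <- function(target, model, with_ase = TRUE) {
  versions <- if (inherits(target, "casp_structure")) list(target) else target
  best <- NULL
  for (tv in versions) {
    corr <- map_residues(tv, model)
    sup <- gdt_reference_superposition(tv, model, corr)
    ld <- lddt(tv, model, corr)
    g_all <- gdc(tv, model, corr, "all", sup)
    g_mc <- gdc(tv, model, corr, "mc", sup)
    g_sc <- try(gdc(tv, model, corr, "sc", sup), silent = TRUE)
    vals <- c(
      gdt_ts = gdt_ts(tv, model, corr),
      gdt_ha = gdt_ha(tv, model, corr),
      gdc_all = g_all$score,
      gdc_mc = g_mc$score,
      gdc_sc = if (inherits(g_sc, "try-error")) NA_real_ else g_sc$score,
      al0_p = al0_p(tv, model, corr, sup),
      lddt = ld$score,
      aaa = tryCatch(aaa(tv, model, corr)$score, error = function(e) NA_real_),
      ase = if (with_ase)
        tryCatch({
          lp <- ld$per_residue
          names(lp) <- corr$pairs$model_key[match(names(lp),
                                                  corr$pairs$target_key)]
          ase(model, lp[!is.na(names(lp))])
        }, error = function(e) NA_real_)
      else NA_real_)
    pr <- list(lddt = ld$per_residue, gdc_all = g_all$per_residue,
               gdc_mc = g_mc$per_residue)
    if (is.null(best)) {
      best <- list(vals = vals, pr = pr, mean = mean(vals, na.rm = TRUE))
    } else {
      # alternative conformations: keep the highest score per metric,
      # and the per-residue profiles of the best version overall
      m <- mean(vals, na.rm = TRUE)
      best$vals <- pmax(best$vals, vals, na.rm = TRUE)
      if (isTRUE(m > best$mean)) {
        best$pr <- pr
        best$mean <- m
      }
    }
  }
  out <- best$vals
  attr(out, "per_residue") <- best$pr
  out
}
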