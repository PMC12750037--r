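# GDT family: the fraction of CA atoms simultaneously fittable under one
# rigid superposition within a distance cutoff, maximized over
# superpositions and averaged over cutoffs.
#
# The search is a seed-and-extend heuristic: every contiguous window of
# length 3, 5, 7 (plus the full set) seeds a superposition, the residue
# set within the cutoff is re-fit iteratively until stable (at most 10
# iterations), and the best count over seeds is kept per cutoff. An
# exhaustive all-subsets oracle is available for small instances and pins
# the heuristic's correctness in the test suite.

GDT_TS_CUTOFFS <- c(1, 2, 4, 8)
GDT_HA_CUTOFFS <- c(0.5, 1, 2, 4)

# paired CA coordinate matrices; rows where the model CA is absent are
# kept (as NA) so they count in the denominator but never in a fit
paired_ca <- function(target, model, corr) {
  tca <- atom_coords(target, corr$pairs$target_key, "CA")
  mca <- atom_coords(model, corr$pairs$model_key, "CA")
  ok_t <- stats::complete.cases(tca)
  list(P = tca[ok_t, , drop = FALSE],
       Q = mca[ok_t, , drop = FALSE])
}

gdt_count <- function(P, Q, cutoff, sup) {
  Qf <- apply_superposition(sup, Q)
  d <- sqrt(rowSums((Qf - P)^2))
  within <- !is.na(d) & d <= cutoff
  list(count = sum(within), within = which(within), sup = sup)
}

# seed-and-extend for one cutoff; returns best count and superposition.
# every evaluated superposition competes for the best count: the
# within-cutoff refit chain from each seed, plus nested refits on the
# j closest residues under each chain superposition. The rigid fit is
# inlined (same math as kabsch_superpose) because it runs thousands of
# times per score.
gdt_heuristic_one <- function(P, Q, cutoff, max_iter = 10) {
  n <- nrow(P)
  valid <- which(stats::complete.cases(Q))
  best <- list(count = -1L, rmsd = Inf, R = NULL, t = NULL, support = NULL)
  Qv <- Q[valid, , drop = FALSE]
  Pv <- P[valid, , drop = FALSE]
  nvr <- nrow(Qv)
  # fit on `sel` (indices into P/Q rows), count residues within cutoff;
  # returns list(count, within, dev) or NULL on a degenerate subset
  fit_count <- function(sel) {
    Ps <- P[sel, , drop = FALSE]; Qs <- Q[sel, , drop = FALSE]
    np <- nrow(Ps)
    pc <- colMeans(Ps); qc <- colMeans(Qs)
    Psc <- Ps - rep(pc, each = np); Qsc <- Qs - rep(qc, each = np)
    s <- tryCatch(svd(crossprod(Qsc, Psc)), error = function(e) NULL)
    if (is.null(s) || s$d[2] < 1e-12 * max(s$d[1], 1)) return(NULL)
    d_sign <- sign(det(s$v) * det(s$u))
    if (d_sign == 0) return(NULL)
    R <- s$v %*% (c(1, 1, d_sign) * t(s$u))
    tr <- pc - as.numeric(R %*% qc)
    dev2 <- rowSums((Qv %*% t(R) + rep(tr, each = nvr) - Pv)^2)
    within <- valid[dev2 <= cutoff * cutoff]
    cnt <- length(within)
    rmsd <- sqrt(mean(rowSums((Qsc %*% t(R) - Psc)^2)))
    if (cnt > best$count || (cnt == best$count && rmsd < best$rmsd))
      best <<- list(count = cnt, rmsd = rmsd, R = R, t = tr, support = sel)
    list(count = cnt, within = within, dev = dev2)
  }
  nv <- length(valid)
  if (nv < 3) stop("GDT search failed: fewer than 3 fit-able residues")
  # small instances are searched completely: with at most ~1000 candidate
  # subsets, every residue subset of size >= 3 seeds one fit, which makes
  # the search provably optimal there (it coincides with the exhaustive
  # mode). Larger instances use the seed-and-extend windows below.
  n_subsets <- sum(choose(nv, 3:nv))
  if (n_subsets <= 1000) {
    for (k in 3:nv) {
      for (sel in utils::combn(valid, k, simplify = FALSE)) {
        fit_count(sel)
        if (best$count == n) break
      }
      if (best$count == n) break
    }
  } else {
    seeds <- list()
    for (w in c(3L, 5L, 7L)) {
      for (s in seq_len(max(0L, nv - w + 1L)))
        seeds[[length(seeds) + 1L]] <- valid[s:(s + w - 1L)]
    }
    seeds[[length(seeds) + 1L]] <- valid
    j_grid <- unique(round(seq(3, nv, length.out = min(nv - 2, 8))))
    for (seed in seeds) {
      sel <- seed
      res <- fit_count(sel)
      if (is.null(res)) next
      for (it in seq_len(max_iter)) {
        if (it == 1L) {
          # nested extension: refit on the j closest residues under the
          # seed superposition over a coarse j ladder; keeps the search
          # from being trapped by one inconsistent far atom
          ord <- valid[order(res$dev)]
          for (j in j_grid) fit_count(sort(ord[seq_len(j)]))
        }
        nsel <- res$within
        if (length(nsel) < 3 || identical(nsel, sel)) break
        sel <- nsel
        res2 <- fit_count(sel)
        if (is.null(res2)) break
        res <- res2
      }
      if (best$count == n) break
    }
  }
  if (is.null(best$R)) stop("GDT search failed: no valid subset fit")
  # polish: re-fit on the full within-cutoff set of the winning
  # superposition so the returned transform is the least-squares fit over
  # the largest consistent residue set, not a raw seed fit
  for (polish in 1:3) {
    dev2 <- rowSums((Qv %*% t(best$R) + rep(best$t, each = nvr) - Pv)^2)
    W <- valid[dev2 <= cutoff * cutoff]
    if (length(W) < 3 || identical(W, best$support)) break
    Ps <- P[W, , drop = FALSE]; Qs <- Q[W, , drop = FALSE]
    np <- nrow(Ps)
    pc <- colMeans(Ps); qc <- colMeans(Qs)
    Psc <- Ps - rep(pc, each = np); Qsc <- Qs - rep(qc, each = np)
    s <- tryCatch(svd(crossprod(Qsc, Psc)), error = function(e) NULL)
    if (is.null(s)) break
    d_sign <- sign(det(s$v) * det(s$u))
    if (d_sign == 0) break
    R <- s$v %*% (c(1, 1, d_sign) * t(s$u))
    tr <- pc - as.numeric(R %*% qc)
    cnt <- sum(rowSums((Qv %*% t(R) + rep(tr, each = nvr) - Pv)^2) <=
                 cutoff * cutoff)
    if (cnt < best$count) break
    best <- list(count = cnt,
                 rmsd = sqrt(mean(rowSums((Qsc %*% t(R) - Psc)^2))),
                 R = R, t = tr, support = W)
  }
  list(count = best$count,
       sup = structure(list(rotation = best$R, translation = best$t,
                            rmsd = best$rmsd, support = best$support),
                       class = "superposition"))
}

gdt_exhaustive_one <- function(P, Q, cutoff) {
  n <- nrow(P)
  valid <- which(stats::complete.cases(Q))
  if (n > 12) stop("exhaustive GDT mode is limited to <= 12 residues")
  best <- list(count = -1L, sup = NULL)
  for (k in 3:length(valid)) {
    combs <- utils::combn(valid, k)
    for (j in seq_len(ncol(combs))) {
      sel <- combs[, j]
      sup <- try(kabsch_superpose(P[sel, , drop = FALSE],
                                  Q[sel, , drop = FALSE], support = sel),
                 silent = TRUE)
      if (inherits(sup, "try-error")) next
      res <- gdt_count(P, Q, cutoff, sup)
      if (res$count > best$count) best <- list(count = res$count, sup = sup)
    }
  }
  if (is.null(best$sup)) stop("exhaustive GDT: no valid subset of size >= 3")
  best
}

#' GDT score of a model against a target
#'
#' For each distance cutoff, finds the maximal fraction of paired CA atoms
#' that fit simultaneously under one rigid superposition with deviation at
#' most the cutoff; the score is 100 times the mean fraction over cutoffs.
#' `GDT_TS` uses cutoffs 1, 2, 4, 8 Angstrom; `GDT_HA` (high accuracy)
#' uses 0.5, 1, 2, 4.
#'
#' @param target,model `casp_structure` objects.
#' @param corr Correspondence from [map_residues()].
#' @param cutoffs Positive ascending cutoffs in Angstrom.
#' @param mode `"heuristic"` (seed-and-extend) or `"exhaustive"` (all
#'   residue subsets of size >= 3; only for <= 12 residues).
#' @return List: `score` (0-100), `fractions` (per cutoff), `cutoffs`,
#'   and `sup` (the best superposition found at the largest cutoff).
#' @export
gdt <- function(target, model, corr, cutoffs = GDT_TS_CUTOFFS,
                mode = c("heuristic", "exhaustive")) {
  mode <- match.arg(mode)
  if (!nrow(corr$pairs)) stop("empty correspondence")
  if (any(diff(cutoffs) <= 0) || any(cutoffs <= 0))
    stop("cutoffs must be positive and ascending")
  pq <- paired_ca(target, model, corr)
  n <- nrow(pq$P)
  if (n < 3) stop("GDT needs at least 3 paired CA atoms")
  fracs <- numeric(length(cutoffs))
  sup_last <- NULL
  for (i in seq_along(cutoffs)) {
    best <- switch(mode,
                   heuristic = gdt_heuristic_one(pq$P, pq$Q, cutoffs[i]),
                   exhaustive = gdt_exhaustive_one(pq$P, pq$Q, cutoffs[i]))
    fracs[i] <- best$count / n
    sup_last <- best$sup
  }
  list(score = 100 * mean(fracs), fractions = fracs, cutoffs = cutoffs,
       sup = sup_last)
}

#' GDT_TS and GDT_HA convenience wrappers
#' @inheritParams gdt
#' @return Numeric score 0-100.
#' @export
gdt_ts <- function(target, model, corr, mode = "heuristic")
  gdt(target, model, corr, GDT_TS_CUTOFFS, mode)$score

#' @rdname gdt_ts
#' @export
gdt_ha <- function(target, model, corr, mode = "heuristic")
  gdt(target, model, corr, GDT_HA_CUTOFFS, mode)$score

#' Reference CA superposition for distance-based scores
#'
#' The superposition conventionally used for GDC and AL0_P: the
#' seed-and-extend GDT fit at a 4 Angstrom cutoff (the distance parameter
#' classically used for the reference superposition), i.e. the rigid fit
#' on the largest CA set consistent within 4 Angstrom.
#'
#' @inheritParams gdt
#' @param cutoff Cutoff in Angstrom for the fit (default 4).
#' @return A `superposition`.
#' @export
gdt_reference_superposition <- function(target, model, corr, cutoff = 4) {
  pq <- paired_ca(target, model, corr)
  gdt_heuristic_one(pq$P, pq$Q, cutoff)$sup
}
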