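# Synthetic data: toy targets built from ideal internal coordinates,
# graded decoys with pLDDT, and latent skill-model score tables. These
# drive every test of the pipeline; no external structures are needed.

# ideal backbone internal coordinates (Angstrom / degrees)
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.8, omega = 180)

SEGMENT_PHIPSI <- list(helix = c(-57, -47), strand = c(-120, 120))

# sidechain construction recipes: atom, reference atom names, bond
# length, bond angle, dihedral ("chiK" or "chiK+offset" or a number)
SIDECHAIN_BUILD <- list(
  ALA = list(list("CB", c("C", "N", "CA"), 1.53, 110.5, -122.6)),
  SER = list(list("CB", c("C", "N", "CA"), 1.53, 110.5, -122.6),
             list("OG", c("N", "CA", "CB"), 1.42, 110.5, "chi1")),
  LEU = list(list("CB", c("C", "N", "CA"), 1.53, 110.5, -122.6),
             list("CG", c("N", "CA", "CB"), 1.53, 116.3, "chi1"),
             list("CD1", c("CA", "CB", "CG"), 1.53, 110.5, "chi2"),
             list("CD2", c("CA", "CB", "CG"), 1.53, 110.5, "chi2+122")),
  PHE = list(list("CB", c("C", "N", "CA"), 1.53, 110.5, -122.6),
             list("CG", c("N", "CA", "CB"), 1.50, 113.8, "chi1"),
             list("CD1", c("CA", "CB", "CG"), 1.39, 120, "chi2"),
             list("CD2", c("CA", "CB", "CG"), 1.39, 120, "chi2+180"),
             list("CE1", c("CB", "CG", "CD1"), 1.39, 120, 180),
             list("CE2", c("CB", "CG", "CD2"), 1.39, 120, 180),
             list("CZ", c("CG", "CD1", "CE1"), 1.39, 120, 0)),
  ARG = list(list("CB", c("C", "N", "CA"), 1.53, 110.5, -122.6),
             list("CG", c("N", "CA", "CB"), 1.52, 114.1, "chi1"),
             list("CD", c("CA", "CB", "CG"), 1.52, 111.3, "chi2"),
             list("NE", c("CB", "CG", "CD"), 1.46, 112, "chi3"),
             list("CZ", c("CG", "CD", "NE"), 1.33, 124.2, "chi4"),
             list("NH1", c("CD", "NE", "CZ"), 1.33, 120, 0),
             list("NH2", c("CD", "NE", "CZ"), 1.33, 120, 180)),
  GLY = list()
)

# template chi rotamer per residue type
TEMPLATE_CHI <- list(SER = -65, LEU = c(-65, 175), PHE = c(-65, 90),
                     ARG = c(-65, 180, 180, 180),
                     ALA = numeric(0), GLY = numeric(0))

# distal atoms moved by each chi rotation (per residue type)
CHI_MOVED <- list(
  SER = list("OG"),
  LEU = list(c("CG", "CD1", "CD2"), c("CD1", "CD2")),
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
             c("CD1", "CD2", "CE1", "CE2", "CZ")),
  ARG = list(c("CG", "CD", "NE", "CZ", "NH1", "NH2"),
             c("CD", "NE", "CZ", "NH1", "NH2"),
             c("NE", "CZ", "NH1", "NH2"),
             c("CZ", "NH1", "NH2"))
)

#' Specification for synthetic targets and decoys
#'
#' @param topology List of segments, each `list(type, length)` with type
#'   `"helix"`, `"strand"` or `"coil"`. The default 30-residue
#'   helix-coil-strand topology is compact enough for local-distance
#'   metrics yet long enough for superposition search to be non-trivial.
#' @param residue_palette Residue types drawn for the chain; the default
#'   mixes chi-bearing types (Ser, Leu, Phe, Arg) with Gly/Ala so both
#'   sidechain and backbone metrics are exercised.
#' @param sigma_xyz Coordinate noise s.d. in Angstrom applied by
#'   [make_decoy()].
#' @param sigma_chi Sidechain chi noise s.d. in degrees.
#' @param plddt_tau Self-estimate noise s.d. (pLDDT points).
#' @param seed Integer seed; all construction randomness flows from it.
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(topology = list(list(type = "helix", length = 12),
                                           list(type = "coil", length = 6),
                                           list(type = "strand", length = 12)),
                           residue_palette = c("SER", "LEU", "PHE", "ARG",
                                               "GLY", "ALA"),
                           sigma_xyz = 0, sigma_chi = 0, plddt_tau = 0,
                           seed = 1) {
  stopifnot(sigma_xyz >= 0, sigma_chi >= 0, plddt_tau >= 0)
  types <- vapply(topology, `[[`, "", "type")
  if (!all(types %in% c("helix", "strand", "coil")))
    stop("segment types must be helix, strand or coil")
  structure(list(topology = topology, residue_palette = residue_palette,
                 n_res = sum(vapply(topology, `[[`, 0, "length")),
                 sigma_xyz = sigma_xyz, sigma_chi = sigma_chi,
                 plddt_tau = plddt_tau, seed = seed),
            class = "synthetic_spec")
}

sample_coil_phipsi <- function() {
  region <- sample(3, 1, prob = c(0.5, 0.3, 0.2))
  switch(region,
         c(stats::runif(1, -140, -60), stats::runif(1, 120, 170)),
         c(stats::runif(1, -90, -40), stats::runif(1, -60, -20)),
         c(stats::runif(1, 50, 70), stats::runif(1, 30, 50)))
}

#' Build a toy protein target from ideal internal coordinates
#'
#' The backbone is grown residue by residue from ideal bond lengths and
#' angles with segment-typed phi/psi (helix -57/-47, strand -120/+120,
#' coil sampled from allowed Ramachandran regions). Sidechains are placed
#' from ideal rotamer templates. Deterministic under the spec seed.
#'
#' @param spec A `synthetic_spec`.
#' @param id Structure id.
#' @param chain Chain id.
#' @return A `casp_structure`.
#' @export
build_target <- function(spec, id = "synthetic_target", chain = "A") {
  set.seed(spec$seed)
  n <- spec$n_res
  seg_type <- unlist(lapply(spec$topology,
                            function(s) rep(s$type, s$length)))
  resnames <- sample(spec$residue_palette, n, replace = TRUE)
  phi <- numeric(n); psi <- numeric(n)
  for (i in seq_len(n)) {
    if (seg_type[i] == "coil") {
      pp <- sample_coil_phipsi()
    } else {
      pp <- SEGMENT_PHIPSI[[seg_type[i]]]
    }
    phi[i] <- pp[1]; psi[i] <- pp[2]
  }
  g <- BB_GEOM
  rows <- list()
  add <- function(resno, resname, atom, xyz, elem) {
    rows[[length(rows) + 1L]] <<-
      data.frame(record = "ATOM", chain = chain, resno = resno, icode = "",
                 resname = resname, atom = atom, x = xyz[1], y = xyz[2],
                 z = xyz[3], occ = 1, b = 0, elem = elem,
                 stringsAsFactors = FALSE)
  }
  # bootstrap first residue in a canonical frame
  N <- c(0, 0, 0)
  CA <- c(g$n_ca, 0, 0)
  th <- g$ang_n_ca_c * pi / 180
  C <- CA + c(-g$ca_c * cos(th), g$ca_c * sin(th), 0)
  bb <- vector("list", n)
  bb[[1]] <- list(N = N, CA = CA, C = C)
  for (i in seq_len(n)[-1]) {
    Np <- place_atom(bb[[i - 1]]$N, bb[[i - 1]]$CA, bb[[i - 1]]$C,
                     g$c_n, g$ang_ca_c_n, psi[i - 1])
    CAp <- place_atom(bb[[i - 1]]$CA, bb[[i - 1]]$C, Np,
                      g$n_ca, g$ang_c_n_ca, g$omega)
    Cp <- place_atom(bb[[i - 1]]$C, Np, CAp, g$ca_c, g$ang_n_ca_c, phi[i])
    bb[[i]] <- list(N = Np, CA = CAp, C = Cp)
  }
  for (i in seq_len(n)) {
    res <- resnames[i]
    add(i, res, "N", bb[[i]]$N, "N")
    add(i, res, "CA", bb[[i]]$CA, "C")
    add(i, res, "C", bb[[i]]$C, "C")
    O <- place_atom(bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C,
                    g$c_o, g$ang_ca_c_o, psi[i] + 180)
    add(i, res, "O", O, "O")
    placed <- list(N = bb[[i]]$N, CA = bb[[i]]$CA, C = bb[[i]]$C, O = O)
    chis <- TEMPLATE_CHI[[res]]
    for (step in SIDECHAIN_BUILD[[res]]) {
      dih <- step[[5]]
      if (is.character(dih)) {
        m <- regmatches(dih, regexec("^chi([0-9]+)(\\+([0-9.-]+))?$", dih))[[1]]
        k <- as.integer(m[2])
        off <- if (nzchar(m[4])) as.numeric(m[4]) else 0
        dih <- chis[k] + off
      }
      refs <- lapply(step[[2]], function(a) placed[[a]])
      xyz <- place_atom(refs[[1]], refs[[2]], refs[[3]], step[[3]],
                        step[[4]], dih)
      elem <- substr(step[[1]], 1, 1)
      add(i, res, step[[1]], xyz, elem)
      placed[[step[[1]]]] <- xyz
    }
  }
  new_structure(id, do.call(rbind, rows))
}

# rotate a residue's distal atoms about a chi bond axis by delta degrees
rotate_chi <- function(atoms, res_key, resname, k, delta) {
  quad <- CHI_ATOMS[[resname]][[k]]
  moved <- CHI_MOVED[[resname]][[k]]
  ri <- which(atoms$res_key == res_key)
  i2 <- ri[match(quad[2], atoms$atom[ri])]
  i3 <- ri[match(quad[3], atoms$atom[ri])]
  im <- ri[atoms$atom[ri] %in% moved]
  if (is.na(i2) || is.na(i3) || !length(im)) return(atoms)
  p2 <- c(atoms$x[i2], atoms$y[i2], atoms$z[i2])
  p3 <- c(atoms$x[i3], atoms$y[i3], atoms$z[i3])
  R <- rotation_about_axis(p3 - p2, delta)
  xyz <- cbind(atoms$x[im], atoms$y[im], atoms$z[im])
  xyz <- sweep(sweep(xyz, 2, p3) %*% t(R), 2, p3, "+")
  atoms$x[im] <- xyz[, 1]; atoms$y[im] <- xyz[, 2]; atoms$z[im] <- xyz[, 3]
  atoms
}

#' Generate a graded decoy of a target
#'
#' Perturbs each sidechain chi-angle by Gaussian noise (rotating the
#' distal atoms about the chi bond), adds i.i.d. Gaussian coordinate
#' noise to every atom, optionally applies a rigid rotation to a residue
#' segment (a domain-swap-style error), and writes per-residue pLDDT
#' into the B-factor column as the decoy's true per-residue lDDT plus
#' Gaussian self-estimate noise, clamped to [0, 100].
#'
#' @param target A `casp_structure` from [build_target()].
#' @param spec A `synthetic_spec` carrying `sigma_xyz`, `sigma_chi`,
#'   `plddt_tau`.
#' @param seed Seed for the decoy (default `spec$seed + 1`).
#' @param segment_rotation Optional `list(start, end, angle)`: residues
#'   (author numbers) rotated rigidly by `angle` degrees about an axis
#'   through the segment start.
#' @param id Structure id.
#' @return A `casp_structure` with pLDDT in B-factors.
#' @export
make_decoy <- function(target, spec, seed = spec$seed + 1,
                       segment_rotation = NULL, id = "decoy") {
  set.seed(seed)
  atoms <- target$atoms
  rt <- residue_table(target)
  if (spec$sigma_chi > 0) {
    for (i in seq_len(nrow(rt))) {
      res <- canonical_resname(rt$resname[i])
      nk <- length(CHI_ATOMS[[res]])
      if (res %in% names(CHI_MOVED) && nk > 0) {
        for (k in seq_len(nk)) {
          atoms <- rotate_chi(atoms, rt$res_key[i], res, k,
                              stats::rnorm(1, 0, spec$sigma_chi))
        }
      }
    }
  }
  if (!is.null(segment_rotation)) {
    sel <- which(atoms$resno >= segment_rotation$start &
                   atoms$resno <= segment_rotation$end)
    if (length(sel)) {
      origin <- c(atoms$x[sel[1]], atoms$y[sel[1]], atoms$z[sel[1]])
      R <- rotation_about_axis(c(0, 0, 1), segment_rotation$angle)
      xyz <- cbind(atoms$x[sel], atoms$y[sel], atoms$z[sel])
      xyz <- sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, "+")
      atoms$x[sel] <- xyz[, 1]; atoms$y[sel] <- xyz[, 2]
      atoms$z[sel] <- xyz[, 3]
    }
  }
  if (spec$sigma_xyz > 0) {
    n <- nrow(atoms)
    atoms$x <- atoms$x + stats::rnorm(n, 0, spec$sigma_xyz)
    atoms$y <- atoms$y + stats::rnorm(n, 0, spec$sigma_xyz)
    atoms$z <- atoms$z + stats::rnorm(n, 0, spec$sigma_xyz)
  }
  decoy <- new_structure(id, atoms)
  corr <- map_residues(target, decoy)
  ld <- lddt(target, decoy, corr)$per_residue
  plddt <- pmin(pmax(ld + stats::rnorm(length(ld), 0, spec$plddt_tau), 0), 100)
  # per-residue pLDDT goes into every atom's B-factor (CA carries it for ASE)
  decoy$atoms$b <- unname(plddt[decoy$atoms$res_key])
  decoy$atoms$b[is.na(decoy$atoms$b)] <- 0
  decoy
}

#' Latent generative model for score tables
#'
#' @param n_groups,n_targets Numbers of groups and targets.
#' @param eus_per_target EUs per target (constant).
#' @param skill Per-group latent skill (default: normal with s.d.
#'   `2 * noise_sd`, the regime where ranking recovery is expected).
#' @param difficulty Per-target latent difficulty (default: normal,
#'   s.d. `2 * noise_sd`).
#' @param noise_sd Observation noise s.d. on the 0-100 metric scale.
#' @param p_missing Probability that a (group, EU) submission block is
#'   entirely missing.
#' @param seed Seed for drawing the latent parameters.
#' @return List of class `latent_experiment`.
#' @export
latent_experiment <- function(n_groups = 20, n_targets = 30,
                              eus_per_target = 1, skill = NULL,
                              difficulty = NULL, noise_sd = 5,
                              p_missing = 0.1, seed = 1) {
  stopifnot(p_missing >= 0, p_missing < 1)
  set.seed(seed)
  if (is.null(skill)) skill <- stats::rnorm(n_groups, 0, 2 * noise_sd)
  if (is.null(difficulty)) difficulty <- stats::rnorm(n_targets, 0, 2 * noise_sd)
  structure(list(n_groups = n_groups, n_targets = n_targets,
                 eus_per_target = eus_per_target,
                 skill = skill, difficulty = difficulty,
                 noise_sd = noise_sd, p_missing = p_missing, seed = seed),
            class = "latent_experiment")
}

# base level per metric on its own scale; molprobity is inverted
METRIC_BASE <- c(gdt_ts = 60, gdt_ha = 55, ase = 80, rellg_const = 50,
                 sphgr = 60, cad_aa = 70, gdc_sc = 50, al0_p = 70, lddt = 75)

#' Simulate a long score table from the latent model
#'
#' Every (group, EU, model 1..5, metric) value is
#' `clip(base + skill_g - difficulty_t + N(0, noise_sd))` on the 0-100
#' scale; MolProbity is generated on its inverted scale (lower = better).
#' Whole (group, EU) blocks are dropped with probability `p_missing`.
#'
#' @param x A `latent_experiment`.
#' @param seed Seed for the observation noise and missingness.
#' @return Long score table (data frame) with attributes `skill`,
#'   `difficulty`, `eus` (EU/weight data frame).
#' @export
simulate_experiment <- function(x, seed = x$seed) {
  set.seed(seed)
  groups <- sprintf("G%02d", seq_len(x$n_groups))
  targets <- sprintf("T%03d", seq_len(x$n_targets))
  eus <- unlist(lapply(targets, function(t)
    paste0(t, "-D", seq_len(x$eus_per_target))))
  eu_target <- rep(targets, each = x$eus_per_target)
  metrics <- c(names(METRIC_BASE), "molprobity")
  grid <- expand.grid(group = groups, eu = eus, model = 1:5,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$target <- eu_target[match(grid$eu, eus)]
  grid$phase <- 1L
  skill <- setNames(x$skill, groups)
  diff <- setNames(x$difficulty, targets)
  base_effect <- skill[grid$group] - diff[grid$target]
  rows <- lapply(metrics, function(m) {
    g <- grid
    g$metric <- m
    eps <- stats::rnorm(nrow(g), 0, x$noise_sd)
    if (m == "molprobity") {
      g$value <- pmin(pmax(2.5 - 0.05 * (base_effect + eps), 0), 6)
    } else {
      g$value <- pmin(pmax(METRIC_BASE[m] + base_effect + eps, 0), 100)
    }
    g
  })
  tab <- do.call(rbind, rows)
  # drop whole (group, EU) submission blocks
  blocks <- expand.grid(group = groups, eu = eus, stringsAsFactors = FALSE)
  drop <- blocks[stats::runif(nrow(blocks)) < x$p_missing, ]
  if (nrow(drop)) {
    tab <- tab[!(paste(tab$group, tab$eu) %in% paste(drop$group, drop$eu)), ]
  }
  tab <- tab[order(tab$group, tab$eu, tab$model, tab$metric), ]
  rownames(tab) <- NULL
  tab <- tab[c("group", "target", "eu", "phase", "model", "metric", "value")]
  attr(tab, "skill") <- skill
  attr(tab, "difficulty") <- diff
  attr(tab, "eus") <- data.frame(eu = eus, target = eu_target,
                                 weight = 1 / x$eus_per_target,
                                 stringsAsFactors = FALSE)
  tab
}
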