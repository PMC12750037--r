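test_that("Kabsch superposition recovers exact transforms and forbids reflection", {
  P <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.3, 0.4, 1.2), 4, 3, byrow = TRUE)
  sup <- kabsch_superpose(P, P)
  expect_equal(sup$rmsd, 0, tolerance = 1e-12)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-9)

  Q <- sweep(P, 2, c(5, 0, 0), "+")
  sup2 <- kabsch_superpose(P, Q)
  expect_equal(sup2$rmsd, 0, tolerance = 1e-10)
  expect_equal(sup2$translation, c(-5, 0, 0), tolerance = 1e-9)
  expect_equal(apply_superposition(sup2, Q), P, tolerance = 1e-9)

  # mirror image of a chiral 4-point set: rmsd > 0, determinant stays +1,
  # and the minimum matches a quaternion brute-force oracle
  Qm <- P %*% diag(c(-1, 1, 1))
  sup3 <- kabsch_superpose(P, Qm)
  expect_gt(sup3$rmsd, 0.1)
  expect_equal(det(sup3$rotation), 1, tolerance = 1e-9)
  expect_equal(sup3$rmsd, quaternion_fit_rmsd(P, Qm), tolerance = 1e-4)

  expect_error(kabsch_superpose(P[1:2, ], P[1:2, ]), "at least 3")
  coll <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(coll, coll), "collinear")
})

test_that("GDC follows the ten-threshold weighted formula", {
  s <- ten_ca_structure()
  corr <- map_residues(s, s)
  sup <- structure(list(rotation = diag(3), translation = c(0, 0, 0),
                        rmsd = 0, support = 1:10), class = "superposition")
  expect_equal(gdc(s, s, corr, "all", sup)$score, 100)
  expect_equal(gdc(s, s, corr, "mc", sup)$score, 100)

  # single selected atom displaced 2.2 A passes thresholds 2.5..5.0 only:
  # sum of weights for k = 5..10 is 21, so GDC = 100 * 21 / 55
  one <- point_structure(cbind(0, 0, 0))
  m_one <- point_structure(cbind(2.2, 0, 0))
  corr1 <- map_residues(one, m_one)
  idsup <- structure(list(rotation = diag(3), translation = c(0, 0, 0),
                          rmsd = 0, support = 1L), class = "superposition")
  expect_equal(gdc(one, m_one, corr1, "all", idsup)$score, 100 * 21 / 55,
               tolerance = 1e-9)

  m_far <- point_structure(cbind(10, 0, 0))
  corr2 <- map_residues(one, m_far)
  expect_equal(gdc(one, m_far, corr2, "all", idsup)$score, 0)

  gly <- point_structure(cbind(0, 0, 0), resname = "GLY")
  expect_error(gdc(gly, gly, map_residues(gly, gly), "sc", idsup),
               "no atoms")
})

test_that("AL0_P counts close-and-nearest residues under the superposition", {
  s <- point_structure(cbind(3.8 * (0:5), 0, 0))
  corr <- map_residues(s, s)
  idsup <- structure(list(rotation = diag(3), translation = c(0, 0, 0),
                          rmsd = 0, support = 1:6), class = "superposition")
  expect_equal(al0_p(s, s, corr, idsup), 100)

  m <- s
  m$atoms$z[6] <- 10
  m <- caspr:::new_structure("m", m$atoms)
  expect_equal(al0_p(s, m, map_residues(s, m), idsup), 100 * 5 / 6,
               tolerance = 1e-9)

  # register shift: model CA_i sits on target CA_{i+1}; nearest-neighbor
  # condition fails everywhere
  reg <- s
  reg$atoms$x <- reg$atoms$x + 3.8
  reg <- caspr:::new_structure("reg", reg$atoms)
  expect_equal(al0_p(s, reg, map_residues(s, reg), idsup), 0)
})

test_that("lDDT matches hand enumeration on a 3-residue toy", {
  # target pairwise distances (5, 7, 6); model (5, 10, 6): the 3 A error
  # on pair (1,3) passes only the 4 A threshold
  t3 <- point_structure(rbind(c(0, 0, 0), c(5, 0, 0), c(3.8, 5.8788, 0)))
  m3 <- point_structure(rbind(c(0, 0, 0), c(5, 0, 0), c(8.9, 4.5596, 0)))
  res <- lddt(t3, m3, map_residues(t3, m3))
  expect_equal(unname(res$per_residue), c(62.5, 100, 62.5), tolerance = 1e-3)
  expect_equal(res$score, 75, tolerance = 1e-3)

  expect_equal(lddt(t3, t3, map_residues(t3, t3))$score, 100)

  # missing model atom: pairs involving it are scored not preserved
  m_miss <- t3
  m_miss$atoms <- m_miss$atoms[1:2, ]
  m_miss <- caspr:::new_structure("miss", m_miss$atoms)
  expect_lt(lddt(t3, m_miss, map_residues(t3, m_miss))$score, 100)

  far <- point_structure(rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_error(lddt(far, far, map_residues(far, far)), "reference pairs")
})

test_that("lDDT is superposition-free", {
  spec <- synthetic_spec(seed = 5, sigma_xyz = 1)
  t <- build_target(spec)
  d <- make_decoy(t, spec)
  corr <- map_residues(t, d)
  base <- lddt(t, d, corr)$score
  moved <- transform_structure(d, angle = 111, shift = c(20, -7, 3))
  expect_equal(lddt(t, moved, corr)$score, base)
})

test_that("ASE measures pLDDT/lDDT agreement on the 0-100 scale", {
  keys <- paste("A", 1:4, "", sep = "|")
  ld <- setNames(c(80, 70, 90, 60), keys)
  m_eq <- point_structure(cbind(3.8 * (0:3), 0, 0), b = c(80, 70, 90, 60))
  expect_equal(ase(m_eq, ld), 100)
  m_off <- point_structure(cbind(3.8 * (0:3), 0, 0), b = c(90, 80, 100, 70))
  expect_equal(ase(m_off, ld), 90)
  m_max <- point_structure(cbind(3.8 * (0:3), 0, 0), b = 100)
  expect_equal(ase(m_max, setNames(rep(0, 4), keys)), 0)
  m_none <- point_structure(cbind(3.8 * (0:3), 0, 0), b = 0)
  expect_error(ase(m_none, ld), "self-estimate")
})

test_that("AAA applies the 40-degree rule per chi-angle", {
  ser_at <- function(chi1) {
    s <- atoms_structure(data.frame(
      resno = 1, resname = "SER", atom = c("N", "CA", "CB", "OG"),
      x = c(0, 1.5, 2.0, 0), y = c(0, 0, 1.4, 0), z = c(0, 0, 0, 0)))
    og <- caspr:::place_atom(c(0, 0, 0), c(1.5, 0, 0), c(2.0, 1.4, 0),
                             1.42, 110.5, chi1)
    s$atoms$x[4] <- og[1]; s$atoms$y[4] <- og[2]; s$atoms$z[4] <- og[3]
    s
  }
  t <- ser_at(100)
  expect_equal(aaa(t, ser_at(100 + 39), map_residues(t, t))$score, 100)
  expect_equal(aaa(t, ser_at(100 + 41), map_residues(t, t))$score, 0)

  # identity on a full synthetic target
  spec <- synthetic_spec(seed = 8)
  s <- build_target(spec)
  expect_equal(aaa(s, s, map_residues(s, s))$score, 100)

  # Leu with chi1 off 10 and chi2 off 90: one of two chis within 40
  leu <- build_target(synthetic_spec(
    topology = list(list(type = "helix", length = 1)),
    residue_palette = "LEU", seed = 2))
  leu_mod <- leu
  leu_mod$atoms <- caspr:::rotate_chi(leu_mod$atoms, leu_mod$atoms$res_key[1],
                                      "LEU", 1L, 10)
  leu_mod$atoms <- caspr:::rotate_chi(leu_mod$atoms, leu_mod$atoms$res_key[1],
                                      "LEU", 2L, 90)
  leu_mod <- caspr:::new_structure("m", leu_mod$atoms)
  r <- aaa(leu, leu_mod, map_residues(leu, leu_mod))
  expect_equal(unname(r$per_residue), 50)
  expect_equal(r$score, 50)

  gly <- point_structure(cbind(0, 0, 0), resname = "GLY")
  expect_error(aaa(gly, gly, map_residues(gly, gly)), "chi-bearing")
})

test_that("AAA compares symmetric terminal groups modulo 180 degrees", {
  phe <- build_target(synthetic_spec(
    topology = list(list(type = "helix", length = 1)),
    residue_palette = "PHE", seed = 2))
  flipped <- phe
  flipped$atoms <- caspr:::rotate_chi(flipped$atoms, flipped$atoms$res_key[1],
                                      "PHE", 2L, 180)
  flipped <- caspr:::new_structure("flip", flipped$atoms)
  expect_equal(aaa(phe, flipped, map_residues(phe, flipped))$score, 100)
})

test_that("site_mean splits per-residue scores into site and complement", {
  pr <- c(A = 80, B = 60, C = 100)
  r <- site_mean(pr, c("A", "B"))
  expect_equal(r$site_mean, 70)
  expect_equal(r$complement_mean, 100)
  expect_equal(site_mean(c(A = 100, B = 100), "A")$site_mean, 100)
  expect_warning(r2 <- site_mean(pr, c("A", "Z")), "not present")
  expect_equal(r2$site_mean, 80)
  expect_error(suppressWarnings(site_mean(pr, "Z")), "no members")
})

test_that("superposition-based metrics are rigid-motion invariant", {
  spec <- synthetic_spec(seed = 13, sigma_xyz = 1.5, sigma_chi = 25)
  t <- build_target(spec)
  d <- make_decoy(t, spec)
  corr <- map_residues(t, d)
  base_ts <- gdt_ts(t, d, corr)
  base_aaa <- aaa(t, d, corr)$score
  moved <- transform_structure(d, axis = c(2, 1, -1), angle = 63,
                               shift = c(-8, 4, 12))
  expect_equal(gdt_ts(t, moved, corr), base_ts, tolerance = 1e-6)
  expect_equal(aaa(t, moved, corr)$score, base_aaa, tolerance = 1e-6)
  # moving the target as well leaves everything unchanged
  t_moved <- transform_structure(t, axis = c(0, 1, 1), angle = -40,
                                 shift = c(3, 3, 3))
  expect_equal(gdt_ts(t_moved, moved, corr), base_ts, tolerance = 1e-6)
})
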