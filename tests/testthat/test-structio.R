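test_that("PDB parsing turns ATOM records into residues and atoms", {
  s <- parse_structure(text = two_ca_pdb(), format = "pdb", id = "toy")
  expect_equal(n_residues(s), 2)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$resname, c("GLY", "ALA"))
  expect_equal(s$atoms$b, c(90, 80))
  expect_equal(s$atoms$x, c(0, 3.8))
})

test_that("minimal mmCIF parses to the same structure field by field", {
  s_pdb <- parse_structure(text = two_ca_pdb(), format = "pdb", id = "toy")
  s_cif <- parse_structure(text = two_ca_mmcif(), format = "mmcif", id = "toy")
  for (col in c("record", "chain", "resno", "icode", "resname", "atom",
                "x", "y", "z", "occ", "b"))
    expect_equal(s_cif$atoms[[col]], s_pdb$atoms[[col]], info = col)
})

test_that("malformed coordinate fields raise format errors naming the line", {
  bad <- sub("   0.000", "   xx.00", two_ca_pdb())
  expect_error(parse_structure(text = bad, format = "pdb"),
               "line 1")
  expect_error(parse_structure(text = "", format = "pdb"), "empty")
  expect_error(parse_structure(text = "REMARK nothing here", format = "pdb"),
               "empty structure")
})

test_that("alternate locations resolve to highest occupancy, ties first", {
  lines <- c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.40 10.00          C",
    "ATOM      2  CA BGLY A   1       1.000   0.000   0.000  0.60 10.00          C",
    "ATOM      3  CA ASER A   2       5.000   0.000   0.000  0.50 10.00          C",
    "ATOM      4  CA BSER A   2       6.000   0.000   0.000  0.50 10.00          C")
  s <- parse_structure(text = paste(lines, collapse = "\n"), format = "pdb")
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x, c(1, 5))  # B wins on occupancy; A wins the tie
})

test_that("PDB round trip preserves coordinates and identifiers", {
  spec <- synthetic_spec(seed = 3)
  s <- build_target(spec, id = "rt")
  s2 <- parse_structure(text = paste(write_pdb(s), collapse = "\n"),
                        format = "pdb", id = "rt")
  expect_equal(s2$atoms$x, s$atoms$x, tolerance = 1e-3)
  expect_equal(s2$atoms$y, s$atoms$y, tolerance = 1e-3)
  expect_equal(s2$atoms$z, s$atoms$z, tolerance = 1e-3)
  expect_identical(s2$atoms$resname, s$atoms$resname)
  expect_identical(s2$atoms$atom, s$atoms$atom)
  expect_identical(s2$atoms$resno, s$atoms$resno)
  expect_identical(s2$atoms$chain, s$atoms$chain)
})

test_that("EU extraction selects ranges inclusively and is idempotent", {
  s <- ten_ca_structure()
  eu <- eu_definition("T", "T-D1", list(list(chain = "A", start = 3, end = 7)))
  e <- extract_eu(s, eu)
  expect_equal(n_residues(e), 5)
  expect_equal(sort(unique(e$atoms$resno)), 3:7)
  e2 <- extract_eu(e, eu)
  expect_equal(e2$atoms[names(e$atoms)], e$atoms)

  eu2 <- eu_definition("T", "T-D2",
                       list(list(chain = "A", start = 1, end = 2),
                            list(chain = "A", start = 9, end = 10)))
  e3 <- extract_eu(s, eu2)
  expect_equal(n_residues(e3), 4)
  expect_equal(sort(unique(e3$atoms$resno)), c(1, 2, 9, 10))

  eu_bad <- eu_definition("T", "T-D3", list(list(chain = "B", start = 1, end = 5)))
  expect_error(extract_eu(s, eu_bad), "chain")
})

test_that("EU extraction keeps only ligands within 5 A of kept residues", {
  s <- ten_ca_structure()
  lig <- data.frame(record = "HETATM", chain = "A", resno = c(101L, 102L),
                    icode = "", resname = c("ZN", "ZN"), atom = "ZN",
                    x = c(3.8 * 2 + 1, 200), y = 0, z = 0, occ = 1, b = 0,
                    elem = "ZN", stringsAsFactors = FALSE)
  s$atoms <- rbind(s$atoms[names(s$atoms) != "res_key"][, ],
                   lig)[, names(lig)]
  s <- caspr:::new_structure("t10+lig", s$atoms)
  eu <- eu_definition("T", "T-D1", list(list(chain = "A", start = 1, end = 5)))
  e <- extract_eu(s, eu)
  het <- e$atoms[e$atoms$record == "HETATM", ]
  expect_equal(het$resno, 101L)  # the 200-A-away metal is dropped
})

test_that("residue correspondence follows author numbering", {
  s <- ten_ca_structure()
  corr <- map_residues(s, s)
  expect_equal(nrow(corr$pairs), 10)
  expect_equal(corr$coverage, 1)

  m <- s
  m$atoms <- m$atoms[!(m$atoms$resno %in% c(2, 5)), ]
  m <- caspr:::new_structure("m", m$atoms)
  corr2 <- map_residues(s, m)
  expect_equal(nrow(corr2$pairs), 8)
  expect_equal(corr2$coverage, 0.8)

  shifted <- s
  shifted$atoms$resno <- shifted$atoms$resno + 100L
  shifted <- caspr:::new_structure("shift", shifted$atoms)
  expect_error(map_residues(s, shifted), "numbering")
})

test_that("chi angles follow the standard quadruples and degrade gracefully", {
  gly <- point_structure(cbind(0, 0, 0), resname = "GLY")
  expect_equal(chi_angles(gly)[[1]], numeric(0))
  ala <- atoms_structure(data.frame(
    resno = 1, resname = "ALA",
    atom = c("N", "CA", "CB"),
    x = c(0, 1.46, 2.0), y = c(0, 0, 1.2), z = 0))
  expect_equal(chi_angles(ala)[[1]], numeric(0))

  # Ser with N-CA-CB-OG exactly planar trans: chi1 = 180
  ser <- atoms_structure(data.frame(
    resno = 1, resname = "SER",
    atom = c("N", "CA", "CB", "OG"),
    x = c(0, 1.5, 2.0, 3.5),
    y = c(0, 0, 1.4, 1.4),
    z = c(0, 0, 0, 0)))
  expect_equal(chi_angles(ser)[[1]], 180)

  # missing OG truncates the list
  ser2 <- atoms_structure(data.frame(
    resno = 1, resname = "SER", atom = c("N", "CA", "CB"),
    x = c(0, 1.5, 2.0), y = c(0, 0, 1.4), z = 0))
  expect_equal(chi_angles(ser2)[[1]], numeric(0))
})

test_that("chi angles are invariant under rigid motion", {
  spec <- synthetic_spec(seed = 11)
  s <- build_target(spec)
  chis <- chi_angles(s)
  moved <- transform_structure(s, axis = c(1, -2, 0.5), angle = 77,
                               shift = c(-4, 9, 1))
  chis2 <- chi_angles(moved)
  for (k in names(chis)) {
    expect_equal(length(chis2[[k]]), length(chis[[k]]))
    if (length(chis[[k]]))  # compare circularly: 180 and -180 coincide
      expect_lt(max(caspr:::circ_diff(chis2[[k]], chis[[k]])), 1e-6)
  }
})

test_that("chi angles and fitted rmsd agree with an independent implementation", {
  skip_if_not_installed("bio3d")
  spec <- synthetic_spec(seed = 9)
  t <- build_target(spec, id = "xcheck")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(t, f)
  tor <- bio3d::torsion.pdb(bio3d::read.pdb(f, verbose = FALSE))
  ours <- chi_angles(t)
  chi1 <- vapply(ours, function(v) if (length(v)) v[1] else NA_real_, 0)
  chi2 <- vapply(ours, function(v) if (length(v) > 1) v[2] else NA_real_, 0)
  for (k in list(list(chi1, "chi1"), list(chi2, "chi2"))) {
    ref <- tor$tbl[, k[[2]]]
    both <- !is.na(k[[1]]) & !is.na(ref)
    expect_gt(sum(both), 5)
    expect_lt(max(caspr:::circ_diff(k[[1]][both], ref[both])), 0.2)
  }
  # rigid-fit rmsd against bio3d's least-squares fit
  d <- make_decoy(t, synthetic_spec(seed = 9, sigma_xyz = 1))
  P <- caspr:::atom_coords(t, caspr:::polymer_keys(t), "CA")
  Q <- caspr:::atom_coords(d, caspr:::polymer_keys(d), "CA")
  sup <- kabsch_superpose(P, Q)
  fit <- suppressWarnings(bio3d::fit.xyz(fixed = as.numeric(t(P)),
                                         mobile = as.numeric(t(Q))))
  expect_equal(sup$rmsd, bio3d::rmsd(as.numeric(t(P)), fit),
               tolerance = 1e-3)
})
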