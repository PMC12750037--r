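# Fixtures built in code: minimal structures, handcrafted PDB text, and
# small independent oracles used across the tests.

# structure with one named atom per residue at given coordinates
point_structure <- function(xyz, id = "pts", resname = "GLY", atom = "CA",
                            chain = "A", resno = seq_len(nrow(xyz)),
                            b = 0) {
  xyz <- as.matrix(xyz)
  atoms <- data.frame(record = "ATOM", chain = chain, resno = resno,
                      icode = "", resname = resname, atom = atom,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      occ = 1, b = b, elem = "C",
                      stringsAsFactors = FALSE)
  caspr:::new_structure(id, atoms)
}

# structure from an explicit atom table (record defaults to ATOM)
atoms_structure <- function(df, id = "s") {
  defaults <- list(record = "ATOM", chain = "A", icode = "", occ = 1,
                   b = 0, elem = "C")
  for (nm in names(defaults)) if (is.null(df[[nm]])) df[[nm]] <- defaults[[nm]]
  caspr:::new_structure(id, df)
}

# a rigid motion applied to a whole structure
transform_structure <- function(s, axis = c(1, 2, 3), angle = 30,
                                shift = c(5, -3, 2)) {
  R <- caspr:::rotation_about_axis(axis, angle)
  xyz <- as.matrix(s$atoms[c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

pdb_line <- function(resno, resname, atom, x, y, z, chain = "A",
                     occ = 1, b = 0, record = "ATOM", elem = "C") {
  sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, resno, sprintf(" %-3s", atom), resname, chain, resno,
          x, y, z, occ, b, elem)
}

two_ca_pdb <- function() {
  paste(pdb_line(1, "GLY", "CA", 0, 0, 0, b = 90),
        pdb_line(2, "ALA", "CA", 3.8, 0, 0, b = 80),
        sep = "\n")
}

two_ca_mmcif <- function() {
  paste(
    "data_toy",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "ATOM 1 C CA . GLY A 1 ? 0.000 0.000 0.000 1.00 90.00",
    "ATOM 2 C CA . ALA A 2 ? 3.800 0.000 0.000 1.00 80.00",
    sep = "\n")
}

# a 10-residue single-chain CA trace along x
ten_ca_structure <- function(id = "t10") {
  point_structure(cbind(3.8 * (0:9), 0, 0), id = id)
}

# brute-force rigid-fit oracle: minimize rmsd over unit-quaternion
# rotations by multi-start Nelder-Mead (independent of the Kabsch path)
quaternion_fit_rmsd <- function(P, Q, n_starts = 40, seed = 7) {
  set.seed(seed)
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  rot_from_q <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  obj <- function(q) {
    if (sum(q^2) < 1e-12) return(1e6)
    R <- rot_from_q(q)
    sqrt(mean(rowSums((Qc %*% t(R) - Pc)^2)))
  }
  best <- Inf
  for (i in seq_len(n_starts)) {
    q0 <- stats::rnorm(4)
    res <- stats::optim(q0, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-12))
    best <- min(best, res$value)
  }
  best
}

# brute-force assignment oracle: minimum total |difference| over all
# injections of reference items into source items
brute_force_assignment <- function(d_source, d_reference) {
  ns <- length(d_source); nr <- length(d_reference)
  perms <- function(v, k) {
    if (k == 0) return(list(integer(0)))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i], k - 1))
        out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  best <- Inf
  for (p in perms(seq_len(ns), nr))
    best <- min(best, sum(abs(d_source[p] - d_reference)))
  best
}

# small latent-model score table used by several ranking tests
toy_score_table <- function(groups = c("A", "B"), eus = c("T1-D1"),
                            models = 1:2, metrics = c("gdt_ha", "lddt"),
                            value_fun = function(g, e, m, met) 50) {
  grid <- expand.grid(group = groups, eu = eus, model = models,
                      metric = metrics, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid$target <- sub("-D[0-9]+$", "", grid$eu)
  grid$phase <- 1L
  grid$value <- mapply(value_fun, grid$group, grid$eu, grid$model,
                       grid$metric)
  grid[c("group", "target", "eu", "phase", "model", "metric", "value")]
}

# weight scheme with all mass on one metric
single_metric_scheme <- function(metric = "gdt_ha") {
  data.frame(metric = metric, weight = 1, orientation = "higher_better",
             stringsAsFactors = FALSE)
}
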