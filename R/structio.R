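# Structure I/O: PDB / minimal mmCIF parsing, EU extraction, residue
# correspondence, and chi-angle computation.
#
# A structure is a light container: one atom table in file order plus an id.
# Polymer atoms come from ATOM records, hetero groups (metals, ligands)
# from HETATM. Models carry predictor pLDDT (0-100) in the B-factor column.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

# common nonstandard residues mapped to their parent standard type for
# metric purposes; anything else is kept but excluded from chi computation
NONSTANDARD_MAP <- c(MSE = "MET", SEC = "CYS", PYL = "LYS", HYP = "PRO")

new_structure <- function(id, atoms) {
  atoms$res_key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "|")
  structure(list(id = id, atoms = atoms), class = "casp_structure")
}

#' @export
print.casp_structure <- function(x, ...) {
  pol <- x$atoms[x$atoms$record == "ATOM", ]
  het <- x$atoms[x$atoms$record == "HETATM", ]
  cat("<casp_structure>", x$id, "\n")
  cat("  polymer residues:", length(unique(pol$res_key)),
      " atoms:", nrow(pol), "\n")
  cat("  hetero groups:   ", length(unique(het$res_key)),
      " atoms:", nrow(het), "\n")
  invisible(x)
}

#' Parse a structure from PDB or minimal mmCIF text
#'
#' Reads ATOM and HETATM records into an atom table. Alternate locations
#' are resolved to the highest-occupancy copy (ties: first in file).
#' HETATM groups (metals, ligands, waters) are kept separately from the
#' polymer and are available to site-based analyses.
#'
#' @param text Character: raw file content (single string or vector of
#'   lines). Exactly one of `text`/`file` must be given.
#' @param file Path to a file to read.
#' @param format `"pdb"` or `"mmcif"`.
#' @param id Identifier stored on the returned structure.
#' @return A `casp_structure`: list with `id` and an `atoms` data frame
#'   (record, chain, resno, icode, resname, atom, x, y, z, occ, b, elem).
#' @examples
#' pdb <- paste(
#'   "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00 90.00",
#'   "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00 80.00",
#'   sep = "\n")
#' s <- parse_structure(text = pdb, format = "pdb", id = "toy")
#' n_residues(s)
#' @export
parse_structure <- function(text = NULL, file = NULL, format = c("pdb", "mmcif"),
                            id = "structure") {
  format <- match.arg(format)
  if (is.null(text) == is.null(file))
    stop("supply exactly one of `text` or `file`")
  if (!is.null(file)) {
    text <- readLines(file, warn = FALSE)
    if (id == "structure") id <- sub("\\.[^.]*$", "", basename(file))
  }
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  if (!length(lines) || all(!nzchar(lines))) stop("empty structure input")
  atoms <- switch(format,
                  pdb = parse_pdb_lines(lines),
                  mmcif = parse_mmcif_lines(lines))
  if (!nrow(atoms)) stop("no ATOM/HETATM records found: empty structure")
  atoms <- resolve_altloc(atoms)
  atoms$altloc <- NULL
  rownames(atoms) <- NULL
  new_structure(id, atoms)
}

parse_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  keep <- which(trimws(rec) %in% c("ATOM", "HETATM"))
  if (!length(keep)) return(empty_atoms())
  ln <- lines[keep]
  num <- function(s, what, lineno) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) & nzchar(trimws(s)) | !nzchar(trimws(s)) & what != "occ/b")
    if (length(bad))
      stop(sprintf("PDB format error: non-numeric %s field at line %d: '%s'",
                   what, lineno[bad[1]], trimws(s[bad[1]])))
    v
  }
  x <- num(substr(ln, 31, 38), "x coordinate", keep)
  y <- num(substr(ln, 39, 46), "y coordinate", keep)
  z <- num(substr(ln, 47, 54), "z coordinate", keep)
  occ <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
  occ[is.na(occ)] <- 1
  b <- suppressWarnings(as.numeric(substr(ln, 61, 66)))
  b[is.na(b)] <- 0
  resno <- suppressWarnings(as.integer(substr(ln, 23, 26)))
  if (anyNA(resno))
    stop(sprintf("PDB format error: non-numeric residue number at line %d",
                 keep[which(is.na(resno))[1]]))
  elem <- trimws(substr(ln, 77, 78))
  data.frame(
    record = trimws(substr(ln, 1, 6)),
    chain = substr(ln, 22, 22),
    resno = resno,
    icode = trimws(substr(ln, 27, 27)),
    resname = trimws(substr(ln, 18, 20)),
    atom = trimws(substr(ln, 13, 16)),
    altloc = substr(ln, 17, 17),
    x = x, y = y, z = z, occ = occ, b = b,
    elem = ifelse(nzchar(elem), elem, guess_element(trimws(substr(ln, 13, 16)))),
    stringsAsFactors = FALSE)
}

# element from the PDB atom name when column 77-78 is blank
guess_element <- function(atom_name) {
  first <- substr(gsub("[0-9']", "", atom_name), 1, 1)
  ifelse(first %in% c("C", "N", "O", "S", "P", "H"), first, atom_name)
}

parse_mmcif_lines <- function(lines) {
  lines <- trimws(lines)
  # locate the atom_site loop: collect its field names, then data rows
  loop_starts <- which(lines == "loop_")
  fields <- character(0); data_rows <- character(0)
  for (st in loop_starts) {
    i <- st + 1
    f <- character(0)
    while (i <= length(lines) && startsWith(lines[i], "_")) {
      f <- c(f, lines[i]); i <- i + 1
    }
    if (any(startsWith(f, "_atom_site."))) {
      fields <- sub("^_", "", f)
      while (i <= length(lines) && nzchar(lines[i]) &&
             !startsWith(lines[i], "_") && !startsWith(lines[i], "loop_") &&
             !startsWith(lines[i], "#")) {
        data_rows <- c(data_rows, lines[i]); i <- i + 1
      }
      break
    }
  }
  if (!length(fields)) stop("mmCIF format error: no _atom_site loop found")
  toks <- strsplit(data_rows, "[[:space:]]+")
  nf <- length(fields)
  bad <- which(vapply(toks, length, 1L) != nf)
  if (length(bad))
    stop(sprintf("mmCIF format error: row %d has %d tokens, expected %d",
                 bad[1], length(toks[[bad[1]]]), nf))
  m <- do.call(rbind, toks)
  colnames(m) <- fields
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% colnames(m)) return(m[, nm])
    rep(NA_character_, nrow(m))
  }
  cif_na <- function(v, default = "") ifelse(v %in% c("?", ".", NA), default, v)
  numf <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    if (anyNA(out))
      stop(sprintf("mmCIF format error: non-numeric %s in atom_site row %d",
                   what, which(is.na(out))[1]))
    out
  }
  occ <- suppressWarnings(as.numeric(cif_na(pick("atom_site.occupancy"), "1")))
  occ[is.na(occ)] <- 1
  b <- suppressWarnings(as.numeric(cif_na(pick("atom_site.B_iso_or_equiv"), "0")))
  b[is.na(b)] <- 0
  data.frame(
    record = pick("atom_site.group_PDB"),
    chain = cif_na(pick("atom_site.auth_asym_id", "atom_site.label_asym_id"), "A"),
    resno = as.integer(pick("atom_site.auth_seq_id", "atom_site.label_seq_id")),
    icode = cif_na(pick("atom_site.pdbx_PDB_ins_code")),
    resname = pick("atom_site.auth_comp_id", "atom_site.label_comp_id"),
    atom = gsub('"', "", pick("atom_site.auth_atom_id", "atom_site.label_atom_id")),
    altloc = cif_na(pick("atom_site.label_alt_id"), " "),
    x = numf(pick("atom_site.Cartn_x"), "Cartn_x"),
    y = numf(pick("atom_site.Cartn_y"), "Cartn_y"),
    z = numf(pick("atom_site.Cartn_z"), "Cartn_z"),
    occ = occ, b = b,
    elem = cif_na(pick("atom_site.type_symbol")),
    stringsAsFactors = FALSE)
}

empty_atoms <- function() {
  data.frame(record = character(0), chain = character(0), resno = integer(0),
             icode = character(0), resname = character(0), atom = character(0),
             altloc = character(0), x = numeric(0), y = numeric(0),
             z = numeric(0), occ = numeric(0), b = numeric(0),
             elem = character(0), stringsAsFactors = FALSE)
}

# keep the highest-occupancy altloc copy of each atom; ties -> first in file
resolve_altloc <- function(atoms) {
  key <- paste(atoms$record, atoms$chain, atoms$resno, atoms$icode, atoms$atom,
               sep = "|")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occ, seq_len(nrow(atoms)))
  atoms <- atoms[ord, ]
  key <- key[ord]
  atoms <- atoms[!duplicated(key), ]
  atoms[order(as.integer(rownames(atoms))), ]
}

#' Write a structure as PDB text
#'
#' @param s A `casp_structure`.
#' @param file Optional path; if `NULL` the text is returned invisibly.
#' @return Character vector of PDB lines (invisibly when written to file).
#' @export
write_pdb <- function(s, file = NULL) {
  a <- s$atoms
  name4 <- ifelse(nchar(a$atom) >= 4, substr(a$atom, 1, 4),
                  sprintf(" %-3s", a$atom))
  lines <- sprintf("%-6s%5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   a$record, seq_len(nrow(a)) %% 100000, name4, a$resname,
                   a$chain, a$resno, ifelse(nzchar(a$icode), a$icode, " "),
                   a$x, a$y, a$z, a$occ, a$b, a$elem)
  lines <- c(lines, "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

# ordered polymer residue keys (file order)
polymer_keys <- function(s) unique(s$atoms$res_key[s$atoms$record == "ATOM"])

#' Number of polymer residues in a structure
#' @param s A `casp_structure`.
#' @export
n_residues <- function(s) length(polymer_keys(s))

# per-residue first-seen table for the polymer part
residue_table <- function(s) {
  a <- s$atoms[s$atoms$record == "ATOM", ]
  first <- !duplicated(a$res_key)
  data.frame(res_key = a$res_key[first], chain = a$chain[first],
             resno = a$resno[first], icode = a$icode[first],
             resname = a$resname[first], stringsAsFactors = FALSE)
}

# resname normalized for metric purposes (MSE -> MET etc.)
canonical_resname <- function(resname) {
  mapped <- NONSTANDARD_MAP[resname]
  ifelse(!is.na(mapped), mapped, resname)
}

#' Extract an evaluation unit (EU) from a structure
#'
#' Keeps exactly the polymer residues whose author numbering falls inside
#' the EU ranges (inclusive on both ends), preserving file order. Hetero
#' groups are retained only if any of their atoms lies within 5 Angstrom
#' of a kept polymer residue.
#'
#' @param s A `casp_structure`.
#' @param eu An EU definition as returned by [eu_definition()].
#' @return A `casp_structure` restricted to the EU.
#' @export
extract_eu <- function(s, eu) {
  a <- s$atoms
  pol <- a$record == "ATOM"
  present_chains <- unique(a$chain[pol])
  missing <- setdiff(vapply(eu$ranges, `[[`, "", "chain"), present_chains)
  if (length(missing))
    stop("EU range addresses chain(s) absent from structure: ",
         paste(missing, collapse = ", "))
  keep <- rep(FALSE, nrow(a))
  for (rg in eu$ranges) {
    keep <- keep | (pol & a$chain == rg$chain &
                    a$resno >= rg$start & a$resno <= rg$end)
  }
  if (!any(keep)) stop("EU ranges select zero residues in structure ", s$id)
  het <- which(a$record == "HETATM")
  if (length(het)) {
    kp <- which(keep)
    kept_xyz <- as.matrix(a[kp, c("x", "y", "z")])
    het_keep_key <- character(0)
    for (hk in unique(a$res_key[het])) {
      hx <- as.matrix(a[het, ][a$res_key[het] == hk, c("x", "y", "z"), drop = FALSE])
      d2 <- min(outer(rowSums(hx^2), rowSums(kept_xyz^2), "+") -
                  2 * hx %*% t(kept_xyz))
      if (d2 <= 25) het_keep_key <- c(het_keep_key, hk)
    }
    keep[het] <- a$res_key[het] %in% het_keep_key
  }
  out <- a[keep, ]
  rownames(out) <- NULL
  new_structure(paste0(s$id, ":", eu$eu_id), out)
}

#' Construct an EU definition
#'
#' @param target_id,eu_id Identifiers.
#' @param ranges List of `list(chain, start, end)` inclusive author-numbered
#'   intervals, or a data frame with those columns.
#' @param weight EU weight; the convention is `1 / n_EUs` of the target so
#'   every target carries equal total weight.
#' @param versions Character vector of alternative-conformation structure
#'   ids (metrics take the maximum over versions).
#' @return A list of class `eu_definition`.
#' @export
eu_definition <- function(target_id, eu_id, ranges, weight = 1,
                          versions = character(0)) {
  if (is.data.frame(ranges))
    ranges <- lapply(seq_len(nrow(ranges)), function(i)
      list(chain = ranges$chain[i], start = ranges$start[i], end = ranges$end[i]))
  if (!length(ranges)) stop("EU must have at least one residue range")
  for (rg in ranges)
    if (rg$end < rg$start) stop("EU range with end < start")
  structure(list(target_id = target_id, eu_id = eu_id, ranges = ranges,
                 weight = weight, versions = versions),
            class = "eu_definition")
}

#' Read EU definitions from a JSON file
#'
#' Expected layout: a JSON array of objects with fields `target_id`,
#' `eu_id`, `ranges` (array of `{chain, start, end}`), optional `weight`
#' and `versions`. If `weight` is missing it is filled as 1/n over the
#' EUs of each target.
#'
#' @param path JSON file path.
#' @return List of `eu_definition` objects.
#' @export
read_eu_definitions <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  eus <- lapply(raw, function(e) {
    eu_definition(e$target_id, e$eu_id,
                  lapply(e$ranges, function(r)
                    list(chain = r$chain, start = r$start, end = r$end)),
                  weight = if (!is.null(e$weight)) e$weight else NA_real_,
                  versions = as.character(unlist(e$versions)))
  })
  tids <- vapply(eus, `[[`, "", "target_id")
  for (t in unique(tids)) {
    idx <- which(tids == t)
    for (i in idx)
      if (is.na(eus[[i]]$weight)) eus[[i]]$weight <- 1 / length(idx)
  }
  eus
}

#' Residue correspondence between a target and a model
#'
#' Residues are paired by identical author numbering (chain, residue
#' number, insertion code), the CASP submission convention. Residue-name
#' mismatches at paired positions are reported in `mismatches`.
#'
#' @param target,model `casp_structure` objects.
#' @return List with `pairs` (data frame: `target_key`, `model_key`,
#'   indices into each structure's residue order), `coverage` (matched
#'   fraction of target residues) and `mismatches`.
#' @export
map_residues <- function(target, model) {
  tt <- residue_table(target)
  mt <- residue_table(model)
  if (!nrow(tt) || !nrow(mt)) stop("empty structure in residue mapping")
  idx <- match(tt$res_key, mt$res_key)
  hit <- which(!is.na(idx))
  if (!length(hit))
    stop("no residues share author numbering between target and model")
  pairs <- data.frame(target_idx = hit, model_idx = idx[hit],
                      target_key = tt$res_key[hit],
                      model_key = mt$res_key[idx[hit]],
                      stringsAsFactors = FALSE)
  mism <- pairs$target_key[canonical_resname(tt$resname[hit]) !=
                             canonical_resname(mt$resname[idx[hit]])]
  list(pairs = pairs, coverage = nrow(pairs) / nrow(tt), mismatches = mism)
}

# coordinates of one named atom per residue key; NA rows where absent
atom_coords <- function(s, keys, atom_name = "CA") {
  a <- s$atoms[s$atoms$record == "ATOM" & s$atoms$atom == atom_name, ]
  i <- match(keys, a$res_key)
  cbind(x = a$x[i], y = a$y[i], z = a$z[i])
}
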