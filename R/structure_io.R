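#' @useDynLib protsemble, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils head read.table write.table
NULL

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL")

# backbone first, side chain alphabetical, OXT last: canonical within-residue
# atom order shared by every structure in a run
.atom_name_rank <- function(name) {
  fixed <- c(N = 1L, CA = 2L, C = 3L, O = 4L)
  r <- unname(fixed[name])
  r[is.na(r)] <- 5L
  r[name == "OXT"] <- 6L
  r
}

#' Protein structure container
#'
#' An ordered list of heavy atoms for one conformation, the universal
#' currency of the pipeline. Atoms are held in a data frame with PDB-style
#' identity columns plus coordinates in Angstroms.
#'
#' @param atoms data frame with columns `record`, `serial`, `name`,
#'   `altloc`, `resname`, `chain`, `resseq`, `icode`, `x`, `y`, `z`,
#'   `occ`, `element`.
#' @param title character title.
#' @param sec_struct optional per-residue secondary structure in
#'   `{"H","E","C"}`; length must equal the residue count.
#' @return object of class `pse_structure`.
#' @export
pse_structure <- function(atoms, title = "", sec_struct = NULL) {
  stopifnot(is.data.frame(atoms))
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) ||
      !all(is.finite(atoms$z))) {
    stop("non-finite coordinates in structure")
  }
  key <- atom_keys(atoms)
  if (anyDuplicated(key)) {
    stop("duplicate atom identities: ", paste(key[duplicated(key)][1], collapse = ", "))
  }
  s <- structure(list(atoms = atoms, title = title, sec_struct = sec_struct),
                 class = "pse_structure")
  if (!is.null(sec_struct) && length(sec_struct) != n_residues(s)) {
    stop("sec_struct length must equal residue count")
  }
  s
}

#' @export
print.pse_structure <- function(x, ...) {
  cat(sprintf("<pse_structure> %s: %d atoms, %d residues%s\n",
              if (nzchar(x$title)) x$title else "(untitled)",
              n_atoms(x), n_residues(x),
              if (is.null(x$sec_struct)) "" else ", sec_struct assigned"))
  invisible(x)
}

atom_keys <- function(atoms) {
  paste(atoms$chain, atoms$resseq, atoms$icode, atoms$resname, atoms$name,
        sep = "|")
}

#' Number of atoms in a structure
#' @param s a `pse_structure`
#' @return integer
#' @export
n_atoms <- function(s) nrow(s$atoms)

residue_ids <- function(s) {
  unique(paste(s$atoms$chain, s$atoms$resseq, s$atoms$icode, sep = "|"))
}

#' Number of residues in a structure
#' @param s a `pse_structure`
#' @return integer
#' @export
n_residues <- function(s) length(residue_ids(s))

#' Residue index (sequential, 1-based) of every atom
#' @param s a `pse_structure`
#' @return integer vector, length `n_atoms(s)`
#' @export
residue_index <- function(s) {
  rid <- paste(s$atoms$chain, s$atoms$resseq, s$atoms$icode, sep = "|")
  match(rid, unique(rid))
}

#' Coordinate matrix of a structure
#' @param s a `pse_structure`
#' @return numeric matrix, n_atoms x 3, Angstroms
#' @export
coords <- function(s) {
  cbind(x = s$atoms$x, y = s$atoms$y, z = s$atoms$z)
}

#' Replace the coordinates of a structure
#' @param s a `pse_structure`
#' @param xyz n_atoms x 3 matrix
#' @return modified structure
#' @export
set_coords <- function(s, xyz) {
  stopifnot(nrow(xyz) == n_atoms(s), ncol(xyz) == 3)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

#' Indices of C-alpha atoms
#' @param s a `pse_structure`
#' @return integer vector
#' @export
ca_indices <- function(s) which(s$atoms$name == "CA")

canonical_order <- function(atoms) {
  order(atoms$chain, atoms$resseq, atoms$icode, .atom_name_rank(atoms$name),
        atoms$name)
}

#' Read one model from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records. Alternate locations are
#' resolved to the highest-occupancy conformer (ties: first encountered).
#' Coordinates are in Angstroms.
#'
#' @param path PDB file path.
#' @param model 1-based model number for multi-model files (default 1;
#'   files without MODEL records hold a single model).
#' @return a [pse_structure]
#' @export
read_structure <- function(path, model = 1L) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(startsWith(rec, "MODEL"))
  if (length(model_starts) == 0) {
    block <- lines
  } else {
    if (model > length(model_starts)) {
      stop("model ", model, " requested but file has ",
           length(model_starts), " models")
    }
    from <- model_starts[model]
    ends <- which(startsWith(rec, "ENDMDL"))
    to <- min(ends[ends > from], length(lines))
    block <- lines[from:to]
  }
  isatom <- startsWith(block, "ATOM  ") | startsWith(block, "HETATM")
  block <- block[isatom]
  if (length(block) == 0) stop("no ATOM/HETATM records in ", path)
  num <- function(a, b) suppressWarnings(as.numeric(trimws(substr(block, a, b))))
  atoms <- data.frame(
    record  = trimws(substr(block, 1, 6)),
    serial  = as.integer(num(7, 11)),
    name    = trimws(substr(block, 13, 16)),
    altloc  = substr(block, 17, 17),
    resname = trimws(substr(block, 18, 20)),
    chain   = substr(block, 22, 22),
    resseq  = as.integer(num(23, 26)),
    icode   = substr(block, 27, 27),
    x = num(31, 38), y = num(39, 46), z = num(47, 54),
    occ = num(55, 60),
    element = trimws(substr(block, 77, 78)),
    stringsAsFactors = FALSE
  )
  atoms$occ[is.na(atoms$occ)] <- 1
  noel <- !nzchar(atoms$element)
  atoms$element[noel] <- guess_element(atoms$name[noel])
  atoms <- resolve_altlocs(atoms)
  atoms <- atoms[canonical_order(atoms), , drop = FALSE]
  rownames(atoms) <- NULL
  pse_structure(atoms, title = basename(path))
}

guess_element <- function(name) {
  # strip digits, first alphabetic run; two-letter elements in proteins are
  # rare (SE of MSE handled; metals arrive as HETATM and are stripped anyway)
  el <- sub("^[0-9]*", "", name)
  el <- substr(el, 1, 1)
  el[grepl("^SE", name)] <- "SE"
  el
}

resolve_altlocs <- function(atoms) {
  blank <- atoms$altloc %in% c(" ", "")
  if (all(blank)) return(atoms)
  key <- atom_keys(atoms)
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[!blank])) {
    idx <- which(key == k)
    if (length(idx) > 1) {
      best <- idx[which.max(atoms$occ[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  atoms <- atoms[keep, , drop = FALSE]
  atoms$altloc <- " "
  atoms
}

#' Remove non-protein atoms
#'
#' Drops HETATM-derived atoms, waters, non-standard residues and all
#' hydrogens/deuteriums, leaving the heavy atoms of the twenty standard
#' amino acids. Idempotent.
#'
#' @param s a `pse_structure`
#' @return cleaned `pse_structure`
#' @export
strip_non_protein <- function(s) {
  a <- s$atoms
  keep <- a$record == "ATOM" &
    a$resname %in% AMINO3 &
    !(a$element %in% c("H", "D"))
  a <- a[keep, , drop = FALSE]
  rownames(a) <- NULL
  pse_structure(a, title = s$title)
}

#' Intersect the atom rosters of two structures
#'
#' Retains exactly the atoms whose identity key (chain, residue
#' number + insertion code, residue name, atom name) occurs in both
#' structures, in identical canonical order, so the pair can feed the
#' constraint engine. Only atoms common to both conformations carry
#' usable distance information.
#'
#' @param a,b `pse_structure` objects with the same chain naming.
#' @return list with elements `a` and `b`, same roster and order.
#' @export
intersect_atoms <- function(a, b) {
  ka <- atom_keys(a$atoms); kb <- atom_keys(b$atoms)
  common <- intersect(ka, kb)
  if (length(common) == 0) stop("no atoms in common between structures")
  aa <- a$atoms[ka %in% common, , drop = FALSE]
  bb <- b$atoms[kb %in% common, , drop = FALSE]
  aa <- aa[canonical_order(aa), , drop = FALSE]
  bb <- bb[canonical_order(bb), , drop = FALSE]
  rownames(aa) <- rownames(bb) <- NULL
  stopifnot(identical(atom_keys(aa), atom_keys(bb)))
  list(a = pse_structure(aa, title = a$title),
       b = pse_structure(bb, title = b$title))
}

#' Assign per-residue secondary structure
#'
#' With a DSSP output file, DSSP codes are collapsed to three states
#' (H/G/I to H, E/B to E, everything else C). Without one, a
#' deterministic phi/psi-window fallback is used: runs of at least four
#' consecutive residues with phi in \[-100, -30\] and psi in \[-80, -5\]
#' degrees are helix; runs of at least three with phi in \[-180, -90\]
#' and psi in \[90, 180\] or \[-180, -170\] are strand; the rest is coil.
#'
#' @param s a `pse_structure`
#' @param dssp_path optional DSSP-format file for the same protein.
#' @return the structure with `sec_struct` filled.
#' @export
assign_secondary_structure <- function(s, dssp_path = NULL) {
  if (is.null(dssp_path)) {
    ss <- ss_fallback(s)
  } else {
    ss <- ss_from_dssp(s, dssp_path)
  }
  s$sec_struct <- ss
  s
}

ss_from_dssp <- function(s, dssp_path) {
  lines <- readLines(dssp_path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0) stop("not a DSSP file: ", dssp_path)
  tab <- lines[(hdr[1] + 1):length(lines)]
  tab <- tab[nchar(tab) >= 17]
  resseq <- suppressWarnings(as.integer(trimws(substr(tab, 6, 10))))
  icode <- substr(tab, 11, 11)
  chain <- substr(tab, 12, 12)
  code <- substr(tab, 17, 17)
  ok <- !is.na(resseq)  # chain-break rows have '!' and no number
  dk <- paste(chain[ok], resseq[ok], icode[ok], sep = "|")
  dss <- ifelse(code[ok] %in% c("H", "G", "I"), "H",
                ifelse(code[ok] %in% c("E", "B"), "E", "C"))
  rid <- residue_ids(s)
  hit <- match(rid, dk)
  if (anyNA(hit)) {
    stop("DSSP file does not cover residues: ",
         paste(head(rid[is.na(hit)], 5), collapse = ", "))
  }
  dss[hit]
}

ss_fallback <- function(s) {
  tor <- backbone_torsions(s)
  nres <- nrow(tor)
  helix_ok <- !is.na(tor$phi) & !is.na(tor$psi) &
    tor$phi >= -100 & tor$phi <= -30 & tor$psi >= -80 & tor$psi <= -5
  strand_ok <- !is.na(tor$phi) & !is.na(tor$psi) &
    tor$phi >= -180 & tor$phi <= -90 &
    ((tor$psi >= 90 & tor$psi <= 180) | (tor$psi >= -180 & tor$psi <= -170))
  ss <- rep("C", nres)
  ss[run_mask(helix_ok, 4)] <- "H"
  ss[run_mask(strand_ok, 3) & ss == "C"] <- "E"
  ss
}

run_mask <- function(ok, minlen) {
  r <- rle(ok)
  r$values <- r$values & r$lengths >= minlen
  inverse.rle(r)
}

#' Backbone phi/psi torsions
#'
#' @param s a `pse_structure` with backbone N, CA, C atoms.
#' @return data frame with columns `phi`, `psi` in degrees (NA at chain
#'   termini or where backbone atoms are missing).
#' @export
backbone_torsions <- function(s) {
  a <- s$atoms
  rid <- paste(a$chain, a$resseq, a$icode, sep = "|")
  urid <- unique(rid)
  nres <- length(urid)
  get1 <- function(r, nm) {
    i <- which(rid == urid[r] & a$name == nm)
    if (length(i) == 1) c(a$x[i], a$y[i], a$z[i]) else NULL
  }
  chain_of <- a$chain[match(urid, rid)]
  phi <- psi <- rep(NA_real_, nres)
  for (r in seq_len(nres)) {
    N <- get1(r, "N"); CA <- get1(r, "CA"); C <- get1(r, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (r > 1 && chain_of[r - 1] == chain_of[r]) {
      Cp <- get1(r - 1, "C")
      if (!is.null(Cp) && sqrt(sum((Cp - N)^2)) < 2.0) {
        phi[r] <- dihedral_angle(Cp, N, CA, C)
      }
    }
    if (r < nres && chain_of[r + 1] == chain_of[r]) {
      Nn <- get1(r + 1, "N")
      if (!is.null(Nn) && sqrt(sum((C - Nn)^2)) < 2.0) {
        psi[r] <- dihedral_angle(N, CA, C, Nn)
      }
    }
  }
  data.frame(phi = phi, psi = psi)
}

#' Dihedral angle of four points
#' @param p1,p2,p3,p4 3-vectors
#' @return angle in degrees in (-180, 180]
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Ensemble of conformations on a shared atom roster
#'
#' @param roster atoms data frame giving atom identities (as in
#'   [pse_structure]); coordinates in the roster are ignored.
#' @param models list of n_atoms x 3 coordinate matrices.
#' @param error_scores per-model non-negative embedding error scores.
#' @param aligned logical; TRUE after [iterative_align].
#' @return object of class `pse_ensemble`
#' @export
pse_ensemble <- function(roster, models, error_scores = NULL,
                         aligned = FALSE) {
  stopifnot(is.list(models), length(models) >= 1)
  na <- nrow(roster)
  for (m in models) stopifnot(is.matrix(m), nrow(m) == na, ncol(m) == 3)
  if (is.null(error_scores)) error_scores <- rep(NA_real_, length(models))
  stopifnot(length(error_scores) == length(models))
  structure(list(roster = roster, models = models,
                 error_scores = error_scores, aligned = aligned),
            class = "pse_ensemble")
}

#' @export
print.pse_ensemble <- function(x, ...) {
  cat(sprintf("<pse_ensemble> %d models x %d atoms (%saligned)\n",
              length(x$models), nrow(x$roster),
              if (x$aligned) "" else "not "))
  invisible(x)
}

#' Number of models in an ensemble
#' @param e a `pse_ensemble`
#' @return integer
#' @export
n_models <- function(e) length(e$models)

pdb_atom_line <- function(a, xyz, serial) {
  name <- a$name
  # PDB column 13 is blank for <4-char names unless the element is 2 letters
  nm <- if (nchar(name) >= 4 || nchar(a$element) == 2) {
    sprintf("%-4s", name)
  } else {
    sprintf(" %-3s", name)
  }
  sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$record, serial %% 100000L, nm, " ", a$resname, a$chain,
          a$resseq %% 10000L, a$icode, xyz[1], xyz[2], xyz[3], 1, 0,
          a$element)
}

#' Write a structure as a PDB file
#' @param s a `pse_structure`
#' @param path output path
#' @return path, invisibly
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  xyz <- coords(s)
  lines <- vapply(seq_len(nrow(a)),
                  function(i) pdb_atom_line(a[i, ], xyz[i, ], i),
                  character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Models are wrapped in MODEL/ENDMDL records; coordinates round-trip
#' through [read_structure] to 1e-3 Angstrom (PDB fixed-column precision).
#'
#' @param e a `pse_ensemble` (nonempty)
#' @param path output path
#' @return path, invisibly
#' @export
write_ensemble <- function(e, path) {
  if (!inherits(e, "pse_ensemble") || n_models(e) == 0) {
    stop("cannot write an empty ensemble")
  }
  a <- e$roster
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(e$models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- e$models[[m]]
    lines <- vapply(seq_len(nrow(a)),
                    function(i) pdb_atom_line(a[i, ], xyz[i, ], i),
                    character(1))
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
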