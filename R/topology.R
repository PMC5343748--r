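# Residue-template connectivity for the 20 standard amino acids.
# Covalent topology is template-derived, as distance-constraint programs
# usually do it, because PDB CONECT records are unreliable; inter-residue
# peptide bonds and disulfides are detected geometrically.

.side_bonds <- list(
  ALA = list(c("CA", "CB")),
  ARG = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "NE"),
             c("NE", "CZ"), c("CZ", "NH1"), c("CZ", "NH2")),
  ASN = list(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"), c("CG", "ND2")),
  ASP = list(c("CA", "CB"), c("CB", "CG"), c("CG", "OD1"), c("CG", "OD2")),
  CYS = list(c("CA", "CB"), c("CB", "SG")),
  GLN = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"),
             c("CD", "NE2")),
  GLU = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "OE1"),
             c("CD", "OE2")),
  GLY = list(),
  HIS = list(c("CA", "CB"), c("CB", "CG"), c("CG", "ND1"), c("CG", "CD2"),
             c("ND1", "CE1"), c("CD2", "NE2"), c("CE1", "NE2")),
  ILE = list(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2"), c("CG1", "CD1")),
  LEU = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2")),
  LYS = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "CE"),
             c("CE", "NZ")),
  MET = list(c("CA", "CB"), c("CB", "CG"), c("CG", "SD"), c("SD", "CE")),
  PHE = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
             c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ")),
  PRO = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD"), c("CD", "N")),
  SER = list(c("CA", "CB"), c("CB", "OG")),
  THR = list(c("CA", "CB"), c("CB", "OG1"), c("CB", "CG2")),
  TRP = list(c("CA", "CB"), c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2"),
             c("CD1", "NE1"), c("NE1", "CE2"), c("CD2", "CE2"),
             c("CD2", "CE3"), c("CE2", "CZ2"), c("CE3", "CZ3"),
             c("CZ2", "CH2"), c("CZ3", "CH2")),
  TYR = list(c("CA", "CB"), c("CG", "CD1"), c("CB", "CG"), c("CG", "CD2"),
             c("CD1", "CE1"), c("CD2", "CE2"), c("CE1", "CZ"), c("CE2", "CZ"),
             c("CZ", "OH")),
  VAL = list(c("CA", "CB"), c("CB", "CG1"), c("CB", "CG2"))
)

.ring_atoms <- list(
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  PRO = c("N", "CA", "CB", "CG", "CD")
)

# central bonds whose 1-4 dihedrals are locked by side-chain partial double
# bonds (planar amide / guanidinium groups)
.double_bond_central <- list(
  ASN = list(c("CG", "ND2")),
  GLN = list(c("CD", "NE2")),
  ARG = list(c("NE", "CZ"), c("CZ", "NH1"), c("CZ", "NH2"))
)

# heavy-atom hydrogen-bond donors mapped to their antecedent atom (used for
# the antecedent-donor-acceptor angle test); backbone N handled separately
.side_donors <- list(
  ARG = list(c("NE", "CD"), c("NH1", "CZ"), c("NH2", "CZ")),
  ASN = list(c("ND2", "CG")),
  GLN = list(c("NE2", "CD")),
  HIS = list(c("ND1", "CG"), c("NE2", "CE1")),
  LYS = list(c("NZ", "CE")),
  SER = list(c("OG", "CB")),
  THR = list(c("OG1", "CB")),
  TRP = list(c("NE1", "CD1")),
  TYR = list(c("OH", "CZ"))
)

.side_acceptors <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = c("OD1"), GLN = c("OE1"),
  SER = c("OG"), THR = c("OG1"), TYR = c("OH"),
  HIS = c("ND1", "NE2")
)

.salt_positive <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                       HIS = c("ND1", "NE2"))
.salt_negative <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

.vdw_radii <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)

#' Covalent bond list of a structure
#'
#' Bonds come from residue templates, peptide C-N links detected below
#' 1.8 Angstrom between consecutive residues of one chain, and disulfide
#' SG-SG pairs below 2.5 Angstrom.
#'
#' @param s a `pse_structure`
#' @return two-column integer matrix of atom indices (i < j)
#' @export
covalent_bonds <- function(s) {
  a <- s$atoms
  ridx <- residue_index(s)
  bonds <- list()
  find_atom <- function(r, nm) which(ridx == r & a$name == nm)
  for (r in unique(ridx)) {
    rn <- a$resname[match(r, ridx)]
    tmpl <- c(list(c("N", "CA"), c("CA", "C"), c("C", "O"), c("C", "OXT")),
              .side_bonds[[rn]])
    for (bd in tmpl) {
      i <- find_atom(r, bd[1]); j <- find_atom(r, bd[2])
      if (length(i) == 1 && length(j) == 1) bonds[[length(bonds) + 1]] <- c(i, j)
    }
  }
  # peptide bonds
  xyz <- coords(s)
  nres <- max(ridx)
  for (r in seq_len(nres - 1)) {
    i <- find_atom(r, "C"); j <- find_atom(r + 1, "N")
    if (length(i) == 1 && length(j) == 1 &&
        a$chain[i] == a$chain[j] &&
        sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < 1.8) {
      bonds[[length(bonds) + 1]] <- c(i, j)
    }
  }
  # disulfides
  sg <- which(a$name == "SG" & a$resname == "CYS")
  if (length(sg) > 1) {
    for (u in seq_along(sg)) for (v in seq_len(u - 1)) {
      if (sqrt(sum((xyz[sg[u], ] - xyz[sg[v], ])^2)) < 2.5) {
        bonds[[length(bonds) + 1]] <- c(sg[v], sg[u])
      }
    }
  }
  m <- do.call(rbind, bonds)
  m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  m[!duplicated(m), , drop = FALSE]
}
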