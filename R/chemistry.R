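# Residue chemistry used by the threading engine: heavy-atom side-chain
# topologies as internal coordinates, per-atom scoring parameters, and the
# coarse chi-grid rotamer library.  Hydrogens are not modeled; hydrogen bonds
# are detected from heavy-atom donor/acceptor geometry.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

AA3_TO_1 <- stats::setNames(names(AA3), unname(AA3))

# Modified residues mapped to their parent standard residue on PDB input.
MODIFIED_PARENT <- c(MSE = "MET", SEC = "CYS", PYL = "LYS", HYP = "PRO",
                     SEP = "SER", TPO = "THR", PTR = "TYR", CSO = "CYS",
                     MLY = "LYS", M3L = "LYS")

# One side-chain atom: placed by natural-extension from three reference atoms
# of the same residue.  torsion = chi[chi_idx] + offset; chi_idx 0 => fixed.
sc_atom <- function(name, a, b, c, bond, angle, chi_idx, offset = 0) {
  list(name = name, a = a, b = b, c = c, bond = bond, angle = angle,
       chi = chi_idx, offset = offset)
}

# Side-chain topology beyond CB.  CB itself is placed uniformly for all
# non-glycine residues (improper N-C-CA-CB = +122.6 deg, L-configuration).
SIDECHAIN_TOPOLOGY <- list(
  ALA = list(),
  SER = list(sc_atom("OG",  "N", "CA", "CB", 1.42, 110.5, 1)),
  CYS = list(sc_atom("SG",  "N", "CA", "CB", 1.81, 114.0, 1)),
  VAL = list(sc_atom("CG1", "N", "CA", "CB", 1.52, 110.5, 1),
             sc_atom("CG2", "N", "CA", "CB", 1.52, 110.5, 1, 122)),
  THR = list(sc_atom("OG1", "N", "CA", "CB", 1.43, 109.5, 1),
             sc_atom("CG2", "N", "CA", "CB", 1.52, 111.0, 1, -120)),
  ILE = list(sc_atom("CG1", "N", "CA", "CB", 1.53, 110.4, 1),
             sc_atom("CG2", "N", "CA", "CB", 1.52, 110.5, 1, -122),
             sc_atom("CD1", "CA", "CB", "CG1", 1.52, 114.0, 2)),
  LEU = list(sc_atom("CG",  "N", "CA", "CB", 1.53, 116.3, 1),
             sc_atom("CD1", "CA", "CB", "CG", 1.52, 110.5, 2),
             sc_atom("CD2", "CA", "CB", "CG", 1.52, 110.5, 2, 122)),
  MET = list(sc_atom("CG",  "N", "CA", "CB", 1.52, 114.1, 1),
             sc_atom("SD",  "CA", "CB", "CG", 1.80, 112.7, 2),
             sc_atom("CE",  "CB", "CG", "SD", 1.79, 100.9, 3)),
  ASN = list(sc_atom("CG",  "N", "CA", "CB", 1.52, 112.6, 1),
             sc_atom("OD1", "CA", "CB", "CG", 1.23, 120.8, 2),
             sc_atom("ND2", "CA", "CB", "CG", 1.33, 116.4, 2, 180)),
  ASP = list(sc_atom("CG",  "N", "CA", "CB", 1.52, 112.6, 1),
             sc_atom("OD1", "CA", "CB", "CG", 1.25, 118.5, 2),
             sc_atom("OD2", "CA", "CB", "CG", 1.25, 118.5, 2, 180)),
  GLN = list(sc_atom("CG",  "N", "CA", "CB", 1.52, 114.1, 1),
             sc_atom("CD",  "CA", "CB", "CG", 1.52, 112.6, 2),
             sc_atom("OE1", "CB", "CG", "CD", 1.23, 120.8, 3),
             sc_atom("NE2", "CB", "CG", "CD", 1.33, 116.4, 3, 180)),
  GLU = list(sc_atom("CG",  "N", "CA", "CB", 1.52, 114.1, 1),
             sc_atom("CD",  "CA", "CB", "CG", 1.52, 112.6, 2),
             sc_atom("OE1", "CB", "CG", "CD", 1.25, 118.5, 3),
             sc_atom("OE2", "CB", "CG", "CD", 1.25, 118.5, 3, 180)),
  LYS = list(sc_atom("CG",  "N", "CA", "CB", 1.52, 114.1, 1),
             sc_atom("CD",  "CA", "CB", "CG", 1.52, 111.3, 2),
             sc_atom("CE",  "CB", "CG", "CD", 1.52, 111.3, 3),
             sc_atom("NZ",  "CG", "CD", "CE", 1.49, 111.0, 4)),
  ARG = list(sc_atom("CG",  "N", "CA", "CB", 1.52, 114.1, 1),
             sc_atom("CD",  "CA", "CB", "CG", 1.52, 111.3, 2),
             sc_atom("NE",  "CB", "CG", "CD", 1.46, 112.0, 3),
             sc_atom("CZ",  "CG", "CD", "NE", 1.33, 124.2, 4),
             sc_atom("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0, 0),
             sc_atom("NH2", "CD", "NE", "CZ", 1.33, 120.0, 0, 180)),
  HIS = list(sc_atom("CG",  "N", "CA", "CB", 1.50, 113.8, 1),
             sc_atom("ND1", "CA", "CB", "CG", 1.38, 122.7, 2),
             sc_atom("CD2", "CA", "CB", "CG", 1.36, 129.7, 2, 180),
             sc_atom("CE1", "CB", "CG", "ND1", 1.32, 109.0, 0, 180),
             sc_atom("NE2", "CB", "CG", "CD2", 1.37, 107.0, 0, 180)),
  PHE = list(sc_atom("CG",  "N", "CA", "CB", 1.50, 113.8, 1),
             sc_atom("CD1", "CA", "CB", "CG", 1.39, 120.8, 2),
             sc_atom("CD2", "CA", "CB", "CG", 1.39, 120.8, 2, 180),
             sc_atom("CE1", "CB", "CG", "CD1", 1.39, 120.8, 0, 180),
             sc_atom("CE2", "CB", "CG", "CD2", 1.39, 120.8, 0, 180),
             sc_atom("CZ",  "CG", "CD1", "CE1", 1.39, 120.0, 0, 0)),
  TYR = list(sc_atom("CG",  "N", "CA", "CB", 1.51, 113.8, 1),
             sc_atom("CD1", "CA", "CB", "CG", 1.39, 120.8, 2),
             sc_atom("CD2", "CA", "CB", "CG", 1.39, 120.8, 2, 180),
             sc_atom("CE1", "CB", "CG", "CD1", 1.39, 120.8, 0, 180),
             sc_atom("CE2", "CB", "CG", "CD2", 1.39, 120.8, 0, 180),
             sc_atom("CZ",  "CG", "CD1", "CE1", 1.39, 120.0, 0, 0),
             sc_atom("OH",  "CD1", "CE1", "CZ", 1.38, 119.9, 0, 180)),
  TRP = list(sc_atom("CG",  "N", "CA", "CB", 1.50, 113.6, 1),
             sc_atom("CD1", "CA", "CB", "CG", 1.37, 126.9, 2),
             sc_atom("CD2", "CA", "CB", "CG", 1.43, 126.7, 2, 180),
             sc_atom("NE1", "CB", "CG", "CD1", 1.38, 110.2, 0, 180),
             sc_atom("CE2", "CB", "CG", "CD2", 1.41, 107.2, 0, 180),
             sc_atom("CE3", "CB", "CG", "CD2", 1.40, 133.9, 0, 0),
             sc_atom("CZ2", "CG", "CD2", "CE2", 1.40, 122.4, 0, 180),
             sc_atom("CZ3", "CG", "CD2", "CE3", 1.39, 118.7, 0, 180),
             sc_atom("CH2", "CD2", "CE2", "CZ2", 1.37, 117.5, 0, 0)),
  # Proline ring is shipped with a fixed pucker; torsions below close the
  # ring (CD lands within 0.001 A of bonding distance to backbone N).
  PRO = list(sc_atom("CG",  "N", "CA", "CB", 1.50, 104.5, 0, -6),
             sc_atom("CD",  "CA", "CB", "CG", 1.51, 105.5, 0, 18))
)

#' Number of heavy atoms for a residue (backbone N, CA, C, O plus side chain)
#' @keywords internal
residue_atom_count <- function(aa1) {
  res3 <- AA3[[aa1]]
  n_sc <- length(SIDECHAIN_TOPOLOGY[[res3]]) + (if (aa1 == "G") 0L else 1L)
  4L + n_sc
}

#' Atom names of a residue in build order
#' @keywords internal
residue_atom_names <- function(aa1) {
  res3 <- AA3[[aa1]]
  bb <- c("N", "CA", "C", "O")
  if (aa1 == "G") return(bb)
  c(bb, "CB", vapply(SIDECHAIN_TOPOLOGY[[res3]], `[[`, "", "name"))
}

#' Element symbol from a PDB-style heavy-atom name
#' @keywords internal
element_of <- function(atom_name) {
  substr(gsub("^[0-9]+", "", atom_name), 1L, 1L)
}

# Per-element scoring parameters.
#   radius : effective van der Waals radius (angstrom), used by E_rep/E_att
#   eps    : attractive well depth weight (packing attraction)
#   solv   : desolvation parameter; positive = polar (penalized when buried),
#            negative = apolar (rewarded when buried)
ELEMENT_PARAMS <- data.frame(
  element = c("C", "N", "O", "S"),
  radius  = c(1.75, 1.55, 1.50, 1.80),
  eps     = c(0.20, 0.12, 0.12, 0.25),
  solv    = c(-0.15, 0.60, 0.60, -0.10),
  stringsAsFactors = FALSE
)

# Residue-specific desolvation overrides (keyed "aa1:atom").  Charged groups
# carry strong buried-charge penalties; amides and ring nitrogens moderate;
# hydroxyls mild (they hydrogen-bond when buried).
ATOM_SOLV_OVERRIDE <- c(
  "D:OD1" = 2.5, "D:OD2" = 2.5,
  "E:OE1" = 2.5, "E:OE2" = 2.5,
  "K:NZ"  = 2.5,
  "R:NE"  = 1.5, "R:NH1" = 1.5, "R:NH2" = 1.5,
  "H:ND1" = 0.9, "H:NE2" = 0.9,
  "N:OD1" = 0.8, "N:ND2" = 0.8,
  "Q:OE1" = 0.8, "Q:NE2" = 0.8,
  "S:OG"  = 0.4, "T:OG1" = 0.4, "Y:OH" = 0.4
)

#' @keywords internal
atom_solv <- function(aa1, name, element) {
  key <- paste0(aa1, ":", name)
  ov <- ATOM_SOLV_OVERRIDE[key]
  ifelse(is.na(ov),
         ELEMENT_PARAMS$solv[match(element, ELEMENT_PARAMS$element)],
         ov)
}

# Heavy-atom hydrogen-bond roles.  Donors carry at least one polar hydrogen;
# hydroxyls act as both donor and acceptor.  Backbone N donates, backbone O
# accepts; those are handled by name below as well.
HB_DONOR_NAMES <- c("N", "ND1", "ND2", "NE", "NE1", "NE2", "NH1", "NH2",
                    "NZ", "OG", "OG1", "OH")
HB_ACCEPTOR_NAMES <- c("O", "OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH",
                       "ND1", "NE2")

#' Coarse rotamer library
#'
#' Backbone-independent chi-grid rotamers: each rotatable chi takes values
#' from \{-60, 60, 180\} degrees, truncated so no residue exceeds 9 rotamers
#' (distal chis of long side chains are held at 180, terminal sp2 groups at
#' their symmetric positions).  Glycine, alanine and proline have exactly one
#' (trivial) rotamer.
#'
#' @return Named list: per one-letter residue code, a list of numeric chi
#'   vectors (possibly empty vectors for rotamer-free residues).
#' @examples
#' length(rotamerLibrary()$G[[1]])  # 0: glycine has no chi angles
#' length(rotamerLibrary()$L)      # 9 leucine rotamers
#' @export
rotamerLibrary <- function() {
  g3 <- c(-60, 60, 180)
  grid2 <- function(a, b) {
    out <- list()
    for (x in a) for (y in b) out[[length(out) + 1L]] <- c(x, y)
    out
  }
  pad <- function(rots, extra) lapply(rots, function(r) c(r, extra))
  lib <- list(
    G = list(numeric(0)),
    A = list(numeric(0)),
    P = list(numeric(0)),
    S = lapply(g3, function(x) x),
    C = lapply(g3, function(x) x),
    T = lapply(g3, function(x) x),
    V = lapply(g3, function(x) x),
    I = grid2(g3, g3),
    L = grid2(g3, g3),
    M = pad(grid2(g3, g3), 180),          # chi3 fixed anti
    N = grid2(g3, c(-90, 0, 90)),
    D = grid2(g3, c(-90, 0, 90)),
    Q = pad(grid2(g3, g3), 0),            # terminal amide plane fixed
    E = pad(grid2(g3, g3), 0),
    K = pad(grid2(g3, g3), c(180, 180)),  # chi3, chi4 anti
    R = pad(grid2(g3, g3), c(180, 180)),
    H = grid2(g3, c(-90, 90)),
    F = grid2(g3, c(-45, 45, 90)),
    Y = grid2(g3, c(-45, 45, 90)),
    W = grid2(g3, c(-90, 0, 90))
  )
  lib[AA1]
}

#' @keywords internal
n_chi <- function(aa1) {
  res3 <- AA3[[aa1]]
  top <- SIDECHAIN_TOPOLOGY[[res3]]
  if (length(top) == 0L) return(0L)
  max(vapply(top, `[[`, 0, "chi"))
}
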