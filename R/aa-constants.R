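# Amino-acid alphabets, three-letter mappings and canonical side-chain
# atom composition used for contact detection and pair fingerprints.

#' The 20 standard amino acids (one-letter, alphabetical)
#'
#' Alphabet used for all count matrices, background frequencies and
#' energy tables in the package.
#'
#' @format Character vector of length 20.
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# three-letter -> one-letter, including common modified residues that
# have an unambiguous parent amino acid (MSE = selenomethionine, etc.)
AA3TO1 <- c(
  ALA = "A", CYS = "C", ASP = "D", GLU = "E", PHE = "F",
  GLY = "G", HIS = "H", ILE = "I", LYS = "K", LEU = "L",
  MET = "M", ASN = "N", PRO = "P", GLN = "Q", ARG = "R",
  SER = "S", THR = "T", VAL = "V", TRP = "W", TYR = "Y",
  MSE = "M", SEC = "C", PYL = "K", HYP = "P", SEP = "S",
  TPO = "T", PTR = "Y"
)

AA1TO3 <- c(
  A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
  G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
  M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
  S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR"
)

# Canonical heavy side-chain atom names per residue type, in standard
# PDB order. This order fixes the atom correspondence used when two
# pair fingerprints are compared, so it must be deterministic.
SIDECHAIN_ATOMS <- list(
  A = c("CB"),
  C = c("CB", "SG"),
  D = c("CB", "CG", "OD1", "OD2"),
  E = c("CB", "CG", "CD", "OE1", "OE2"),
  F = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  G = character(0),
  H = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  I = c("CB", "CG1", "CG2", "CD1"),
  K = c("CB", "CG", "CD", "CE", "NZ"),
  L = c("CB", "CG", "CD1", "CD2"),
  M = c("CB", "CG", "SD", "CE"),
  N = c("CB", "CG", "OD1", "ND2"),
  P = c("CB", "CG", "CD"),
  Q = c("CB", "CG", "CD", "OE1", "NE2"),
  R = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  S = c("CB", "OG"),
  T = c("CB", "OG1", "CG2"),
  V = c("CB", "CG1", "CG2"),
  W = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  Y = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH")
)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
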