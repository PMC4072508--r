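# PDB parsing and template assembly.
#
# Parsing is delegated to bio3d; this layer resolves altlocs (highest
# occupancy, ties broken by file order), drops hydrogens and waters,
# maps modified residues with an unambiguous parent (MSE -> M, ...) and
# rejects everything else with a warning.

#' Read a structure from PDB-format text or file
#'
#' @param pdb Path to a PDB file, or a character string containing
#'   PDB-format text (detected by the presence of a newline or an
#'   `ATOM`/`HETATM` record).
#' @param id Identifier for the structure (defaults to the file base
#'   name or `"structure"`).
#' @return A [StructureModel-class].
#' @examples
#' txt <- paste(
#'   "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00",
#'   "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00",
#'   "ATOM      3  C   ALA A   1       2.000   1.300   0.000  1.00  0.00",
#'   sep = "\n")
#' readStructure(txt)
#' @export
readStructure <- function(pdb, id = NULL) {
  isText <- grepl("\n", pdb, fixed = TRUE) ||
    grepl("^(ATOM|HETATM)", pdb) || !file.exists(pdb)
  if (isText) {
    if (!grepl("^(ATOM|HETATM)", pdb) && !grepl("\n(ATOM|HETATM)", pdb) &&
        !file.exists(pdb)) {
      stop("no ATOM records found (and no such file): parse error")
    }
    path <- tempfile(fileext = ".pdb")
    writeLines(pdb, path)
    on.exit(unlink(path))
    if (is.null(id)) id <- "structure"
  } else {
    path <- pdb
    if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  }
  p <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE,
                                        verbose = FALSE))
  a <- p$atom
  a <- a[a$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (!nrow(a)) stop("no ATOM records found: parse error")
  a <- a[a$resid != "HOH", , drop = FALSE]
  # drop hydrogens/deuteriums by element symbol (fall back to atom name)
  ele <- ifelse(is.na(a$elesy) | !nzchar(a$elesy),
                substr(gsub("^[0-9]", "", a$elety), 1, 1), a$elesy)
  a <- a[!(ele %in% c("H", "D")), , drop = FALSE]
  # map residue names; skip unmappable residues with a warning
  aa1 <- AA3TO1[a$resid]
  if (anyNA(aa1)) {
    bad <- unique(a$resid[is.na(aa1)])
    warning("skipping non-standard residue(s): ", paste(bad, collapse = ", "))
    a <- a[!is.na(aa1), , drop = FALSE]
    aa1 <- AA3TO1[a$resid]
  }
  if (!nrow(a)) stop("no standard residues found: parse error")
  a$aa <- unname(aa1)
  a$chain[is.na(a$chain)] <- " "
  # altloc resolution: per (chain, resno, atom name) keep highest
  # occupancy, ties -> first encountered
  occ <- ifelse(is.na(a$o), 1, a$o)
  ord <- order(-occ, seq_len(nrow(a)))
  a <- a[ord, , drop = FALSE]
  key <- paste(a$chain, a$resno, a$elety)
  a <- a[!duplicated(key), , drop = FALSE]
  a <- a[order(match(paste(a$chain, a$resno, a$elety),
                     paste(p$atom$chain, p$atom$resno, p$atom$elety))), ,
         drop = FALSE]
  atoms <- data.frame(chain = a$chain, resno = a$resno, aa = a$aa,
                      elety = a$elety, x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  new("StructureModel", id = id, atoms = atoms)
}

#' Write a structure to a PDB file
#'
#' @param x A [StructureModel-class].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeStructure <- function(x, file) {
  a <- x@atoms
  xyz <- as.numeric(t(as.matrix(a[c("x", "y", "z")])))
  bio3d::write.pdb(file = file, xyz = xyz,
                   resno = a$resno, resid = AA1TO3[a$aa],
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain,
                   elesy = substr(gsub("^[0-9]", "", a$elety), 1, 1),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)))
  invisible(file)
}

# atoms of one residue as a small data.frame
getResidue <- function(x, chain, resno) {
  a <- if (is(x, "StructureModel")) x@atoms else x
  a[a$chain == chain & a$resno == resno, , drop = FALSE]
}

atomCoord <- function(res, name) {
  i <- match(name, res$elety)
  if (is.na(i)) return(NULL)
  c(res$x[i], res$y[i], res$z[i])
}

# ---------------------------------------------------------------------
# Ideal-geometry virtual Cbeta
# ---------------------------------------------------------------------

vnorm <- function(v) sqrt(sum(v * v))
vunit <- function(v) v / vnorm(v)
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# place CB at `bond` Angstrom from CA with equal angles to N and C,
# tilted out of the backbone plane (tetrahedral-like geometry)
idealCbeta <- function(n, ca, c, bond = 1.52, angle = 110.5) {
  u1 <- vunit(n - ca)
  u2 <- vunit(c - ca)
  m <- vunit(u1 + u2)
  perp <- vcross(u1, u2)
  if (vnorm(perp) < 1e-8) stop("backbone atoms are collinear")
  perp <- vunit(perp)
  # direction d = alpha*m + beta*perp with d.u1 = cos(angle)
  alpha <- cos(angle * pi / 180) / sum(m * u1)
  beta2 <- 1 - alpha^2
  if (beta2 < 0) stop("backbone geometry too distorted for ideal Cbeta")
  d <- alpha * m + sqrt(beta2) * perp
  ca + bond * d
}

#' Real or ideal-geometry virtual Cbeta of a residue
#'
#' Returns the residue's Cbeta coordinates when present; otherwise
#' (glycine, or truncated side chains) constructs an ideal-geometry
#' Cbeta from the N, Calpha and C backbone atoms (1.52 A bond,
#' tetrahedral-like placement out of the backbone plane).
#'
#' @param res Atom table of a single residue (rows of a
#'   [StructureModel-class] atom table).
#' @return Numeric 3-vector (Angstrom).
#' @export
virtualCbeta <- function(res) {
  cb <- atomCoord(res, "CB")
  if (!is.null(cb)) return(cb)
  n <- atomCoord(res, "N"); ca <- atomCoord(res, "CA"); cc <- atomCoord(res, "C")
  if (is.null(n) || is.null(ca) || is.null(cc)) {
    stop("residue lacks backbone atoms needed to construct Cbeta")
  }
  idealCbeta(n, ca, cc)
}

# ---------------------------------------------------------------------
# Template assembly
# ---------------------------------------------------------------------

#' Build a receptor-peptide template with heptad register
#'
#' Assigns heptad labels to the peptide chain outward from the anchor
#' residue, which is labeled `"3a"` (the conserved-Leu landmark of BH3
#' motifs). Peptide residues whose offset falls outside the 1a-5g
#' template coverage are excluded.
#'
#' @param structure A [StructureModel-class] containing both chains.
#' @param receptorChain,peptideChain Chain identifiers.
#' @param anchor `resno` of the peptide residue at register position 3a.
#' @return A [TemplateComplex-class].
#' @export
buildTemplate <- function(structure, receptorChain, peptideChain, anchor) {
  a <- structure@atoms
  chains <- unique(a$chain)
  if (!receptorChain %in% chains) stop("receptor chain not found: ", receptorChain)
  if (!peptideChain %in% chains) stop("peptide chain not found: ", peptideChain)
  rec <- a[a$chain == receptorChain, , drop = FALSE]
  pep <- a[a$chain == peptideChain, , drop = FALSE]
  resnos <- sort(unique(pep$resno))
  if (!anchor %in% resnos) {
    stop("anchor residue ", anchor, " not in peptide chain ", peptideChain)
  }
  labels <- heptadFromAnchor(resnos - anchor)
  keep <- !is.na(labels)
  reg <- data.frame(resno = resnos[keep], label = labels[keep],
                    stringsAsFactors = FALSE)
  pep <- pep[pep$resno %in% reg$resno, , drop = FALSE]
  new("TemplateComplex", id = structure@id,
      receptor = rec, peptide = pep, register = reg,
      receptorChain = receptorChain, peptideChain = peptideChain)
}
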