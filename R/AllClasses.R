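#' @import methods
NULL

# ---------------------------------------------------------------------
# StructureModel: a parsed structure as a flat atom table
# ---------------------------------------------------------------------

#' StructureModel: parsed protein structure
#'
#' Holds the heavy atoms of a structure as a flat table with one row
#' per atom. Residues are identified by `(chain, resno)`; amino acids
#' are stored as one-letter codes.
#'
#' @slot id Structure identifier.
#' @slot atoms `data.frame` with columns `chain`, `resno`, `aa`,
#'   `elety` (atom name), `x`, `y`, `z`.
#' @exportClass StructureModel
setClass("StructureModel",
  representation(id = "character", atoms = "data.frame"))

setValidity("StructureModel", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "aa", "elety", "x", "y", "z")
  if (!all(need %in% names(a))) {
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(a)) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z))) {
      return("atom coordinates must be finite")
    }
    if (any(!nzchar(a$elety))) return("atom names must be non-empty")
    key <- paste(a$chain, a$resno, a$elety)
    if (anyDuplicated(key)) return("duplicate atom name within a residue")
    if (!all(a$aa %in% AA20)) return("amino acids must be standard one-letter codes")
  }
  TRUE
})

setMethod("show", "StructureModel", function(object) {
  rt <- unique(object@atoms[c("chain", "resno")])
  cat("StructureModel '", object@id, "': ",
      nrow(rt), " residues, ", nrow(object@atoms), " atoms, chains: ",
      paste(unique(object@atoms$chain), collapse = ", "), "\n", sep = "")
})

#' @describeIn StructureModel-class Atom table accessor.
#' @param x A `StructureModel`.
#' @export
structureAtoms <- function(x) x@atoms

#' @describeIn StructureModel-class One row per residue
#'   (`chain`, `resno`, `aa`), in file order.
#' @export
residueTable <- function(x) {
  a <- x@atoms
  unique(a[c("chain", "resno", "aa")])
}

# ---------------------------------------------------------------------
# TemplateComplex: receptor + register-annotated peptide
# ---------------------------------------------------------------------

#' TemplateComplex: receptor-peptide template with heptad register
#'
#' A receptor-peptide complex in which every peptide residue carries a
#' heptad register label assigned outward from the anchor residue
#' (label `"3a"`). This is the input from which interface statistical
#' potentials are derived.
#'
#' @slot id Template identifier.
#' @slot receptor,peptide Atom tables (as in [StructureModel-class]).
#' @slot register `data.frame` with columns `resno`, `label` mapping
#'   peptide residues to heptad labels.
#' @slot receptorChain,peptideChain Chain identifiers.
#' @exportClass TemplateComplex
setClass("TemplateComplex",
  representation(id = "character",
                 receptor = "data.frame", peptide = "data.frame",
                 register = "data.frame",
                 receptorChain = "character", peptideChain = "character"))

setValidity("TemplateComplex", function(object) {
  reg <- object@register
  if (!all(c("resno", "label") %in% names(reg))) {
    return("register needs columns resno, label")
  }
  if (!all(reg$label %in% HEPTAD_FULL)) return("unknown register label")
  if (nrow(reg) > 1) {
    i <- match(reg$label, HEPTAD_FULL)
    if (!all(diff(i) == 1L)) return("register labels must be consecutive")
  }
  pep <- unique(object@peptide$resno)
  if (!all(pep %in% reg$resno)) {
    return("every peptide residue must have a register label")
  }
  rk <- paste(object@receptor$chain, object@receptor$resno)
  pk <- paste(object@peptide$chain, object@peptide$resno)
  if (length(intersect(rk, pk))) {
    return("receptor and peptide residues must be disjoint")
  }
  TRUE
})

setMethod("show", "TemplateComplex", function(object) {
  cat("TemplateComplex '", object@id, "': receptor chain ",
      object@receptorChain, " (",
      nrow(unique(object@receptor[c("chain", "resno")])),
      " residues), peptide chain ", object@peptideChain,
      " on register ", object@register$label[1], "-",
      object@register$label[nrow(object@register)], "\n", sep = "")
})

#' @describeIn TemplateComplex-class Register table accessor.
#' @param x A `TemplateComplex`.
#' @export
templateRegister <- function(x) x@register

#' @describeIn TemplateComplex-class Peptide sequence in register order.
#' @export
templatePeptideSeq <- function(x) {
  rt <- unique(x@peptide[c("resno", "aa")])
  paste(rt$aa[match(x@register$resno, rt$resno)], collapse = "")
}

# ---------------------------------------------------------------------
# StatiumModel: interface statistical potential
# ---------------------------------------------------------------------

#' StatiumModel: interface statistical potential
#'
#' Per template pair and per amino acid, the energy
#' \eqn{E = -\log(P_{AA,i} / P_{AA,PDB})}, where \eqn{P_{AA,i}} is the
#' (pseudocounted) frequency of the amino acid on the peptide side of
#' structurally matching database pairs and \eqn{P_{AA,PDB}} the
#' background frequency. Energies are oriented so that lower means
#' stronger predicted binding.
#'
#' @slot receptorName Name of the receptor the model scores.
#' @slot variant `"SC"` (all-heavy-atom receptor) or `"CB"`
#'   (Calpha/Cbeta only).
#' @slot pairs `data.frame` of template pairs (`pepLabel`, `recChain`,
#'   `recResno`, `recAa`, `total`, `lowCount`); `lowCount` flags pairs
#'   whose raw match count fell below the reliability threshold.
#' @slot counts,energies Pair-by-amino-acid matrices (columns [AA20]).
#' @slot background Background amino-acid frequencies (sums to 1).
#' @slot pseudocountMass Total pseudocount mass distributed by background.
#' @exportClass StatiumModel
setClass("StatiumModel",
  representation(receptorName = "character", variant = "character",
                 pairs = "data.frame", counts = "matrix",
                 energies = "matrix", background = "numeric",
                 pseudocountMass = "numeric"))

setValidity("StatiumModel", function(object) {
  if (!object@variant %in% c("SC", "CB")) return("variant must be SC or CB")
  if (!identical(colnames(object@energies), AA20)) {
    return("energy columns must be AA20")
  }
  if (nrow(object@energies) != nrow(object@pairs)) {
    return("one energy row per pair required")
  }
  if (any(is.nan(object@energies))) return("energies must not be NaN")
  bg <- object@background
  if (length(bg) != 20 || any(bg <= 0) || abs(sum(bg) - 1) > 1e-9) {
    return("background must be 20 positive frequencies summing to 1")
  }
  if (object@pseudocountMass > 0) {
    p <- (object@counts + object@pseudocountMass * rep(bg, each = nrow(object@counts))) /
      (rowSums(object@counts) + object@pseudocountMass)
    if (nrow(p) && any(abs(rowSums(p) - 1) > 1e-9)) {
      return("pair frequencies must sum to 1 after pseudocounts")
    }
  }
  TRUE
})

setMethod("show", "StatiumModel", function(object) {
  cat("StatiumModel (", object@variant, ") for ", object@receptorName,
      ": ", nrow(object@pairs), " template pairs over positions ",
      paste(sort(unique(object@pairs$pepLabel)), collapse = " "),
      "\n", sep = "")
  if (any(object@pairs$lowCount)) {
    cat("  note:", sum(object@pairs$lowCount),
        "pair(s) below the match-count reliability threshold\n")
  }
})

#' @describeIn StatiumModel-class Pair metadata accessor.
#' @param x A `StatiumModel`.
#' @export
modelPairs <- function(x) x@pairs

#' @describeIn StatiumModel-class Pair-by-amino-acid energy matrix.
#' @export
pairEnergies <- function(x) x@energies

#' @describeIn StatiumModel-class Energies collapsed per register
#'   position: a 20 x n-position matrix whose entry is the summed
#'   energy over all pairs at that position.
#' @export
positionEnergies <- function(x) {
  labs <- sort(unique(x@pairs$pepLabel))
  m <- vapply(labs, function(l) {
    colSums(x@energies[x@pairs$pepLabel == l, , drop = FALSE])
  }, numeric(20))
  rownames(m) <- AA20
  m
}

# ---------------------------------------------------------------------
# PssmModel: SPOT-array-derived position-specific scores
# ---------------------------------------------------------------------

#' The ten register positions covered by SPOT-array substitution data
#' @export
PSSM_POSITIONS <- c("2d", "2e", "2g", "3a", "3b", "3d", "3e", "3f", "3g", "4a")

#' PssmModel: position-specific scoring model from SPOT intensities
#'
#' Scores are \eqn{S = -(\log I - \log I_{ref})} for each substitution
#' relative to the wild-type reference peptide, at the ten register
#' positions with substitution data. Lower scores mean stronger
#' predicted binding; the reference residue scores exactly 0 at each
#' position.
#'
#' @slot receptorName Receptor the model scores.
#' @slot scores 20 x 10 matrix (rows [AA20], columns [PSSM_POSITIONS]).
#' @slot refAa Named character: reference (wild-type) residue per position.
#' @exportClass PssmModel
setClass("PssmModel",
  representation(receptorName = "character", scores = "matrix",
                 refAa = "character"))

setValidity("PssmModel", function(object) {
  s <- object@scores
  if (!identical(rownames(s), AA20)) return("score rows must be AA20")
  if (!identical(colnames(s), PSSM_POSITIONS)) {
    return("score columns must be the ten SPOT positions")
  }
  if (any(!is.finite(s))) return("scores must be finite (cap intensities first)")
  ref <- object@refAa
  if (!identical(names(ref), PSSM_POSITIONS) || !all(ref %in% AA20)) {
    return("refAa must name a standard residue for each position")
  }
  wt <- s[cbind(match(ref, AA20), seq_along(ref))]
  if (any(abs(wt) > 1e-9)) return("reference residue must score 0 at each position")
  TRUE
})

setMethod("show", "PssmModel", function(object) {
  cat("PssmModel for ", object@receptorName, ": 20 x ",
      ncol(object@scores), " positions (",
      paste(colnames(object@scores), collapse = " "),
      "), reference ", paste(object@refAa, collapse = ""), "\n", sep = "")
})

#' @describeIn PssmModel-class Score matrix accessor.
#' @param x A `PssmModel`.
#' @export
pssmScores <- function(x) x@scores

#' @describeIn PssmModel-class Reference (wild-type) residue per
#'   scored position.
#' @export
pssmRefAa <- function(x) x@refAa

# ---------------------------------------------------------------------
# RocResult
# ---------------------------------------------------------------------

#' RocResult: ROC curve, AUC and bootstrap confidence interval
#'
#' @slot points `data.frame` with columns `fpr`, `tpr` (monotone
#'   nondecreasing, from (0,0) to (1,1)).
#' @slot auc Area under the curve.
#' @slot ci90 Bootstrap confidence interval (`NA` if not computed).
#' @slot nPos,nNeg Class sizes.
#' @exportClass RocResult
setClass("RocResult",
  representation(points = "data.frame", auc = "numeric",
                 ci90 = "numeric", nPos = "integer", nNeg = "integer"))

setValidity("RocResult", function(object) {
  p <- object@points
  if (!all(c("fpr", "tpr") %in% names(p))) return("points need fpr, tpr")
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
  if (is.unsorted(p$fpr) || is.unsorted(p$tpr)) {
    return("ROC points must be monotone nondecreasing")
  }
  TRUE
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: AUC = %.3f (n+ = %d, n- = %d)",
              object@auc, object@nPos, object@nNeg))
  if (all(is.finite(object@ci90))) {
    cat(sprintf(", 90%% CI [%.3f, %.3f]", object@ci90[1], object@ci90[2]))
  }
  cat("\n")
})

#' @describeIn RocResult-class AUC accessor.
#' @param x A `RocResult`.
#' @export
aucValue <- function(x) x@auc

#' @describeIn RocResult-class ROC point accessor.
#' @export
rocPoints <- function(x) x@points
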