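# Interface statistical potentials.
#
# A template receptor-peptide complex defines a set of interacting
# residue pairs. Each template pair carries a distance fingerprint:
# all distances between the peptide residue's {Calpha, Cbeta} and the
# receptor residue's heavy side-chain atoms (variant "SC") or its
# {Calpha, Cbeta} (variant "CB"). A database of single-chain
# structures is scanned for residue pairs whose receptor-side amino
# acid matches and whose fingerprint agrees to better than an RMSD
# cutoff; the peptide-side amino acids of the matches populate a count
# matrix per pair, converted to energies against background
# frequencies.

#' Interaction criterion for residue-pair detection and matching
#'
#' @param variant `"SC"`: a pair interacts when any receptor heavy
#'   side-chain atom lies within `distanceCutoff` (default 6 A) of the
#'   peptide residue's Calpha/Cbeta. `"CB"`: Cbeta atoms within
#'   `distanceCutoff` (default 10 A) with Calpha-Cbeta vectors not
#'   pointed away from each other (see `angleRule`).
#' @param distanceCutoff Detection cutoff in Angstrom; defaults to 6
#'   (SC) or 10 (CB).
#' @param angleRule For `"CB"` only: require
#'   \eqn{(C\beta_i-C\alpha_i)\cdot(C\beta_j-C\beta_i) \ge 0} and
#'   \eqn{(C\beta_j-C\alpha_j)\cdot(C\beta_i-C\beta_j) \ge 0}.
#' @param fingerprintRmsdCutoff Structural-similarity cutoff: database
#'   pairs match a template pair when the root-mean-square difference
#'   of their fingerprint distances is strictly below this value
#'   (default 0.4 A).
#' @return A list with class `"InteractionCriterion"`.
#' @export
interactionCriterion <- function(variant = c("SC", "CB"),
                                 distanceCutoff = NULL,
                                 angleRule = NULL,
                                 fingerprintRmsdCutoff = 0.4) {
  variant <- match.arg(variant)
  if (is.null(distanceCutoff)) {
    distanceCutoff <- if (variant == "SC") 6.0 else 10.0
  }
  if (is.null(angleRule)) angleRule <- variant == "CB"
  stopifnot(distanceCutoff > 0, fingerprintRmsdCutoff > 0)
  structure(list(variant = variant, distanceCutoff = distanceCutoff,
                 angleRule = angleRule,
                 fingerprintRmsdCutoff = fingerprintRmsdCutoff),
            class = "InteractionCriterion")
}

# representation of a residue in the peptide role: Calpha plus
# real-or-virtual Cbeta (2 x 3 matrix), or NULL when atoms are missing
peptideRep <- function(res) {
  ca <- atomCoord(res, "CA")
  if (is.null(ca)) return(NULL)
  cb <- tryCatch(virtualCbeta(res), error = function(e) NULL)
  if (is.null(cb)) return(NULL)
  rbind(CA = ca, CB = cb)
}

# receptor-role atoms: canonical heavy side-chain atoms present, in
# canonical PDB order (glycine: Calpha stands in for the side chain)
receptorSidechain <- function(res) {
  aa <- res$aa[1]
  names <- SIDECHAIN_ATOMS[[aa]]
  if (!length(names)) names <- "CA"
  present <- intersect(names, res$elety)
  if (!length(present)) return(NULL)
  i <- match(present, res$elety)
  m <- as.matrix(res[i, c("x", "y", "z")])
  rownames(m) <- present
  m
}

receptorRep <- function(res, variant) {
  if (variant == "SC") return(receptorSidechain(res))
  peptideRep(res)  # CB variant: receptor Calpha/Cbeta
}

crossDist <- function(a, b) {
  # a: m x 3, b: n x 3 -> m x n distance matrix
  m2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(m2, 0))
}

# fingerprint: distances ordered (peptide atom order) x (receptor
# atom-name order): CA to all receptor atoms, then CB to all
pairFingerprint <- function(pepRep, recRep) {
  as.vector(t(crossDist(pepRep, recRep)))
}

cbAngleOk <- function(pepRep, recRep) {
  vi <- pepRep["CB", ] - pepRep["CA", ]
  vj <- recRep["CB", ] - recRep["CA", ]
  d <- recRep["CB", ] - pepRep["CB", ]
  sum(vi * d) >= 0 && sum(vj * -d) >= 0
}

pairInteracts <- function(pepRep, recRep, recSide, crit) {
  if (crit$variant == "SC") {
    min(crossDist(pepRep, recSide)) < crit$distanceCutoff
  } else {
    vnorm(pepRep["CB", ] - recRep["CB", ]) < crit$distanceCutoff &&
      (!crit$angleRule || cbAngleOk(pepRep, recRep))
  }
}

#' Detect interacting template pairs
#'
#' Applies the interaction criterion to every (peptide residue,
#' receptor residue) pair of a template complex and records the
#' distance fingerprint of each interacting pair.
#'
#' @param template A [TemplateComplex-class].
#' @param crit An [interactionCriterion()].
#' @return `data.frame` with one row per interacting pair: `pepLabel`,
#'   `pepResno`, `recChain`, `recResno`, `recAa`, and a list column
#'   `fingerprint` of distance vectors (Angstrom).
#' @export
detectPairs <- function(template, crit = interactionCriterion("SC")) {
  reg <- template@register
  if (!nrow(reg)) stop("template has an empty peptide register")
  recRt <- unique(template@receptor[c("chain", "resno", "aa")])
  out <- vector("list", 0)
  for (pi in seq_len(nrow(reg))) {
    pres <- getResidue(template@peptide, template@peptideChain, reg$resno[pi])
    prep <- peptideRep(pres)
    if (is.null(prep)) {
      warning("peptide residue ", reg$resno[pi],
              " lacks atoms for Calpha/Cbeta representation; skipped")
      next
    }
    for (ri in seq_len(nrow(recRt))) {
      rres <- getResidue(template@receptor, recRt$chain[ri], recRt$resno[ri])
      rside <- receptorSidechain(rres)
      rrep <- receptorRep(rres, crit$variant)
      if (is.null(rrep) || (crit$variant == "SC" && is.null(rside))) next
      if (pairInteracts(prep, rrep, rside, crit)) {
        out[[length(out) + 1L]] <- list(
          pepLabel = reg$label[pi], pepResno = reg$resno[pi],
          recChain = recRt$chain[ri], recResno = recRt$resno[ri],
          recAa = recRt$aa[ri],
          fingerprint = pairFingerprint(prep, rrep))
      }
    }
  }
  pairsToFrame(out)
}

pairsToFrame <- function(out) {
  if (!length(out)) {
    return(data.frame(pepLabel = character(0), pepResno = integer(0),
                      recChain = character(0), recResno = integer(0),
                      recAa = character(0),
                      fingerprint = I(list()), stringsAsFactors = FALSE))
  }
  df <- data.frame(
    pepLabel = vapply(out, `[[`, "", "pepLabel"),
    pepResno = vapply(out, `[[`, 0L, "pepResno"),
    recChain = vapply(out, `[[`, "", "recChain"),
    recResno = vapply(out, `[[`, 0L, "recResno"),
    recAa = vapply(out, `[[`, "", "recAa"),
    stringsAsFactors = FALSE)
  df$fingerprint <- I(lapply(out, `[[`, "fingerprint"))
  df
}

#' Root-mean-square difference of two pair fingerprints
#'
#' @param fp1,fp2 Equal-length numeric distance vectors with matched
#'   atom order.
#' @return RMSD in Angstrom.
#' @examples
#' fingerprintRmsd(c(1, 2, 3, 4), c(1, 2, 3, 4.8))  # 0.4
#' @export
fingerprintRmsd <- function(fp1, fp2) {
  if (length(fp1) != length(fp2)) {
    stop("fingerprint length mismatch: ", length(fp1), " vs ", length(fp2))
  }
  sqrt(mean((fp1 - fp2)^2))
}

# all oriented interacting residue pairs within one structure; each
# residue may play either the receptor or the peptide role
chainPairs <- function(structure, crit = interactionCriterion("SC")) {
  a <- structure@atoms
  rt <- unique(a[c("chain", "resno", "aa")])
  n <- nrow(rt)
  res <- lapply(seq_len(n), function(i) getResidue(a, rt$chain[i], rt$resno[i]))
  preps <- lapply(res, function(r) tryCatch(peptideRep(r), error = function(e) NULL))
  rsides <- lapply(res, receptorSidechain)
  rreps <- if (crit$variant == "SC") rsides else preps
  ca <- t(vapply(seq_len(n), function(i) {
    v <- atomCoord(res[[i]], "CA")
    if (is.null(v)) c(NA_real_, NA_real_, NA_real_) else v
  }, numeric(3)))
  screen <- crit$distanceCutoff + 14  # side chains extend < 14 A from Calpha
  cad <- if (n > 1) crossDist(ca, ca) else matrix(0, 1, 1)
  out <- vector("list", 0)
  for (ri in seq_len(n)) {        # receptor role
    if (is.null(rreps[[ri]])) next
    for (pi in seq_len(n)) {      # peptide role
      if (pi == ri || is.null(preps[[pi]])) next
      if (!is.na(cad[ri, pi]) && cad[ri, pi] > screen) next
      if (pairInteracts(preps[[pi]], rreps[[ri]], rsides[[ri]], crit)) {
        out[[length(out) + 1L]] <- list(
          recAa = rt$aa[ri], pepAa = rt$aa[pi],
          fingerprint = pairFingerprint(preps[[pi]], rreps[[ri]]))
      }
    }
  }
  if (!length(out)) {
    return(data.frame(recAa = character(0), pepAa = character(0),
                      fingerprint = I(list()), stringsAsFactors = FALSE))
  }
  df <- data.frame(recAa = vapply(out, `[[`, "", "recAa"),
                   pepAa = vapply(out, `[[`, "", "pepAa"),
                   stringsAsFactors = FALSE)
  df$fingerprint <- I(lapply(out, `[[`, "fingerprint"))
  df
}

#' Scan a structure database for pairs matching the template
#'
#' For every template pair, every database residue pair whose
#' receptor-role amino acid is identical to the template pair's
#' receptor residue and whose fingerprint RMSD is strictly below the
#' cutoff increments the count of the database pair's peptide-role
#' amino acid. Both orientations of each database pair are tested
#' (either member may play the receptor role).
#'
#' @param pairs Template pairs from [detectPairs()].
#' @param db List of [StructureModel-class] objects.
#' @param crit The [interactionCriterion()] used for the template.
#' @return Integer count matrix, one row per template pair, columns
#'   [AA20].
#' @export
scanDatabase <- function(pairs, db, crit = interactionCriterion("SC")) {
  counts <- matrix(0L, nrow = nrow(pairs), ncol = 20,
                   dimnames = list(NULL, AA20))
  if (!length(db)) {
    warning("empty structure database: all counts are zero")
    return(counts)
  }
  tlen <- vapply(pairs$fingerprint, length, 0L)
  for (s in db) {
    dp <- chainPairs(s, crit)
    if (!nrow(dp)) next
    dlen <- vapply(dp$fingerprint, length, 0L)
    for (i in seq_len(nrow(pairs))) {
      cand <- which(dp$recAa == pairs$recAa[i] & dlen == tlen[i])
      for (j in cand) {
        if (fingerprintRmsd(pairs$fingerprint[[i]], dp$fingerprint[[j]]) <
            crit$fingerprintRmsdCutoff) {
          aa <- dp$pepAa[j]
          counts[i, aa] <- counts[i, aa] + 1L
        }
      }
    }
  }
  counts
}

#' Background amino-acid frequencies of a structure database
#'
#' Counts residues uniformly over all structures. A small smoothing
#' count keeps every frequency strictly positive.
#'
#' @param db List of [StructureModel-class] objects.
#' @param smoothing Count added to every amino acid (default 0.5).
#' @return Named numeric vector over [AA20], summing to 1.
#' @export
backgroundFrequencies <- function(db, smoothing = 0.5) {
  n <- setNames(rep(smoothing, 20), AA20)
  for (s in db) {
    t <- table(residueTable(s)$aa)
    n[names(t)] <- n[names(t)] + as.numeric(t)
  }
  n / sum(n)
}

#' Uniform background frequencies
#'
#' @return Named numeric vector, 1/20 for each amino acid.
#' @export
uniformBackground <- function() setNames(rep(1 / 20, 20), AA20)

#' Derive a statistical potential from pair counts
#'
#' Converts per-pair amino-acid counts to energies
#' \eqn{E = -\ln(P_{AA} / P_{bg})} with
#' \eqn{P_{AA} = (count + m \cdot bg) / (total + m)} where `m` is the
#' pseudocount mass distributed according to the background. With
#' `pseudocountMass = 0` the raw log-ratio is used (amino acids with
#' zero counts then score `+Inf`).
#'
#' @param pairs Template pairs from [detectPairs()].
#' @param counts Count matrix from [scanDatabase()].
#' @param background Background frequencies (e.g.
#'   [backgroundFrequencies()] or [uniformBackground()]).
#' @param pseudocountMass Total pseudocount mass (default 20).
#' @param lowCountThreshold Pairs with fewer raw matches than this are
#'   flagged as unreliable in the model metadata (default 100).
#' @param receptorName,variant Model metadata.
#' @return A [StatiumModel-class].
#' @export
derivePotential <- function(pairs, counts, background = uniformBackground(),
                            pseudocountMass = 20, lowCountThreshold = 100,
                            receptorName = "receptor", variant = "SC") {
  stopifnot(nrow(counts) == nrow(pairs), pseudocountMass >= 0)
  background <- background[AA20]
  total <- rowSums(counts)
  if (pseudocountMass == 0 && any(total == 0)) {
    stop("pair(s) with zero total counts and no pseudocounts")
  }
  p <- (counts + pseudocountMass * rep(background, each = nrow(counts))) /
    (total + pseudocountMass)
  e <- -log(sweep(p, 2, background, "/"))
  colnames(e) <- AA20
  pr <- pairs[c("pepLabel", "pepResno", "recChain", "recResno", "recAa")]
  pr$total <- as.integer(total)
  pr$lowCount <- total < lowCountThreshold
  storage.mode(counts) <- "integer"
  new("StatiumModel", receptorName = receptorName, variant = variant,
      pairs = pr, counts = counts, energies = e,
      background = background, pseudocountMass = pseudocountMass)
}

#' Score peptide windows with a statistical potential
#'
#' The score of a window is the sum, over all template pairs, of the
#' pair's energy for the amino acid the window places at that pair's
#' register position. Lower scores mean stronger predicted binding.
#'
#' @param model A [StatiumModel-class].
#' @param windows Character vector of sequences aligned to `register`.
#' @param register Register labels of the window positions (default:
#'   the 26-residue 1d-5a window).
#' @return Numeric vector of energies.
#' @export
scoreStatium <- function(model, windows,
                         register = registerLabels("1d", "5a")) {
  labs <- sort(unique(model@pairs$pepLabel))
  if (!all(labs %in% register)) {
    stop("window register does not cover model positions: ",
         paste(setdiff(labs, register), collapse = ", "))
  }
  if (any(nchar(windows) != length(register))) {
    stop("all windows must have length ", length(register))
  }
  posE <- positionEnergies(model)
  ch <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
               nrow = length(register))
  scores <- numeric(length(windows))
  for (l in labs) {
    aa <- ch[match(l, register), ]
    i <- match(aa, AA20)
    if (anyNA(i)) stop("non-standard amino acid in window")
    scores <- scores + posE[cbind(i, match(l, colnames(posE)))]
  }
  scores
}
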