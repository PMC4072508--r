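# Seeded generators for synthetic inputs: template complexes,
# structure databases with planted amino-acid preferences, proteomes
# with planted motifs, SPOT intensity tables, K_D tables, alignments.
#
# The geometry is idealized, not physical: an alpha-helical peptide
# trace (2.3 A radius, 1.5 A rise, 100 deg/residue) with
# ideal-geometry Cbeta atoms and pseudo side chains, and receptor
# residues placed radially at controlled approach distances so that
# the planted contact set is exactly the set satisfying the
# interaction criterion. Generators exist to exercise the geometric
# and statistical contracts of the pipeline, not to emulate real
# protein energetics.

# approximate vertebrate proteome amino-acid frequencies
AA_FREQS <- c(A = 0.070, C = 0.023, D = 0.047, E = 0.071, F = 0.036,
              G = 0.066, H = 0.026, I = 0.043, K = 0.057, L = 0.100,
              M = 0.021, N = 0.036, P = 0.063, Q = 0.048, R = 0.056,
              S = 0.083, T = 0.053, V = 0.060, W = 0.012, Y = 0.027)
AA_FREQS <- AA_FREQS / sum(AA_FREQS)

perpBasis <- function(u) {
  a <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  p1 <- vunit(vcross(u, a))
  list(p1 = p1, p2 = vcross(u, p1))
}

# pseudo side-chain atoms beyond CB, stepping outward from the Calpha
sidechainPseudo <- function(ca, cb, aa) {
  names <- SIDECHAIN_ATOMS[[aa]]
  if (length(names) < 2) return(NULL)
  out <- vunit(cb - ca)
  pb <- perpBasis(out)
  k <- seq_len(length(names) - 1)
  pos <- t(vapply(k, function(m) {
    cb + 0.9 * m * out + 0.45 * sin(2.1 * m) * pb$p1 +
      0.45 * cos(2.1 * m) * pb$p2
  }, numeric(3)))
  rownames(pos) <- names[-1]
  pos
}

atomRows <- function(chain, resno, aa, coords) {
  data.frame(chain = chain, resno = resno, aa = aa,
             elety = rownames(coords),
             x = unname(coords[, 1]), y = unname(coords[, 2]),
             z = unname(coords[, 3]),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Helical peptide trace + Cbeta + pseudo side chains. The default
# rise is deliberately larger than a real alpha-helix (1.5 A/residue):
# with physical spacing every contact within the 6 A cutoff of one
# residue also touches its helical neighbours, so no planted contact
# set could be exactly recoverable. Stretching the rise isolates the
# residues while keeping the helical phase of the side-chain
# directions.
buildHelix <- function(seq, chain = "P", startResno = 1L, sidechains = TRUE,
                       radius = 2.3, rise = 5.0, twist = 100) {
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  i <- 0:(n + 1)  # one virtual residue beyond each terminus
  ca <- cbind(radius * cos(i * twist * pi / 180),
              radius * sin(i * twist * pi / 180),
              rise * i)
  rows <- vector("list", n)
  for (j in seq_len(n)) {
    cai <- ca[j + 1, ]
    np <- cai + 1.45 * vunit(ca[j, ] - cai)
    cp <- cai + 1.52 * vunit(ca[j + 2, ] - cai)
    coords <- rbind(N = np, CA = cai, C = cp)
    if (aa[j] != "G") {
      cb <- idealCbeta(np, cai, cp)
      coords <- rbind(coords, CB = cb)
      if (sidechains) {
        ps <- sidechainPseudo(cai, cb, aa[j])
        if (!is.null(ps)) coords <- rbind(coords, ps)
      }
    }
    rows[[j]] <- atomRows(chain, startResno + j - 1L, aa[j], coords)
  }
  do.call(rbind, rows)
}

# a receptor residue approaching a peptide residue radially: its
# nearest side-chain atom sits exactly `approach` Angstrom from the
# peptide residue's Cbeta, the rest of the side chain extends away
receptorResidueAt <- function(pepRes, aa, approach, chain = "R", resno = 101L,
                              tilt = 0) {
  ca <- atomCoord(pepRes, "CA")
  cb <- tryCatch(virtualCbeta(pepRes), error = function(e) NULL)
  if (is.null(ca) || is.null(cb)) stop("peptide residue lacks CA/CB")
  out <- vunit(cb - ca)
  if (tilt != 0) {
    pb <- perpBasis(out)
    out <- vunit(cos(tilt) * out + sin(tilt) * pb$p1)
  }
  tip <- cb + approach * out
  side <- SIDECHAIN_ATOMS[[aa]]
  pb <- perpBasis(out)
  if (!length(side)) {  # glycine: Calpha stands in for the side chain
    coords <- rbind(CA = tip,
                    N = tip + 1.3 * out + 1.45 * pb$p1,
                    C = tip + 1.3 * out - 1.45 * pb$p2)
    return(atomRows(chain, resno, aa, coords))
  }
  m <- length(side)
  pos <- t(vapply(seq_len(m), function(k) {
    jit <- if (k < m) 0.4 * sin(1.7 * k) * pb$p1 + 0.4 * cos(1.7 * k) * pb$p2
           else c(0, 0, 0)  # the tip atom is exactly at `approach`
    tip + (m - k) * 1.3 * out + jit
  }, numeric(3)))
  rownames(pos) <- side
  cbPos <- pos[1, ]
  caPos <- cbPos + 1.52 * out
  coords <- rbind(pos,
                  CA = caPos,
                  N = caPos + 1.45 * vunit(out + pb$p1),
                  C = caPos + 1.52 * vunit(out - pb$p2))
  atomRows(chain, resno, aa, coords)
}

#' Generate a synthetic receptor-peptide template complex
#'
#' Builds an idealized helical peptide and places one receptor
#' residue radially against each requested peptide position, with the
#' nearest receptor side-chain atom at exactly the given approach
#' distance from the peptide Cbeta. Contacts with `approach` below
#' the detection cutoff form the planted pair set; decoy residues are
#' placed far away. With `verify = TRUE` the generator checks that
#' [detectPairs()] recovers exactly the planted set and errors
#' otherwise (a geometrically infeasible specification).
#'
#' @param peptideSeq Peptide sequence (23-mer on 1g-5a or 26-mer on
#'   1d-5a; anchor 3a inferred from the length).
#' @param contacts `data.frame` with columns `label` (heptad label),
#'   `aa` (receptor residue type) and optionally `approach`
#'   (Angstrom, default 4.0).
#' @param decoys Optional `data.frame` like `contacts`; default
#'   approach 14 A (beyond any cutoff).
#' @param crit Criterion used for verification.
#' @param verify Check planted-set recovery (default `TRUE`).
#' @return List: `structure` ([StructureModel-class]), `template`
#'   ([TemplateComplex-class]), `receptorChain`, `peptideChain`,
#'   `anchor` (resno of 3a), `planted` (the contacts table with
#'   receptor `resno`).
#' @export
simComplex <- function(peptideSeq = "EIAQELRKIGDEFNAYYARSELV",
                       contacts = data.frame(
                         label = c("2d", "3a", "3e", "3f", "4a"),
                         aa = c("F", "W", "R", "K", "Y")),
                       decoys = NULL,
                       crit = interactionCriterion("SC"),
                       verify = TRUE) {
  n <- nchar(peptideSeq)
  from <- switch(as.character(n), "23" = "1g", "26" = "1d",
                 stop("peptide must be a 23-mer (1g-5a) or 26-mer (1d-5a)"))
  register <- registerLabels(from, "5a")
  anchor <- registerIndex("3a", register)
  pep <- buildHelix(peptideSeq, chain = "P")
  if (is.null(contacts$approach)) contacts$approach <- 4.0
  planted <- contacts
  planted$resno <- 100L + seq_len(nrow(contacts))
  recRows <- list()
  seen <- table(character(0))
  for (i in seq_len(nrow(planted))) {
    lab <- planted$label[i]
    dup <- sum(planted$label[seq_len(i - 1)] == lab)
    pres <- pep[pep$resno == match(lab, register), , drop = FALSE]
    if (!nrow(pres)) stop("contact label outside peptide register: ", lab)
    recRows[[i]] <- receptorResidueAt(pres, planted$aa[i], planted$approach[i],
                                      resno = planted$resno[i],
                                      tilt = dup * pi / 6)
  }
  if (!is.null(decoys)) {
    if (is.null(decoys$approach)) decoys$approach <- 14.0
    for (i in seq_len(nrow(decoys))) {
      pres <- pep[pep$resno == match(decoys$label[i], register), , drop = FALSE]
      recRows[[length(recRows) + 1L]] <-
        receptorResidueAt(pres, decoys$aa[i], decoys$approach[i],
                          resno = 200L + i)
    }
  }
  atoms <- rbind(do.call(rbind, recRows), pep)
  rownames(atoms) <- NULL
  structure <- new("StructureModel", id = "synthetic-complex", atoms = atoms)
  template <- buildTemplate(structure, "R", "P", anchor)
  if (verify) {
    det <- detectPairs(template, crit)
    want <- planted[planted$approach < crit$distanceCutoff, , drop = FALSE]
    got <- paste(det$pepLabel, det$recResno)
    exp <- paste(want$label, want$resno)
    if (!setequal(got, exp)) {
      stop("geometrically infeasible specification: planted pairs ",
           paste(exp, collapse = ","), " but detected ",
           paste(got, collapse = ","))
    }
  }
  list(structure = structure, template = template,
       receptorChain = "R", peptideChain = "P",
       anchor = anchor, planted = planted)
}

#' Generate a random synthetic complex
#'
#' Receptor residues of random type are placed against random peptide
#' positions at approach distances spanning both sides of the
#' detection cutoff. No planted bookkeeping: use against a
#' brute-force oracle.
#'
#' @param seed Integer seed.
#' @param nReceptor Number of receptor residues (default 8).
#' @return As [simComplex()], without verification.
#' @export
simRandomComplex <- function(seed = 1, nReceptor = 8) {
  set.seed(seed)
  register <- registerLabels("1g", "5a")
  peptideSeq <- paste(sample(AA20, 23, replace = TRUE, prob = AA_FREQS),
                      collapse = "")
  contacts <- data.frame(
    label = sample(register, nReceptor, replace = TRUE),
    aa = sample(AA20, nReceptor, replace = TRUE),
    approach = round(stats::runif(nReceptor, 3, 12), 2))
  simComplex(peptideSeq, contacts, verify = FALSE)
}

#' Generate a structure database with planted amino-acid preferences
#'
#' Each database structure is a single chain containing, for every
#' template pair, a geometric copy of that pair (receptor residue plus
#' peptide-role Calpha/Cbeta backbone) whose peptide-role amino acid
#' is drawn from the planted preference distribution for that pair's
#' register position, with small coordinate jitter. Optional decoy
#' copies are displaced by 1 A so they are detected as interacting but
#' fail the fingerprint-RMSD match.
#'
#' @param template A [TemplateComplex-class] (e.g. from
#'   [simComplex()]).
#' @param crit The [interactionCriterion()].
#' @param n Number of structures (default 500).
#' @param preferences Named list: register label -> named probability
#'   vector over amino acids. Positions without an entry draw
#'   uniformly from `defaultAa`.
#' @param defaultAa Amino acids used for unlisted positions (default
#'   avoids clashing with common receptor residue types).
#' @param decoys Include displaced decoy copies (default `TRUE`).
#' @param jitterSd Per-coordinate Gaussian jitter, A (default 0.02).
#' @param exactCounts Plant amino-acid counts at the exact preference
#'   proportions (largest-remainder rounding, shuffled across
#'   structures) instead of binomial draws (default `FALSE`).
#' @param seed Integer seed.
#' @return List: `db` (list of [StructureModel-class]), `truth`
#'   (`data.frame` of drawn amino acids per structure and position).
#' @note Template pairs sharing a receptor residue type and congruent
#'   local geometry cross-match each other's copies, as they would in
#'   a real database; keep receptor types distinct per position when
#'   exact per-position bookkeeping is wanted.
#' @export
simStructureDb <- function(template, crit = interactionCriterion("SC"),
                           n = 500, preferences = list(),
                           defaultAa = c("A", "D", "G", "L", "N", "S"),
                           decoys = TRUE, jitterSd = 0.02,
                           exactCounts = FALSE, seed = 1) {
  set.seed(seed)
  pairs <- detectPairs(template, crit)
  if (!nrow(pairs)) stop("template has no interacting pairs")
  drawFor <- function(lab) {
    pref <- preferences[[lab]]
    if (is.null(pref)) return(sample(defaultAa, n, replace = TRUE))
    if (!exactCounts) return(sample(names(pref), n, replace = TRUE,
                                    prob = pref))
    # largest-remainder apportionment of n among the preference aas
    q <- n * pref / sum(pref)
    k <- floor(q)
    rem <- n - sum(k)
    if (rem > 0) {
      k[order(q - floor(q), decreasing = TRUE)[seq_len(rem)]] <-
        k[order(q - floor(q), decreasing = TRUE)[seq_len(rem)]] + 1
    }
    sample(rep(names(pref), k))
  }
  drawnAll <- vapply(pairs$pepLabel, drawFor, character(n))
  if (n == 1) drawnAll <- matrix(drawnAll, nrow = 1)
  db <- vector("list", n)
  truth <- vector("list", n)
  for (s in seq_len(n)) {
    groups <- vector("list", nrow(pairs) * (1 + decoys))
    drawn <- character(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      aa <- drawnAll[s, i]
      drawn[i] <- aa
      rres <- getResidue(template@receptor, pairs$recChain[i],
                         pairs$recResno[i])
      pres <- getResidue(template@peptide, template@peptideChain,
                         pairs$pepResno[i])
      off <- c((i - 1) * 80, 0, 0)
      grp <- pairCopy(rres, pres, aa, resnoBase = i * 10L, offset = off,
                      jitterSd = jitterSd)
      groups[[i]] <- grp
      if (decoys) {
        offd <- c((i - 1) * 80, 120, 0)
        groups[[nrow(pairs) + i]] <-
          pairCopy(rres, pres, sample(defaultAa, 1),
                   resnoBase = 1000L + i * 10L, offset = offd,
                   jitterSd = jitterSd, displace = 1.0)
      }
    }
    atoms <- do.call(rbind, groups)
    rownames(atoms) <- NULL
    db[[s]] <- new("StructureModel", id = sprintf("db%04d", s), atoms = atoms)
    truth[[s]] <- data.frame(structure = s, pepLabel = pairs$pepLabel,
                             aa = drawn, stringsAsFactors = FALSE)
  }
  list(db = db, truth = do.call(rbind, truth))
}

# copy a template pair into a free-standing two-residue group
pairCopy <- function(rres, pres, pepAa, resnoBase, offset, jitterSd,
                     displace = 0) {
  recC <- as.matrix(rres[c("x", "y", "z")])
  rownames(recC) <- rres$elety
  keep <- c("N", "CA", "C", if (pepAa != "G") "CB")
  pepAtoms <- pres[match(keep, pres$elety), , drop = FALSE]
  if (anyNA(pepAtoms$elety)) stop("template peptide residue lacks backbone")
  pepC <- as.matrix(pepAtoms[c("x", "y", "z")])
  rownames(pepC) <- pepAtoms$elety
  if (displace > 0) {
    u <- vunit(colMeans(pepC) - colMeans(recC))
    pepC <- sweep(pepC, 2, displace * u, "+")
  }
  jig <- function(m) m + matrix(stats::rnorm(length(m), 0, jitterSd),
                                nrow = nrow(m))
  recC <- sweep(jig(recC), 2, offset, "+")
  pepC <- sweep(jig(pepC), 2, offset, "+")
  rbind(atomRows("A", resnoBase + 1L, rres$aa[1], recC),
        atomRows("A", resnoBase + 2L, pepAa, pepC))
}

#' Consensus window optimal under a pair of models
#'
#' Builds the 26-mer (1d-5a register) that minimizes the summed
#' position contributions of a statistical potential and a SPOT model,
#' subject to the compositional filter: 3a and 3e are chosen within
#' their allowed sets, prolines are avoided in the 2d-4a core, and
#' positions not covered by either model are filled with glutamate to
#' satisfy the polar-fraction rule.
#'
#' @param statiumModel A [StatiumModel-class].
#' @param pssmModel A [PssmModel-class].
#' @param cfg A [filterConfig()].
#' @return A 26-character string passing [compositionFilter()].
#' @export
consensusWindow <- function(statiumModel, pssmModel, cfg = filterConfig()) {
  register <- registerLabels("1d", "5a")
  contrib <- matrix(0, nrow = 20, ncol = 26, dimnames = list(AA20, register))
  covered <- rep(FALSE, 26)
  posE <- positionEnergies(statiumModel)
  for (l in intersect(colnames(posE), register)) {
    contrib[, l] <- contrib[, l] + posE[, l]
    covered[match(l, register)] <- TRUE
  }
  for (p in PSSM_POSITIONS) {
    contrib[, p] <- contrib[, p] + pssmScores(pssmModel)[, p]
    covered[match(p, register)] <- TRUE
  }
  core <- registerIndex("2d", register):registerIndex("4a", register)
  pick <- character(26)
  for (j in seq_len(26)) {
    allowed <- AA20
    if (register[j] == "3a") allowed <- cfg$pos3aSet
    if (register[j] == "3e") allowed <- cfg$pos3eSet
    if (j %in% core) allowed <- setdiff(allowed, "P")
    pick[j] <- if (covered[j]) allowed[which.min(contrib[allowed, j])]
               else "E"
  }
  # enforce the polar-fraction rule with minimal score cost
  repeat {
    polar <- mean(pick %in% cfg$polarSet)
    if (polar >= cfg$polarMinFraction) break
    cand <- which(!pick %in% cfg$polarSet &
                    !register %in% c("3a", "3e"))
    cost <- vapply(cand, function(j) {
      pol <- intersect(cfg$polarSet, AA20)
      min(contrib[pol, j]) - contrib[pick[j], j]
    }, numeric(1))
    j <- cand[which.min(cost)]
    pol <- intersect(cfg$polarSet, AA20)
    pick[j] <- pol[which.min(contrib[pol, j])]
  }
  paste(pick, collapse = "")
}

#' Generate a synthetic proteome with planted motifs
#'
#' Random-composition proteins (approximate vertebrate amino-acid
#' frequencies) with `plantSequence` inserted at a random offset in
#' `nPlanted` distinct proteins.
#'
#' @param nProteins,proteinLength Proteome dimensions (default 100
#'   proteins of 300 residues).
#' @param plantSequence 26-mer to plant (e.g. from
#'   [consensusWindow()]); `NULL` plants nothing.
#' @param nPlanted Number of planted copies (default 5).
#' @param seed Integer seed.
#' @return List: `proteome` (named character vector), `truth`
#'   (`data.frame` with `protein`, `start` 0-based, `sequence`).
#' @export
simProteome <- function(nProteins = 100, proteinLength = 300,
                        plantSequence = NULL, nPlanted = 5, seed = 1) {
  set.seed(seed)
  stopifnot(nPlanted <= nProteins)
  prots <- vapply(seq_len(nProteins), function(i) {
    paste(sample(AA20, proteinLength, replace = TRUE, prob = AA_FREQS),
          collapse = "")
  }, "")
  names(prots) <- sprintf("prot%04d", seq_len(nProteins))
  truth <- data.frame(protein = character(0), start = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  if (!is.null(plantSequence) && nPlanted > 0) {
    w <- nchar(plantSequence)
    stopifnot(w <= proteinLength)
    hosts <- sample(nProteins, nPlanted)
    starts <- sample(proteinLength - w + 1, nPlanted, replace = TRUE)
    for (k in seq_len(nPlanted)) {
      s <- prots[[hosts[k]]]
      substr(s, starts[k], starts[k] + w - 1) <- plantSequence
      prots[[hosts[k]]] <- s
    }
    truth <- data.frame(protein = names(prots)[hosts],
                        start = starts - 1L,
                        sequence = plantSequence, stringsAsFactors = FALSE)
  }
  list(proteome = prots, truth = truth)
}

#' Generate a synthetic SPOT substitution table
#'
#' One intensity per (position, amino acid), relative to a wild-type
#' reference peptide whose residues have intensity 1. Substitutions
#' at strongly constrained positions (3a, 3e, 3f) draw low
#' intensities; tolerant positions draw intensities near the
#' reference.
#'
#' @param refAa Named character: wild-type residue per
#'   [PSSM_POSITIONS].
#' @param noiseSd Lognormal noise on mutant intensities (default 0.5).
#' @param seed Integer seed.
#' @return A [spotTable()].
#' @export
simSpotTable <- function(refAa = c("2d" = "E", "2e" = "I", "2g" = "Q",
                                   "3a" = "L", "3b" = "R", "3d" = "I",
                                   "3e" = "G", "3f" = "D", "3g" = "E",
                                   "4a" = "N"),
                         noiseSd = 0.5, seed = 1) {
  set.seed(seed)
  stopifnot(identical(sort(names(refAa)), sort(PSSM_POSITIONS)))
  severity <- c("2d" = 0.5, "2e" = 0.6, "2g" = 0.4, "3a" = 2.2,
                "3b" = 0.5, "3d" = 1.2, "3e" = 1.8, "3f" = 2.5,
                "3g" = 0.6, "4a" = 1.3)
  rows <- lapply(PSSM_POSITIONS, function(p) {
    inten <- exp(-severity[p] + stats::rnorm(20, 0, noiseSd))
    inten[match(refAa[p], AA20)] <- 1.0
    data.frame(position = p, aa = AA20, intensity = inten,
               ref = AA20 == refAa[p], stringsAsFactors = FALSE)
  })
  spotTable(do.call(rbind, rows))
}

#' Generate a synthetic interaction (K_D) table with model Z-scores
#'
#' Emulates a benchmark panel: each peptide is measured against 2-5
#' receptors; each measurement is a binder (K_D < 1 uM), a non-binder
#' (K_D > 10 uM, sometimes censored as a `">"` bound) or an
#' intermediate, with class probabilities matching a roughly balanced
#' binder/non-binder panel. Model Z-scores are drawn unit-variance
#' with mean `zSeparation` for binders and 0 otherwise, so
#' `zSeparation` sets the benchmark separability
#' (AUC = pnorm(zSeparation / sqrt(2))).
#'
#' @param nPeptides Number of peptides (default 128).
#' @param zSeparation Z-score separation between classes (default
#'   1.47, i.e. AUC ~ 0.85).
#' @param receptors Receptor names.
#' @param seed Integer seed.
#' @return List: `records` (peptide, receptor, kdNm, censor),
#'   `zScores` (peptide, receptor, z), `truth` (class per
#'   measurement).
#' @export
simKdTable <- function(nPeptides = 128, zSeparation = 1.47,
                       receptors = RECEPTORS, seed = 1) {
  set.seed(seed)
  rows <- list(); zrows <- list(); trows <- list()
  for (i in seq_len(nPeptides)) {
    pep <- sprintf("pep%03d", i)
    rs <- sample(receptors, sample(2:5, 1))
    cls <- sample(c("binder", "nonbinder", "intermediate"), length(rs),
                  replace = TRUE, prob = c(0.47, 0.42, 0.11))
    kd <- ifelse(cls == "binder", 10^stats::runif(length(rs), 0.3, 2.95),
          ifelse(cls == "nonbinder", 10^stats::runif(length(rs), 4.05, 5.3),
                 10^stats::runif(length(rs), 3.05, 3.95)))
    censor <- ifelse(cls == "nonbinder" & stats::runif(length(rs)) < 0.3,
                     ">", "")
    kd[censor == ">"] <- 10000
    z <- stats::rnorm(length(rs), mean = ifelse(cls == "binder",
                                                zSeparation, 0))
    rows[[i]] <- data.frame(peptide = pep, receptor = rs, kdNm = kd,
                            censor = censor, stringsAsFactors = FALSE)
    zrows[[i]] <- data.frame(peptide = pep, receptor = rs, z = z,
                             stringsAsFactors = FALSE)
    trows[[i]] <- data.frame(peptide = pep, receptor = rs, class = cls,
                             stringsAsFactors = FALSE)
  }
  list(records = do.call(rbind, rows), zScores = do.call(rbind, zrows),
       truth = do.call(rbind, trows))
}

#' Generate scored examples with a target AUC
#'
#' Binormal model: negatives score N(0,1), positives
#' N(sqrt(2) * qnorm(auc), 1), so the expected AUC equals `auc`.
#'
#' @param n Number of examples.
#' @param auc Target AUC.
#' @param prevalence Positive-class probability (default 0.5; classes
#'   are redrawn if one is empty).
#' @param seed Integer seed.
#' @return `data.frame` with columns `score`, `label`.
#' @export
simScoredExamples <- function(n = 200, auc = 0.8, prevalence = 0.5,
                              seed = 1) {
  set.seed(seed)
  repeat {
    label <- stats::runif(n) < prevalence
    if (any(label) && any(!label)) break
  }
  mu <- sqrt(2) * stats::qnorm(auc)
  data.frame(score = stats::rnorm(n, mean = mu * label), label = label)
}

#' Generate a synthetic multiple sequence alignment
#'
#' Columns inside the conserved core carry a consensus residue that
#' each row matches with probability `coreConservation`; all other
#' columns are uniform-random per row.
#'
#' @param nRows,nCols Alignment dimensions.
#' @param coreStart,coreWidth Conserved core location (1-based).
#' @param coreConservation Per-row probability of the consensus
#'   residue inside the core (1 = invariant core).
#' @param seed Integer seed.
#' @return Character matrix (rows = sequences).
#' @export
simMsa <- function(nRows = 12, nCols = 60, coreStart = 25, coreWidth = 12,
                   coreConservation = 1.0, seed = 1) {
  set.seed(seed)
  stopifnot(coreStart >= 1, coreStart + coreWidth - 1 <= nCols)
  m <- matrix(sample(AA20, nRows * nCols, replace = TRUE), nrow = nRows)
  cons <- sample(AA20, coreWidth, replace = TRUE)
  for (k in seq_len(coreWidth)) {
    j <- coreStart + k - 1
    hit <- stats::runif(nRows) < coreConservation
    m[hit, j] <- cons[k]
  }
  m
}

#' Render a structure as PDB-format text
#'
#' @param x A [StructureModel-class].
#' @return Character vector of PDB lines.
#' @export
structureToPdb <- function(x) {
  f <- tempfile(fileext = ".pdb")
  on.exit(unlink(f))
  writeStructure(x, f)
  readLines(f)
}
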