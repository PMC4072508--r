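# Independent brute-force oracles used to cross-check the vectorized
# implementations. These are literal nested loops over residues and
# atoms, kept free of the code paths they check.

euclid <- function(a, b) sqrt(sum((a - b)^2))

oracleResidues <- function(atoms) {
  rt <- unique(atoms[c("chain", "resno", "aa")])
  lapply(seq_len(nrow(rt)), function(i) {
    atoms[atoms$chain == rt$chain[i] & atoms$resno == rt$resno[i], ,
          drop = FALSE]
  })
}

oracleCoord <- function(res, name) {
  i <- match(name, res$elety)
  if (is.na(i)) return(NULL)
  c(res$x[i], res$y[i], res$z[i])
}

oracleCaCb <- function(res) {
  ca <- oracleCoord(res, "CA")
  cb <- oracleCoord(res, "CB")
  if (is.null(cb)) cb <- tryCatch(virtualCbeta(res), error = function(e) NULL)
  if (is.null(ca) || is.null(cb)) return(NULL)
  list(ca = ca, cb = cb)
}

oracleSidechain <- function(res) {
  nm <- bh3scan:::SIDECHAIN_ATOMS[[res$aa[1]]]
  if (!length(nm)) nm <- "CA"
  nm <- nm[nm %in% res$elety]
  lapply(nm, function(a) oracleCoord(res, a))
}

# all-against-all atom-distance loop for the SC criterion
bruteForcePairsSC <- function(template, cutoff = 6) {
  reg <- templateRegister(template)
  out <- NULL
  for (pi in seq_len(nrow(reg))) {
    pres <- template@peptide[template@peptide$resno == reg$resno[pi], ,
                             drop = FALSE]
    rep <- oracleCaCb(pres)
    if (is.null(rep)) next
    for (rres in oracleResidues(template@receptor)) {
      hit <- FALSE
      for (satom in oracleSidechain(rres)) {
        for (patom in rep) {
          if (euclid(satom, patom) < cutoff) hit <- TRUE
        }
      }
      if (hit) {
        out <- rbind(out, data.frame(pepLabel = reg$label[pi],
                                     recResno = rres$resno[1]))
      }
    }
  }
  out
}

# Cbeta-distance + angle-rule loop for the CB criterion
bruteForcePairsCB <- function(template, cutoff = 10, angleRule = TRUE) {
  reg <- templateRegister(template)
  out <- NULL
  for (pi in seq_len(nrow(reg))) {
    pres <- template@peptide[template@peptide$resno == reg$resno[pi], ,
                             drop = FALSE]
    p <- oracleCaCb(pres)
    if (is.null(p)) next
    for (rres in oracleResidues(template@receptor)) {
      r <- oracleCaCb(rres)
      if (is.null(r)) next
      ok <- euclid(p$cb, r$cb) < cutoff
      if (ok && angleRule) {
        d <- r$cb - p$cb
        ok <- sum((p$cb - p$ca) * d) >= 0 && sum((r$cb - r$ca) * -d) >= 0
      }
      if (ok) {
        out <- rbind(out, data.frame(pepLabel = reg$label[pi],
                                     recResno = rres$resno[1]))
      }
    }
  }
  out
}

pairKey <- function(df) {
  if (is.null(df) || !nrow(df)) return(character(0))
  sort(paste(df$pepLabel, df$recResno))
}

# Mann-Whitney pair counting: ties credited 0.5
bruteForceAuc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# literal re-statement of the four compositional rules
bruteForceFilter <- function(seq26) {
  ch <- strsplit(seq26, "")[[1]]
  polar <- sum(ch %in% c("D", "E", "H", "K", "N", "Q", "R", "S", "T")) / 26
  core <- ch[8:19]  # 2d..4a on the 1d-5a register
  polar >= 0.35 &&
    sum(core == "P") <= 1 &&
    ch[12] %in% c("F", "I", "L", "V", "Y", "W", "M") &&
    ch[16] %in% c("A", "C", "G", "S")
}

# minimal hand-built structures for boundary-exact matching tests: a
# one-residue peptide against a single ALA receptor residue, all on
# the x-axis so fingerprint distances are controlled exactly
axisTemplate <- function(recCb = 4.0) {
  atoms <- data.frame(
    chain = c("P", "P", "R", "R"),
    resno = c(1L, 1L, 10L, 10L),
    aa = c("L", "L", "A", "A"),
    elety = c("CA", "CB", "CB", "CA"),
    x = c(0, 1.52, recCb, recCb + 1.5),
    y = 0, z = 0, stringsAsFactors = FALSE)
  s <- new("StructureModel", id = "axis", atoms = atoms)
  buildTemplate(s, "R", "P", anchor = 1L)
}

# hand-computed fingerprint of the axis db pair: distances from the
# peptide-role CA (x=0) and CB (x=1.52) to the receptor-role CB
chainPairsFingerprint <- function(s) {
  a <- structureAtoms(s)
  cbr <- a$x[a$elety == "CB" & a$resno == 2]
  c(cbr - 0, cbr - 1.52)
}

axisDbStructure <- function(recCb = 4.0, pepAa = "L") {
  atoms <- data.frame(
    chain = "A",
    resno = c(1L, 1L, 2L, 2L),
    aa = c(pepAa, pepAa, "A", "A"),
    elety = c("CA", "CB", "CB", "CA"),
    x = c(0, 1.52, recCb, recCb + 1.5),
    y = 0, z = 0, stringsAsFactors = FALSE)
  new("StructureModel", id = "axisdb", atoms = atoms)
}
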