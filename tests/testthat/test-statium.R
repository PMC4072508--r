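# Pair detection, fingerprint matching, count collection and the
# derived statistical potential.

test_that("SC detection respects the 6 A side-chain cutoff", {
  near <- simComplex(contacts = data.frame(label = "3a", aa = "F",
                                           approach = 5.9),
                     verify = FALSE)
  far <- simComplex(contacts = data.frame(label = "3a", aa = "F",
                                          approach = 6.1),
                    verify = FALSE)
  expect_equal(nrow(detectPairs(near$template)), 1)
  expect_equal(nrow(detectPairs(far$template)), 0)
})

test_that("detection equals the brute-force atom-distance loop (both variants)", {
  for (seed in 1:8) {
    cx <- simRandomComplex(seed = seed)
    sc <- detectPairs(cx$template, interactionCriterion("SC"))
    expect_equal(pairKey(data.frame(pepLabel = sc$pepLabel,
                                    recResno = sc$recResno)),
                 pairKey(bruteForcePairsSC(cx$template)))
    cb <- detectPairs(cx$template, interactionCriterion("CB"))
    expect_equal(pairKey(data.frame(pepLabel = cb$pepLabel,
                                    recResno = cb$recResno)),
                 pairKey(bruteForcePairsCB(cx$template)))
  }
})

test_that("fingerprint RMSD matches hand computations and errors on length", {
  expect_equal(fingerprintRmsd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(fingerprintRmsd(c(1, 2, 3, 4), c(1, 2, 3, 4.8)), 0.4)
  expect_error(fingerprintRmsd(1:4, 1:6), "length")
})

test_that("fingerprint RMSD is a metric on sampled triples", {
  set.seed(42)
  for (i in 1:20) {
    a <- runif(6, 0, 10); b <- runif(6, 0, 10); c <- runif(6, 0, 10)
    expect_equal(fingerprintRmsd(a, b), fingerprintRmsd(b, a))
    expect_gte(fingerprintRmsd(a, b), 0)
    expect_lte(fingerprintRmsd(a, c),
               fingerprintRmsd(a, b) + fingerprintRmsd(b, c) + 1e-12)
  }
})

test_that("a geometric self-copy in the database matches at RMSD 0", {
  tpl <- axisTemplate(recCb = 4.0)
  pairs <- detectPairs(tpl)
  expect_equal(nrow(pairs), 1)
  counts <- scanDatabase(pairs, list(axisDbStructure(recCb = 4.0, pepAa = "L")))
  expect_equal(unname(counts[1, "L"]), 1L)
})

test_that("receptor-side amino-acid identity is required regardless of geometry", {
  tpl <- axisTemplate(recCb = 4.0)
  pairs <- detectPairs(tpl)
  # same geometry but the receptor-role residue is VAL, template is ALA
  db <- axisDbStructure(recCb = 4.0, pepAa = "L")
  a <- structureAtoms(db)
  a$aa[a$resno == 2] <- "V"
  db@atoms <- a
  counts <- scanDatabase(pairs, list(db))
  expect_equal(sum(counts), 0)
})

test_that("planted database counts reproduce the generator bookkeeping", {
  cx <- simComplex()
  sim <- simStructureDb(cx$template, n = 50,
                        preferences = list("3a" = c(A = 0.8, G = 0.2)),
                        exactCounts = TRUE, seed = 5)
  pairs <- detectPairs(cx$template)
  counts <- scanDatabase(pairs, sim$db)
  i <- which(pairs$pepLabel == "3a")
  expect_equal(unname(counts[i, "A"]), 40L)
  expect_equal(unname(counts[i, "G"]), 10L)
  # truth table agrees
  tt <- table(sim$truth$aa[sim$truth$pepLabel == "3a"])
  expect_equal(as.integer(tt[c("A", "G")]), c(40L, 10L))
})

test_that("decreasing the fingerprint cutoff never increases counts", {
  cx <- simComplex()
  sim <- simStructureDb(cx$template, n = 20, jitterSd = 0.15, seed = 9)
  pairs <- detectPairs(cx$template)
  cuts <- c(1.0, 0.7, 0.4, 0.2)
  prev <- NULL
  for (ct in cuts) {
    crit <- interactionCriterion("SC", fingerprintRmsdCutoff = ct)
    counts <- scanDatabase(pairs, sim$db, crit)
    if (!is.null(prev)) expect_true(all(counts <= prev))
    prev <- counts
  }
})

test_that("potential energies follow the log-ratio formula", {
  tpl <- axisTemplate()
  pairs <- detectPairs(tpl)
  bg <- uniformBackground()
  # counts proportional to background -> E = 0 everywhere
  counts <- matrix(5L, nrow = 1, ncol = 20, dimnames = list(NULL, AA20))
  m <- derivePotential(pairs, counts, bg, pseudocountMass = 0)
  expect_equal(unname(pairEnergies(m)[1, ]), rep(0, 20))
  # P = 0.20 vs bg = 0.05 -> E = -ln 4
  bg2 <- setNames(rep(0.05, 20), AA20)
  bg2["L"] <- 1 - 0.05 * 19
  counts2 <- matrix(0L, 1, 20, dimnames = list(NULL, AA20))
  counts2[1, "A"] <- 20L; counts2[1, "G"] <- 80L
  m2 <- derivePotential(pairs, counts2, bg2, pseudocountMass = 0)
  expect_equal(unname(pairEnergies(m2)[1, "A"]), -log(0.20 / 0.05))
  # zero count with pseudocounts -> finite positive energy
  m3 <- derivePotential(pairs, counts2, uniformBackground(),
                        pseudocountMass = 20)
  expect_true(is.finite(pairEnergies(m3)[1, "W"]))
  expect_gt(pairEnergies(m3)[1, "W"], 0)
  # frequencies sum to 1 after pseudocounts
  p <- (counts2 + 20 / 20) / (rowSums(counts2) + 20)
  expect_equal(sum(p), 1)
  # zero totals without pseudocounts are an error
  zero <- matrix(0L, 1, 20, dimnames = list(NULL, AA20))
  expect_error(derivePotential(pairs, zero, bg, pseudocountMass = 0), "zero")
})

test_that("planted preference ratios are recovered as energy differences", {
  cx <- simComplex()
  ratio <- 3
  sim <- simStructureDb(cx$template, n = 120,
                        preferences = list("3f" = c(D = 0.75, N = 0.25)),
                        exactCounts = TRUE, seed = 2)
  pairs <- detectPairs(cx$template)
  counts <- scanDatabase(pairs, sim$db)
  m <- derivePotential(pairs, counts, uniformBackground(),
                       pseudocountMass = 0)
  i <- which(pairs$pepLabel == "3f")
  expect_equal(unname(pairEnergies(m)[i, "D"] - pairEnergies(m)[i, "N"]),
               -log(ratio), tolerance = 1e-9)
  # and the dominant residue is the position argmin
  expect_equal(AA20[which.min(positionEnergies(m)[, "3f"])], "D")
})

test_that("peptide scores are additive over positions and pairs", {
  cx <- simComplex()
  sim <- simStructureDb(cx$template, n = 40, seed = 8)
  pairs <- detectPairs(cx$template)
  m <- derivePotential(pairs, scanDatabase(pairs, sim$db))
  set.seed(1)
  win <- paste(sample(AA20, 26, replace = TRUE), collapse = "")
  total <- scoreStatium(m, win)
  posE <- positionEnergies(m)
  reg <- registerLabels("1d", "5a")
  ch <- strsplit(win, "")[[1]]
  manual <- sum(vapply(colnames(posE), function(l) {
    posE[ch[registerIndex(l, reg)], l]
  }, numeric(1)))
  expect_equal(total, manual)
  # per-position argmin sequence attains the additive minimum
  best <- ch
  for (l in colnames(posE)) best[registerIndex(l, reg)] <- AA20[which.min(posE[, l])]
  expect_lte(scoreStatium(m, paste(best, collapse = "")), total)
})

test_that("windows that do not cover the model positions are rejected", {
  cx <- simComplex()
  sim <- simStructureDb(cx$template, n = 5, seed = 4)
  pairs <- detectPairs(cx$template)
  m <- derivePotential(pairs, scanDatabase(pairs, sim$db))
  expect_error(scoreStatium(m, "AAAAA", register = registerLabels("3a", "3e")),
               "cover|length")
  expect_error(scoreStatium(m, "SHORT"), "length")
})

test_that("empty databases give zero counts with a warning", {
  tpl <- axisTemplate()
  pairs <- detectPairs(tpl)
  expect_warning(counts <- scanDatabase(pairs, list()), "empty")
  expect_equal(sum(counts), 0)
})
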