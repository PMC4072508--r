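# K_D labeling, specificity comparisons, ROC/AUC and the bootstrap.

test_that("affinity labels follow the 1 uM / 10 uM cutoffs", {
  rec <- data.frame(peptide = c("a", "b", "c"), receptor = "Mcl-1",
                    kdNm = c(500, 5000, 20000))
  lab <- labelAffinity(rec)
  expect_equal(lab$label[lab$peptide == "a"], "binder")
  expect_false("b" %in% lab$peptide)          # intermediate excluded
  expect_equal(lab$label[lab$peptide == "c"], "nonbinder")
  # boundary values fall in the excluded zone (strict inequalities)
  bound <- data.frame(peptide = c("x", "y"), receptor = "Bfl-1",
                      kdNm = c(1000, 10000))
  expect_equal(nrow(labelAffinity(bound)), 0)
})

test_that("censored measurements are honoured", {
  rec <- data.frame(peptide = c("a", "b", "c", "d"), receptor = "Bcl-xL",
                    kdNm = c(10000, 5000, 1, 5000),
                    censor = c(">", ">", "<", "<"))
  lab <- labelAffinity(rec)
  expect_equal(lab$label[lab$peptide == "a"], "nonbinder")  # >10 uM
  expect_false("b" %in% lab$peptide)  # >5 uM establishes nothing
  expect_equal(lab$label[lab$peptide == "c"], "binder")     # <1 nM
  expect_false("d" %in% lab$peptide)
})

test_that("labeling is idempotent", {
  sim <- simKdTable(nPeptides = 30, seed = 4)
  l1 <- labelAffinity(sim$records)
  l2 <- labelAffinity(l1)
  expect_equal(l1$label, l2$label)
  expect_equal(nrow(l1), nrow(l2))
})

test_that("K_D tables parse censor prefixes from TSV", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("peptide\treceptor\tkd_nm",
               "a\tMcl-1\t250", "b\tMcl-1\t>10000", "c\tMcl-1\t<1"), f)
  d <- readKdTable(f)
  expect_equal(d$censor, c("", ">", "<"))
  lab <- labelAffinity(d)
  expect_equal(sort(lab$label), c("binder", "binder", "nonbinder"))
})

test_that("specificity comparisons enumerate (bound, unbound) pairs", {
  rec <- data.frame(
    peptide = c("p", "p", "q", "q", "r", "r", "r"),
    receptor = c("Mcl-1", "Bcl-xL", "Mcl-1", "Bcl-xL", "Mcl-1", "Bcl-xL", "Bfl-1"),
    kdNm = c(100, 20000, 100, 200, 100, 20000, 30000))
  cmp <- buildSpecificity(rec)
  expect_equal(nrow(cmp[cmp$peptide == "p", ]), 1)
  expect_equal(cmp$receptorBound[cmp$peptide == "p"], "Mcl-1")
  expect_equal(cmp$receptorUnbound[cmp$peptide == "p"], "Bcl-xL")
  expect_equal(nrow(cmp[cmp$peptide == "q", ]), 0)  # binds both
  expect_equal(nrow(cmp[cmp$peptide == "r", ]), 2)  # 1 bound x 2 unbound
})

test_that("ROC/AUC handles separation, the worked 4-example case and ties", {
  perfect <- rocAuc(c(5, 4, 1, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(aucValue(perfect), 1)
  worked <- rocAuc(c(3, 2, 1, 0), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(aucValue(worked), 0.75)
  ties <- rocAuc(rep(1, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(aucValue(ties), 0.5)
  expect_error(rocAuc(1:3, c(TRUE, TRUE, TRUE)), "positive and.*negative")
})

test_that("ROC points are monotone and anchored at (0,0) and (1,1)", {
  set.seed(13)
  r <- rocAuc(rnorm(50), runif(50) > 0.5)
  p <- rocPoints(r)
  expect_equal(p$fpr[1], 0); expect_equal(p$tpr[1], 0)
  expect_equal(p$fpr[nrow(p)], 1); expect_equal(p$tpr[nrow(p)], 1)
  expect_true(all(diff(p$fpr) >= 0) && all(diff(p$tpr) >= 0))
})

test_that("AUC equals Mann-Whitney pair counting on random inputs", {
  set.seed(14)
  for (k in 1:10) {
    n <- sample(10:200, 1)
    scores <- round(rnorm(n), sample(0:2, 1))  # rounding induces ties
    labels <- runif(n) > 0.4
    if (!any(labels) || all(labels)) next
    expect_equal(aucValue(rocAuc(scores, labels)),
                 bruteForceAuc(scores, labels))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  scores <- rnorm(150); labels <- runif(150) > 0.5
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                         direction = "<"))))
  expect_equal(aucValue(rocAuc(scores, labels)), ref)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(16)
  scores <- rnorm(80); labels <- runif(80) > 0.5
  a0 <- aucValue(rocAuc(scores, labels))
  expect_equal(aucValue(rocAuc(exp(scores), labels)), a0)
  expect_equal(aucValue(rocAuc(scores * 3 - 10, labels)), a0)
})

test_that("the bootstrap is deterministic under a seed", {
  ex <- simScoredExamples(n = 60, auc = 0.8, seed = 17)
  ci1 <- bootstrapAucCi(ex$score, ex$label, nResamples = 200, seed = 99)
  ci2 <- bootstrapAucCi(ex$score, ex$label, nResamples = 200, seed = 99)
  expect_identical(ci1, ci2)
  expect_lt(ci1[1], ci1[2])
})

test_that("perfect separation gives a degenerate interval at 1", {
  scores <- c(rep(10, 40), rep(0, 40))
  labels <- c(rep(TRUE, 40), rep(FALSE, 40))
  ci <- bootstrapAucCi(scores, labels, nResamples = 100, seed = 1)
  expect_equal(ci, c(1, 1))
})

test_that("bootstrap intervals shrink as the sample grows", {
  widths <- vapply(c(50, 200, 800), function(n) {
    ex <- simScoredExamples(n = n, auc = 0.8, seed = 18)
    ci <- bootstrapAucCi(ex$score, ex$label, nResamples = 300, seed = 18)
    ci[2] - ci[1]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("specificity ROC scores preference by Z-score differences", {
  cmp <- data.frame(peptide = c("p", "q"),
                    receptorBound = c("Mcl-1", "Mcl-1"),
                    receptorUnbound = c("Bcl-xL", "Bcl-xL"))
  z <- data.frame(peptide = rep(c("p", "q"), each = 2),
                  receptor = rep(c("Mcl-1", "Bcl-xL"), 2),
                  z = c(3, 1, 0.5, 1.5))  # deltas +2, -1
  r <- specificityRoc(cmp, z)
  expect_equal(aucValue(r),
               bruteForceAuc(c(2, -1, -2, 1), c(TRUE, TRUE, FALSE, FALSE)))
  big <- data.frame(peptide = rep(c("p", "q"), each = 2),
                    receptor = rep(c("Mcl-1", "Bcl-xL"), 2),
                    z = c(5, 0, 4, -1))   # all deltas large positive
  expect_equal(aucValue(specificityRoc(cmp, big)), 1)
  expect_error(specificityRoc(cmp[0, ], z), "no specificity")
  # missing Z-scores drop the comparison with a warning
  expect_warning(r2 <- specificityRoc(cmp, z[z$peptide == "p", ]), "dropped")
  expect_equal(r2@nPos, 1L)
})
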