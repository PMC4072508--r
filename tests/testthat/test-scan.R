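# Window enumeration, compositional filtering, Z-scores and candidate
# selection.

test_that("window enumeration counts follow length - 26 + 1", {
  expect_equal(nrow(enumerateWindows(c(p = strrep("A", 26)))), 1)
  expect_equal(nrow(enumerateWindows(c(p = strrep("A", 30)))), 5)
  expect_equal(nrow(enumerateWindows(c(p = strrep("A", 25)))), 0)
  w <- enumerateWindows(c(a = strrep("A", 30), b = strrep("C", 27)))
  expect_equal(table(w$protein), table(c(rep("a", 5), rep("b", 2))),
               ignore_attr = TRUE)
  expect_equal(w$start[w$protein == "a"], 0:4)
})

test_that("windows with non-standard characters are skipped with a warning", {
  expect_warning(w <- enumerateWindows(c(p = paste0("X", strrep("A", 26)))),
                 "skipped")
  expect_equal(nrow(w), 1)  # only the X-free window survives
})

test_that("the four compositional rules are enforced", {
  base <- strsplit(strrep("E", 26), "")[[1]]
  base[12] <- "L"; base[16] <- "A"  # 3a, 3e
  ok <- paste(base, collapse = "")
  expect_true(compositionFilter(ok))
  twoPro <- base; twoPro[9] <- "P"; twoPro[18] <- "P"  # both inside 2d-4a
  expect_false(compositionFilter(paste(twoPro, collapse = "")))
  onePro <- base; onePro[9] <- "P"
  expect_true(compositionFilter(paste(onePro, collapse = "")))
  d3a <- base; d3a[12] <- "D"
  expect_false(compositionFilter(paste(d3a, collapse = "")))
  big3e <- base; big3e[16] <- "W"
  expect_false(compositionFilter(paste(big3e, collapse = "")))
  apolar <- base; apolar[-c(12, 16)] <- "A"   # polar fraction 0
  expect_false(compositionFilter(paste(apolar, collapse = "")))
})

test_that("a 46%-polar window with L/A at 3a/3e passes rule by rule", {
  ch <- rep("A", 26)
  ch[seq(1, 23, by = 2)] <- "D"   # 12 polar residues = 46%
  ch[12] <- "L"; ch[16] <- "A"    # odd positions avoid 3a (12) and 3e (16)
  seq <- paste(ch, collapse = "")
  expect_equal(sum(ch %in% c("D","E","H","K","N","Q","R","S","T")) / 26,
               12 / 26)
  expect_true(compositionFilter(seq))
})

test_that("filter counts equal a brute-force restatement of the rules", {
  set.seed(10)
  seqs <- vapply(1:400, function(i) {
    paste(sample(AA20, 26, replace = TRUE,
                 prob = bh3scan:::AA_FREQS), collapse = "")
  }, "")
  expect_equal(compositionFilter(seqs),
               vapply(seqs, bruteForceFilter, logical(1), USE.NAMES = FALSE))
})

test_that("background fitting gives sample moments and rejects degenerates", {
  bg <- fitBackground(c(0, 2))
  expect_equal(bg$mean, 1)
  expect_equal(bg$sd, sqrt(2))
  expect_error(fitBackground(3), "at least 2")
  expect_error(fitBackground(rep(1, 5)), "identical")
  set.seed(3)
  x <- rnorm(1e5, mean = -4, sd = 2.5)
  bg2 <- fitBackground(x)
  expect_equal(bg2$mean, -4, tolerance = 0.01 * 4)
  expect_equal(bg2$sd, 2.5, tolerance = 0.01 * 2.5)
})

test_that("Z-scores flip the energy orientation", {
  bg <- fitBackground(c(0, 2, 4, 6))
  expect_equal(zScore(bg$mean, bg), 0)
  expect_equal(zScore(bg$mean - 2 * bg$sd, bg), 2)
  expect_equal(zScore(bg$mean + bg$sd, bg), -1)
  # strictly decreasing in the raw energy
  x <- seq(-5, 5, length.out = 11)
  expect_true(all(diff(zScore(x, bg)) < 0))
})

test_that("background windows standardize to mean 0, sd 1", {
  set.seed(8)
  raw <- rnorm(5000, 10, 3)
  bg <- fitBackground(raw)
  z <- zScore(raw, bg)
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sd(z), 1, tolerance = 1e-10)
})

test_that("combined Z-scores average and stay between their arguments", {
  expect_equal(combineZ(2, 4), 3)
  expect_equal(combineZ(1.3, 1.3), 1.3)
  expect_equal(combineZ(-1, 3), 1)
  expect_error(combineZ(NA, 1), "present")
  set.seed(2)
  a <- rnorm(50); b <- rnorm(50)
  z <- combineZ(a, b)
  expect_true(all(z >= pmin(a, b) & z <= pmax(a, b)))
})

test_that("redundancy filtering keeps the best of similar sequences", {
  s1 <- strrep("A", 26)
  s2 <- s1  # identical
  s3 <- paste(rev(strsplit(paste(rep(c("D","E"), 13), collapse = ""), "")[[1]]),
              collapse = "")  # unrelated
  cand <- data.frame(sequence = c(s1, s2, s3), stringsAsFactors = FALSE)
  kept <- redundancyFilter(cand, score = c(1, 2, 0.5))
  expect_equal(nrow(kept), 2)
  expect_equal(kept$sequence[1], s2)  # the better-scoring duplicate
  expect_true(s3 %in% kept$sequence)
})

test_that("greedy chain semantics keep the ends of a similarity chain", {
  a <- strrep("A", 26)
  b <- paste0(strrep("A", 20), strrep("C", 6))    # 77% identical to a
  c <- paste0(strrep("A", 14), strrep("C", 12))   # 77% to b, 54% to a
  cand <- data.frame(sequence = c(a, b, c), stringsAsFactors = FALSE)
  kept <- redundancyFilter(cand, score = c(3, 2, 1))
  expect_setequal(kept$sequence, c(a, c))
})

test_that("candidate selection applies cutoff, sign rule and top-k", {
  set.seed(6)
  n <- 60
  w <- data.frame(sequence = vapply(1:n, function(i)
                    paste(sample(AA20, 26, TRUE), collapse = ""), ""),
                  pssmZ = runif(n, 0, 4),
                  statiumScRaw = runif(n, -5, 2))
  w$statiumScZ <- -w$statiumScRaw
  none <- selectCandidates(w, pssmZCutoff = 99)
  expect_equal(nrow(none), 0)
  sel <- selectCandidates(w, pssmZCutoff = 0, topK = 20)
  expect_equal(nrow(sel), 20)
  expect_true(all(diff(sel$statiumScZ) <= 0))
  expect_true(all(sel$statiumScRaw < 0))
  wpos <- w; wpos$statiumScRaw <- abs(wpos$statiumScRaw)
  expect_equal(nrow(selectCandidates(wpos, pssmZCutoff = 0)), 0)
  # 30 eligible -> exactly 20 returned in score order
  w30 <- w[w$statiumScRaw < 0, ][1:min(30, sum(w$statiumScRaw < 0)), ]
  sel30 <- selectCandidates(w30, pssmZCutoff = -Inf, topK = 20)
  expect_equal(nrow(sel30), min(20, nrow(w30)))
})

test_that("planted motifs pass the filter and dominate the combined Z ranking", {
  cx <- simComplex()
  sim <- simStructureDb(cx$template, n = 40, preferences = list(
    "2d" = c(F = 0.7, L = 0.3), "3a" = c(L = 0.8, I = 0.2),
    "3e" = c(G = 0.7, A = 0.3), "3f" = c(D = 0.8, E = 0.2),
    "4a" = c(I = 0.6, V = 0.4)), seed = 21)
  pairs <- detectPairs(cx$template)
  sm <- derivePotential(pairs, scanDatabase(pairs, sim$db))
  pm <- buildPssm(simSpotTable(seed = 21))
  cons <- consensusWindow(sm, pm)
  expect_true(compositionFilter(cons))
  pr <- simProteome(nProteins = 60, proteinLength = 400,
                    plantSequence = cons, nPlanted = 5, seed = 22)
  res <- scanProteome(pr$proteome, sm, pm)
  key <- paste(pr$truth$protein, pr$truth$start)
  hit <- match(key, paste(res$protein, res$start))
  expect_false(anyNA(hit))  # all planted windows pass the filter
  r <- rank(-res$combinedZ)[hit]
  expect_true(all(r / nrow(res) <= 0.01))
  expect_gt(nrow(res), 500)
})
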