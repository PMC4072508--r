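# Proteome scanning on the heptad register.
#
# Every protein is scanned in sliding 26-residue windows (extended
# register 1d-5a, whose last 23 residues are the 1g-5a scoring core).
# Windows are filtered for the compositional profile of known BH3
# motifs, scored with the statistical-potential and SPOT-derived
# models, and standardized to Z-scores against the distribution of
# scores over all filtered windows ("genomic" background).

#' Compositional filter configuration
#'
#' Defaults encode the BH3 compositional profile: at least 35%
#' polar/charged residues (DEHKNQRST) over the 26-mer, at most one
#' proline between positions 2d and 4a, a nonpolar residue at 3a
#' (FILVYWM) and a small residue at 3e (ACGS).
#'
#' @param polarSet,polarMinFraction,maxProlineCore,pos3aSet,pos3eSet
#'   Filter parameters; see Details above.
#' @return A list with class `"FilterConfig"`.
#' @export
filterConfig <- function(polarSet = c("D", "E", "H", "K", "N", "Q", "R", "S", "T"),
                         polarMinFraction = 0.35,
                         maxProlineCore = 1,
                         pos3aSet = c("F", "I", "L", "V", "Y", "W", "M"),
                         pos3eSet = c("A", "C", "G", "S")) {
  stopifnot(polarMinFraction >= 0, polarMinFraction <= 1)
  structure(list(polarSet = polarSet, polarMinFraction = polarMinFraction,
                 maxProlineCore = maxProlineCore,
                 pos3aSet = pos3aSet, pos3eSet = pos3eSet),
            class = "FilterConfig")
}

#' Enumerate candidate windows of a proteome
#'
#' Every contiguous 26-mer of every protein, at step 1. Proteins
#' shorter than 26 residues yield no windows; windows containing
#' non-standard characters are skipped with a warning.
#'
#' @param proteome Named character vector of protein sequences, or a
#'   `Biostrings::AAStringSet`.
#' @return `data.frame` with columns `protein`, `start` (0-based
#'   offset) and `sequence` (the 26-mer).
#' @export
enumerateWindows <- function(proteome) {
  if (inherits(proteome, "XStringSet")) {
    proteome <- setNames(as.character(proteome), names(proteome))
  }
  if (is.null(names(proteome))) {
    names(proteome) <- paste0("protein", seq_along(proteome))
  }
  w <- 26L
  pieces <- lapply(seq_along(proteome), function(i) {
    s <- proteome[[i]]
    n <- nchar(s)
    if (n < w) return(NULL)
    starts <- seq_len(n - w + 1L)
    data.frame(protein = names(proteome)[i], start = starts - 1L,
               sequence = substring(s, starts, starts + w - 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(protein = character(0), start = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  }
  ok <- !grepl(paste0("[^", paste(AA20, collapse = ""), "]"), out$sequence)
  if (any(!ok)) {
    warning(sum(!ok), " window(s) with non-standard characters skipped")
    out <- out[ok, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Apply the compositional filter to windows
#'
#' @param sequences Character vector of 26-mers on the 1d-5a register.
#' @param cfg A [filterConfig()].
#' @return Logical vector: `TRUE` for windows passing all four rules.
#' @export
compositionFilter <- function(sequences, cfg = filterConfig()) {
  stopifnot(all(nchar(sequences) == 26))
  reg <- registerLabels("1d", "5a")
  i3a <- registerIndex("3a", reg)
  i3e <- registerIndex("3e", reg)
  core <- registerIndex("2d", reg):registerIndex("4a", reg)
  ch <- matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
               nrow = 26)
  polar <- colSums(matrix(ch %in% cfg$polarSet, nrow = 26)) / 26
  prolines <- colSums(matrix(ch[core, , drop = FALSE] == "P",
                             nrow = length(core)))
  polar >= cfg$polarMinFraction &
    prolines <= cfg$maxProlineCore &
    ch[i3a, ] %in% cfg$pos3aSet &
    ch[i3e, ] %in% cfg$pos3eSet
}

#' Fit a background score distribution
#'
#' @param scores Numeric vector of raw scores of background windows.
#' @return List (`mean`, `sd`, `n`) with class
#'   `"BackgroundDistribution"`.
#' @export
fitBackground <- function(scores) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 2) stop("need at least 2 scores to fit a background")
  s <- stats::sd(scores)
  if (s == 0) stop("background scores are all identical (sd = 0)")
  structure(list(mean = mean(scores), sd = s, n = length(scores)),
            class = "BackgroundDistribution")
}

#' Genomic Z-score of a raw energy
#'
#' Raw model scores are energies (lower = stronger predicted binding),
#' so the Z-score is sign-flipped: \eqn{Z = (\mu - x)/\sigma}. Higher
#' Z means better predicted binding, and "Z better than 2" reads as
#' `Z >= 2`.
#'
#' @param raw Raw energy score(s).
#' @param bg A [fitBackground()] result.
#' @return Numeric Z-score(s).
#' @export
zScore <- function(raw, bg) {
  stopifnot(inherits(bg, "BackgroundDistribution"))
  (bg$mean - raw) / bg$sd
}

#' Combine model Z-scores for the same receptor
#'
#' @param zPssm,zStatiumSc Z-scores of the two models.
#' @return Their arithmetic mean.
#' @export
combineZ <- function(zPssm, zStatiumSc) {
  if (anyNA(zPssm) || anyNA(zStatiumSc)) {
    stop("both Z-scores must be present to combine")
  }
  (zPssm + zStatiumSc) / 2
}

#' Remove near-duplicate candidate windows
#'
#' Greedy by descending score: a candidate is dropped when its
#' ungapped fractional identity to an already-kept candidate exceeds
#' the threshold, so only the best-scoring representative of each
#' similarity group is tested.
#'
#' @param candidates `data.frame` with a `sequence` column of
#'   equal-length windows.
#' @param score Numeric vector, higher = better (e.g. a Z-score).
#' @param identityThreshold Drop above this fractional identity
#'   (default 0.75).
#' @return The kept rows of `candidates`, in descending score order.
#' @export
redundancyFilter <- function(candidates, score, identityThreshold = 0.75) {
  stopifnot(nrow(candidates) == length(score))
  if (!nrow(candidates)) return(candidates)
  ord <- order(score, decreasing = TRUE)
  seqs <- candidates$sequence[ord]
  n <- nchar(seqs[1])
  ch <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
               nrow = n)
  kept <- integer(0)
  for (i in seq_along(seqs)) {
    dup <- FALSE
    for (k in kept) {
      if (mean(ch[, i] == ch[, k]) > identityThreshold) { dup <- TRUE; break }
    }
    if (!dup) kept <- c(kept, i)
  }
  candidates[ord[kept], , drop = FALSE]
}

#' Select candidates for array testing
#'
#' Applies the selection rule used to design the final array: keep
#' windows whose SPOT-model Z-score meets the receptor's cutoff,
#' optionally require the raw statistical-potential energy to be
#' negative, rank by the statistical-potential Z-score and keep the
#' top `topK`.
#'
#' @param windows `data.frame` with columns `pssmZ`, `statiumScZ` and
#'   `statiumScRaw`.
#' @param pssmZCutoff Minimum SPOT-model Z-score.
#' @param topK Number of candidates to keep (default 20).
#' @param requireRawScNegative Require `statiumScRaw < 0`
#'   (default `TRUE`).
#' @return The selected rows, ranked by `statiumScZ` descending.
#' @export
selectCandidates <- function(windows, pssmZCutoff, topK = 20,
                             requireRawScNegative = TRUE) {
  keep <- windows$pssmZ >= pssmZCutoff
  if (requireRawScNegative) keep <- keep & windows$statiumScRaw < 0
  out <- windows[keep, , drop = FALSE]
  out <- out[order(out$statiumScZ, decreasing = TRUE), , drop = FALSE]
  utils::head(out, topK)
}

#' Scan a proteome with a statistical-potential and a SPOT model
#'
#' Full pipeline: enumerate 26-residue windows, apply the
#' compositional filter, score the filtered windows with both models,
#' standardize each model's scores against the filtered-window
#' distribution and add the combined Z-score.
#'
#' @param proteome Named character vector or `AAStringSet`.
#' @param statiumModel A [StatiumModel-class].
#' @param pssmModel A [PssmModel-class].
#' @param cfg A [filterConfig()].
#' @return `data.frame` of filtered windows with raw scores, Z-scores
#'   and `combinedZ`.
#' @export
scanProteome <- function(proteome, statiumModel, pssmModel,
                         cfg = filterConfig()) {
  win <- enumerateWindows(proteome)
  win <- win[compositionFilter(win$sequence, cfg), , drop = FALSE]
  if (!nrow(win)) return(win)
  win$statiumScRaw <- scoreStatium(statiumModel, win$sequence)
  win$pssmRaw <- scorePssm(pssmModel, win$sequence)
  bgS <- fitBackground(win$statiumScRaw)
  bgP <- fitBackground(win$pssmRaw)
  win$statiumScZ <- zScore(win$statiumScRaw, bgS)
  win$pssmZ <- zScore(win$pssmRaw, bgP)
  win$combinedZ <- combineZ(win$pssmZ, win$statiumScZ)
  rownames(win) <- NULL
  win
}
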