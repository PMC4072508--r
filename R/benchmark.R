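# Affinity and specificity benchmarks.
#
# Dissociation constants define the classes: binders have K_D < 1 uM,
# non-binders K_D > 10 uM; measurements in between are excluded.
# Models are compared by ROC/AUC with percentile-bootstrap confidence
# intervals (2000 resamples, 90% interval by default).

RECEPTORS <- c("Bcl-xL", "Bcl-w", "Bcl-2", "Mcl-1", "Bfl-1")

#' Label interaction records as binders and non-binders
#'
#' Binder: K_D below `strongCutoffNm`; non-binder: K_D above
#' `nonCutoffNm`; intermediate affinities are excluded. Censored
#' values are honoured: a `">"` record (lower bound) is a non-binder
#' only when its bound is at or above `nonCutoffNm`, a `"<"` record
#' (upper bound) a binder only when its bound is at or below
#' `strongCutoffNm`.
#'
#' @param records `data.frame` with columns `peptide`, `receptor`,
#'   `kdNm` (numeric, nM) and optionally `censor` (one of `""`, `">"`,
#'   `"<"`).
#' @param strongCutoffNm Binder cutoff (default 1000 nM = 1 uM).
#' @param nonCutoffNm Non-binder cutoff (default 10000 nM = 10 uM).
#' @return `records` restricted to labelable rows, with a `label`
#'   column (`"binder"` / `"nonbinder"`).
#' @export
labelAffinity <- function(records, strongCutoffNm = 1000,
                          nonCutoffNm = 10000) {
  stopifnot(all(c("peptide", "receptor", "kdNm") %in% names(records)))
  censor <- if ("censor" %in% names(records)) records$censor else ""
  censor[is.na(censor)] <- ""
  binder <- (censor == "" & records$kdNm < strongCutoffNm) |
    (censor == "<" & records$kdNm <= strongCutoffNm)
  nonbinder <- (censor == "" & records$kdNm > nonCutoffNm) |
    (censor == ">" & records$kdNm >= nonCutoffNm)
  out <- records[binder | nonbinder, , drop = FALSE]
  out$label <- ifelse(binder[binder | nonbinder], "binder", "nonbinder")
  rownames(out) <- NULL
  out
}

#' Read an interaction (K_D) table from TSV
#'
#' Expects columns `peptide`, `receptor`, `kd_nm`; values like
#' `">10000"` are parsed into a numeric bound plus a censor flag.
#'
#' @param file Path to the TSV file.
#' @return `data.frame` with columns `peptide`, `receptor`, `kdNm`,
#'   `censor`.
#' @export
readKdTable <- function(file) {
  d <- utils::read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("peptide", "receptor", "kd_nm") %in% names(d)))
  raw <- as.character(d$kd_nm)
  censor <- ifelse(grepl("^>", raw), ">", ifelse(grepl("^<", raw), "<", ""))
  kd <- as.numeric(sub("^[<>]", "", raw))
  if (any(is.na(kd) | kd <= 0)) stop("K_D values must be positive numbers")
  data.frame(peptide = d$peptide, receptor = d$receptor,
             kdNm = kd, censor = censor, stringsAsFactors = FALSE)
}

#' Enumerate specificity comparisons
#'
#' One comparison per ordered (bound, unbound) receptor pair of the
#' same peptide, where the peptide binds one receptor (K_D < 1 uM) but
#' not the other (K_D > 10 uM).
#'
#' @param records As for [labelAffinity()].
#' @inheritParams labelAffinity
#' @return `data.frame` with columns `peptide`, `receptorBound`,
#'   `receptorUnbound`.
#' @export
buildSpecificity <- function(records, strongCutoffNm = 1000,
                             nonCutoffNm = 10000) {
  lab <- labelAffinity(records, strongCutoffNm, nonCutoffNm)
  rows <- lapply(split(lab, lab$peptide), function(d) {
    bound <- d$receptor[d$label == "binder"]
    unbound <- d$receptor[d$label == "nonbinder"]
    if (!length(bound) || !length(unbound)) return(NULL)
    expand.grid(peptide = d$peptide[1], receptorBound = bound,
                receptorUnbound = unbound, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(peptide = character(0), receptorBound = character(0),
                      receptorUnbound = character(0))
  }
  rownames(out) <- NULL
  out
}

#' ROC curve and AUC
#'
#' Sweeps all score thresholds (ties grouped), with the true positive
#' rate TP/(TP+FN) against the false positive rate FP/(FP+TN). The
#' AUC is the trapezoidal area, which equals the Mann-Whitney rank
#' statistic with ties credited 0.5.
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Logical (or coercible) class labels, `TRUE` =
#'   positive.
#' @return A [RocResult-class].
#' @examples
#' aucValue(rocAuc(c(3, 2, 1, 0), c(TRUE, FALSE, TRUE, FALSE)))  # 0.75
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0 || nNeg == 0) {
    stop("ROC needs at least one positive and one negative example")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # group tied scores: one ROC point per distinct threshold
  last <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[last] / nPos
  fp <- cumsum(!l)[last] / nNeg
  pts <- data.frame(fpr = c(0, fp), tpr = c(0, tp))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  new("RocResult", points = pts, auc = auc, ci90 = c(NA_real_, NA_real_),
      nPos = as.integer(nPos), nNeg = as.integer(nNeg))
}

#' Percentile-bootstrap confidence interval for the AUC
#'
#' Resamples the examples with replacement; resamples that lose one of
#' the classes are redrawn. The interval is the percentile interval of
#' the resampled AUCs (5th and 95th percentiles at the default 90%
#' level).
#'
#' @inheritParams rocAuc
#' @param nResamples Number of bootstrap resamples (default 2000).
#' @param level Confidence level (default 0.90).
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector `c(low, high)`.
#' @export
bootstrapAucCi <- function(scores, labels, nResamples = 2000, level = 0.90,
                           seed = NULL) {
  labels <- as.logical(labels)
  if (!is.null(seed)) set.seed(seed)
  n <- length(scores)
  aucs <- numeric(nResamples)
  for (b in seq_len(nResamples)) {
    repeat {
      i <- sample.int(n, n, replace = TRUE)
      if (any(labels[i]) && any(!labels[i])) break
    }
    aucs[b] <- aucValue(rocAuc(scores[i], labels[i]))
  }
  unname(stats::quantile(aucs, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Specificity ROC from Z-score differences
#'
#' Each comparison contributes the specificity score
#' \eqn{\Delta Z = Z(bound) - Z(unbound)}. Observed preferences are
#' the positive class; the reversed differences (unbound over bound)
#' form the symmetric negative class, and agreement is evaluated as a
#' function of the score-difference cutoff.
#'
#' @param comparisons From [buildSpecificity()].
#' @param zScores `data.frame` with columns `peptide`, `receptor`,
#'   `z`.
#' @return A [RocResult-class].
#' @export
specificityRoc <- function(comparisons, zScores) {
  if (!nrow(comparisons)) stop("no specificity comparisons provided")
  key <- paste(zScores$peptide, zScores$receptor)
  zb <- zScores$z[match(paste(comparisons$peptide, comparisons$receptorBound), key)]
  zu <- zScores$z[match(paste(comparisons$peptide, comparisons$receptorUnbound), key)]
  ok <- !is.na(zb) & !is.na(zu)
  if (any(!ok)) {
    warning(sum(!ok), " comparison(s) dropped for missing Z-scores")
  }
  if (!any(ok)) stop("no comparisons with Z-scores for both receptors")
  delta <- zb[ok] - zu[ok]
  rocAuc(c(delta, -delta), c(rep(TRUE, length(delta)), rep(FALSE, length(delta))))
}
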