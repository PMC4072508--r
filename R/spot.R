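# SPOT-array candidate classification.
#
# Array signals alone correlate poorly with solution binding for
# diverse peptides, so an interaction is only called a candidate when
# both negative-control mutations -- the buried 3a position mutated to
# Asp and the small 3e position mutated to Leu -- reduce the signal by
# at least 30%.

#' Negative-control mutants of a candidate window
#'
#' Returns the two control sequences: position 3a mutated to Asp and
#' position 3e mutated to Leu, everything else unchanged. Errors when
#' the window already carries the control residue (the control would
#' be indistinguishable; cannot occur for windows passing the
#' compositional filter).
#'
#' @param sequence A window aligned to `register`.
#' @param register Register labels (default: 26-residue 1d-5a window;
#'   must contain `3a` and `3e`).
#' @return Named character vector `c(mut3aD = ..., mut3eL = ...)`.
#' @export
makeNegativeControls <- function(sequence,
                                 register = registerLabels("1d", "5a")) {
  if (!all(c("3a", "3e") %in% register)) {
    stop("register must contain positions 3a and 3e")
  }
  stopifnot(nchar(sequence) == length(register))
  i3a <- registerIndex("3a", register)
  i3e <- registerIndex("3e", register)
  if (substr(sequence, i3a, i3a) == "D") {
    stop("window already has Asp at 3a; control indistinguishable")
  }
  if (substr(sequence, i3e, i3e) == "L") {
    stop("window already has Leu at 3e; control indistinguishable")
  }
  m1 <- sequence; substr(m1, i3a, i3a) <- "D"
  m2 <- sequence; substr(m2, i3e, i3e) <- "L"
  c(mut3aD = m1, mut3eL = m2)
}

#' Signal as a fraction of the reference peptide signal
#'
#' @param intensity Measured spot intensity (>= 0).
#' @param bimIntensity Intensity of the strong-binding reference
#'   peptide on the same membrane (> 0).
#' @return `intensity / bimIntensity`.
#' @export
bimFraction <- function(intensity, bimIntensity) {
  stopifnot(all(bimIntensity > 0))
  intensity / bimIntensity
}

#' Classify an interaction from its negative-control reductions
#'
#' `TRUE` (a "candidate array interaction") when both control mutants
#' reduce the wild-type signal by at least `reductionThreshold`
#' (inclusive, matching "at least 30%"). The test is scale-invariant,
#' so raw intensities and reference-normalized fractions give the same
#' outcome.
#'
#' @param wildtype Wild-type spot intensity.
#' @param controls Numeric vector of the two control intensities
#'   (3a->Asp, 3e->Leu).
#' @param reductionThreshold Minimum fractional reduction (default 0.30).
#' @return Logical.
#' @export
classifyCandidate <- function(wildtype, controls, reductionThreshold = 0.30) {
  stopifnot(length(controls) == 2)
  if (wildtype <= 0) {
    warning("non-positive wild-type intensity: not classifiable as candidate")
    return(FALSE)
  }
  all((wildtype - controls) / wildtype >= reductionThreshold)
}

#' Count interactions above signal-fraction thresholds
#'
#' Bins array interactions by their signal as a fraction of the
#' reference peptide: counts at the default thresholds are nested
#' (n(>=5%) >= n(>=10%) >= n(>=25%)).
#'
#' @param fractions Signal fractions from [bimFraction()].
#' @param thresholds Fraction thresholds (default 5%, 10%, 25%).
#' @return Named integer vector of counts.
#' @export
signalBinCounts <- function(fractions, thresholds = c(0.05, 0.10, 0.25)) {
  setNames(vapply(thresholds, function(t) sum(fractions >= t), 0L),
           paste0("ge", thresholds * 100, "pct"))
}

#' Classify a table of SPOT measurements
#'
#' @param measurements `data.frame` with columns `peptide`,
#'   `receptor`, `variant` (one of `wt`, `3aD`, `3eL`) and
#'   `intensity`. Each (peptide, receptor) needs a `wt` row and both
#'   control rows.
#' @param reductionThreshold Passed to [classifyCandidate()].
#' @return `data.frame` per (peptide, receptor) with the wild-type
#'   intensity, both reductions and the `candidate` call.
#' @export
classifySpotTable <- function(measurements, reductionThreshold = 0.30) {
  need <- c("peptide", "receptor", "variant", "intensity")
  stopifnot(all(need %in% names(measurements)))
  key <- interaction(measurements$peptide, measurements$receptor, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(measurements)), key), function(i) {
    m <- measurements[i, , drop = FALSE]
    wt <- m$intensity[m$variant == "wt"]
    c1 <- m$intensity[m$variant == "3aD"]
    c2 <- m$intensity[m$variant == "3eL"]
    if (length(wt) != 1 || length(c1) != 1 || length(c2) != 1) {
      stop("need exactly one wt, 3aD and 3eL row per (peptide, receptor)")
    }
    data.frame(peptide = m$peptide[1], receptor = m$receptor[1],
               wildtype = wt,
               reduction3aD = if (wt > 0) (wt - c1) / wt else NA_real_,
               reduction3eL = if (wt > 0) (wt - c2) / wt else NA_real_,
               candidate = classifyCandidate(wt, c(c1, c2),
                                             reductionThreshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
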