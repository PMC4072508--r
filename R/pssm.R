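# Position-specific scoring from peptide SPOT-array intensities.
#
# A substitution-array table reports, for each of the ten covered
# register positions and each amino acid, the binding signal intensity
# relative to the wild-type reference peptide. Scores are
# S = -(ln I - ln I_ref), so the reference residue scores 0 and weaker
# binders score positive (energy-like orientation).

#' Assemble a SPOT intensity table
#'
#' @param entries `data.frame` with columns `position` (heptad label,
#'   one of [PSSM_POSITIONS]), `aa` (one-letter code), `intensity`
#'   (non-negative signal), and logical `ref` marking the wild-type
#'   reference residue of each position.
#' @return The validated table, with class `"SpotTable"`.
#' @export
spotTable <- function(entries) {
  need <- c("position", "aa", "intensity", "ref")
  if (!all(need %in% names(entries))) {
    stop("entries must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(entries$position %in% PSSM_POSITIONS)) {
    stop("positions must be among: ", paste(PSSM_POSITIONS, collapse = ", "))
  }
  if (any(entries$intensity < 0)) stop("intensities must be non-negative")
  refs <- entries[as.logical(entries$ref), , drop = FALSE]
  if (!setequal(refs$position, PSSM_POSITIONS) ||
      nrow(refs) != length(PSSM_POSITIONS)) {
    stop("exactly one reference row required per position")
  }
  if (any(refs$intensity <= 0)) stop("reference intensities must be positive")
  structure(entries, class = c("SpotTable", "data.frame"))
}

#' Read a SPOT intensity table from TSV
#'
#' Expects tab-separated columns `position`, `aa`, `intensity`, `ref`.
#'
#' @param file Path to the TSV file.
#' @return A [spotTable()].
#' @export
readSpotTable <- function(file) {
  spotTable(utils::read.delim(file, stringsAsFactors = FALSE))
}

#' Build a position-specific scoring model from SPOT intensities
#'
#' Scores each (position, amino acid) as
#' \eqn{S = -(\ln I - \ln I_{ref})}. Intensities below
#' `floorFraction` of the position's reference intensity are clipped
#' to that floor before the logarithm, which caps the worst score at
#' \eqn{-\ln(floorFraction)} and keeps zero-intensity spots finite.
#'
#' @param table A [spotTable()].
#' @param floorFraction Intensity floor as a fraction of the reference
#'   (default 0.01, capping scores at ln 100).
#' @param receptorName Model metadata.
#' @return A [PssmModel-class].
#' @export
buildPssm <- function(table, floorFraction = 0.01, receptorName = "receptor") {
  stopifnot(inherits(table, "SpotTable"), floorFraction > 0)
  refs <- table[as.logical(table$ref), , drop = FALSE]
  iref <- setNames(refs$intensity, refs$position)[PSSM_POSITIONS]
  refAa <- setNames(refs$aa, refs$position)[PSSM_POSITIONS]
  scores <- matrix(NA_real_, nrow = 20, ncol = length(PSSM_POSITIONS),
                   dimnames = list(AA20, PSSM_POSITIONS))
  i <- cbind(match(table$aa, AA20), match(table$position, PSSM_POSITIONS))
  if (anyNA(i)) stop("non-standard amino acid in SPOT table")
  inten <- pmax(table$intensity, floorFraction * iref[table$position])
  scores[i] <- -(log(inten) - log(iref[table$position]))
  if (anyNA(scores)) {
    miss <- which(is.na(scores), arr.ind = TRUE)
    stop("missing SPOT entries, e.g. ", AA20[miss[1, 1]], " at ",
         PSSM_POSITIONS[miss[1, 2]])
  }
  # the reference residue scores exactly 0 by construction; snap any
  # rounding in the input reference row
  scores[cbind(match(refAa, AA20), seq_along(refAa))] <- 0
  names(refAa) <- PSSM_POSITIONS
  new("PssmModel", receptorName = receptorName, scores = scores,
      refAa = refAa)
}

#' Score peptide windows with a SPOT-derived model
#'
#' Sums the per-residue scores over the ten covered register
#' positions; all other window positions contribute 0.
#'
#' @param model A [PssmModel-class].
#' @param windows Character vector of sequences aligned to `register`.
#' @param register Register labels of the window positions (default:
#'   the 26-residue 1d-5a window). Must cover all ten scored
#'   positions.
#' @return Numeric vector of scores (0 for the reference sequence).
#' @export
scorePssm <- function(model, windows,
                      register = registerLabels("1d", "5a")) {
  if (!all(PSSM_POSITIONS %in% register)) {
    stop("window register must cover positions ",
         paste(PSSM_POSITIONS, collapse = ", "))
  }
  if (any(nchar(windows) != length(register))) {
    stop("all windows must have length ", length(register))
  }
  ch <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
               nrow = length(register))
  scores <- numeric(length(windows))
  for (p in PSSM_POSITIONS) {
    aa <- ch[match(p, register), ]
    i <- match(aa, AA20)
    if (anyNA(i)) stop("non-standard amino acid in window")
    scores <- scores + model@scores[cbind(i, match(p, PSSM_POSITIONS))]
  }
  scores
}
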