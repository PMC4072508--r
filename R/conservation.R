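# Shannon-entropy conservation filter.
#
# Candidate motifs are required to be more conserved than the rest of
# their parent protein: the summed column entropy of the 12-residue
# core window (positions 2d-4a) must be lower than the average entropy
# of all other 12-residue windows across the multiple sequence
# alignment. Gaps are excluded from the frequency counts.

asMsaMatrix <- function(msa) {
  if (inherits(msa, "AAMultipleAlignment")) {
    msa <- as.character(Biostrings::unmasked(msa))
  } else if (inherits(msa, "XStringSet")) {
    msa <- as.character(msa)
  }
  if (is.character(msa) && !is.matrix(msa)) {
    if (length(msa) < 2) stop("an alignment needs at least 2 rows")
    if (length(unique(nchar(msa))) != 1) {
      stop("aligned sequences must have equal length")
    }
    msa <- t(matrix(unlist(strsplit(msa, "", fixed = TRUE), use.names = FALSE),
                    ncol = length(msa)))
  }
  stopifnot(is.matrix(msa), nrow(msa) >= 2)
  msa
}

#' Read an aligned FASTA file as an alignment matrix
#'
#' @param file Path to aligned FASTA.
#' @return Character matrix, one row per sequence.
#' @export
readMsa <- function(file) {
  asMsaMatrix(Biostrings::readAAStringSet(file))
}

#' Shannon entropy of an alignment column
#'
#' \eqn{S = -\sum_a p_a \ln p_a} over the amino-acid frequencies of
#' the column; gap characters (`-`, `.`) are excluded from the
#' counts. An all-gap column has entropy 0 (with a warning).
#'
#' @param column Character vector of residues.
#' @return Entropy in nats, between 0 and ln(20).
#' @export
columnEntropy <- function(column) {
  stopifnot(length(column) >= 1)
  column <- column[!column %in% c("-", ".")]
  if (!length(column)) {
    warning("all-gap column: entropy defined as 0")
    return(0)
  }
  p <- table(column) / length(column)
  -sum(p * log(p))
}

#' Summed entropy of an alignment window
#'
#' @param msa Alignment (matrix, character vector of aligned rows, or
#'   `AAStringSet`/`AAMultipleAlignment`).
#' @param start 1-based first column of the window.
#' @param width Window width in columns (default 12, the 2d-4a core).
#' @return Sum of [columnEntropy()] over the window's columns.
#' @export
windowEntropy <- function(msa, start, width = 12) {
  m <- asMsaMatrix(msa)
  if (start < 1 || start + width - 1 > ncol(m)) {
    stop("window [", start, ", ", start + width - 1,
         "] out of alignment range (", ncol(m), " columns)")
  }
  sum(vapply(start:(start + width - 1),
             function(j) columnEntropy(m[, j]), numeric(1)))
}

#' Conservation test for a candidate motif core
#'
#' `TRUE` when the entropy of the 12-column window starting at
#' `coreStart` (the candidate's 2d-4a core) is strictly lower than the
#' mean entropy of all other 12-column sliding windows of the
#' alignment.
#'
#' @param msa Alignment (see [windowEntropy()]).
#' @param coreStart 1-based column of register position 2d.
#' @param width Window width (default 12).
#' @return Logical.
#' @export
isConserved <- function(msa, coreStart, width = 12) {
  m <- asMsaMatrix(msa)
  starts <- seq_len(ncol(m) - width + 1)
  if (!(coreStart %in% starts)) stop("core window does not fit in alignment")
  others <- setdiff(starts, coreStart)
  if (!length(others)) {
    stop("alignment has no windows other than the core to compare against")
  }
  ent <- vapply(starts, function(s) windowEntropy(m, s, width), numeric(1))
  ent[match(coreStart, starts)] < mean(ent[match(others, starts)])
}
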