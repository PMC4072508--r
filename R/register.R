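# Heptad register arithmetic for BH3-length windows.
#
# BH3 positions are labeled on a heptad [abcdefg]_n convention that
# tracks the hydrophobic/polar periodicity of the bound helix. The
# canonical landmarks are 3a (conserved Leu, buried at the interface)
# and 3f (conserved Asp). Windows used in this package come in two
# nested flavours: the 23-residue scoring core (1g-5a) and the
# 26-residue extended window (1d-5a) used for filtering and reporting.

HEPTAD_FULL <- paste0(rep(1:5, each = 7), rep(letters[1:7], 5))

#' Heptad register labels between two positions
#'
#' Returns the consecutive run of heptad labels from `from` to `to`
#' (inclusive), e.g. `registerLabels("1d", "5a")` gives the 26 labels
#' of an extended BH3 window and `registerLabels("1g", "5a")` the 23
#' labels of the scoring core.
#'
#' @param from,to Heptad labels such as `"1d"` or `"3a"`.
#' @return Character vector of consecutive labels.
#' @examples
#' length(registerLabels("1d", "5a"))  # 26
#' length(registerLabels("1g", "5a"))  # 23
#' @export
registerLabels <- function(from = "1d", to = "5a") {
  i <- match(from, HEPTAD_FULL)
  j <- match(to, HEPTAD_FULL)
  if (is.na(i) || is.na(j)) {
    stop("unknown heptad label: ", if (is.na(i)) from else to)
  }
  if (j < i) stop("'to' precedes 'from' in heptad order")
  HEPTAD_FULL[i:j]
}

#' Index of a heptad label within a register
#'
#' @param label Heptad label(s), e.g. `"3a"`.
#' @param register Character vector of register labels
#'   (default: the 26-residue 1d-5a window).
#' @return Integer position(s) of `label` within `register`; errors if
#'   any label is absent.
#' @examples
#' registerIndex("3a")  # 12
#' registerIndex("3f")  # 17
#' @export
registerIndex <- function(label, register = registerLabels("1d", "5a")) {
  idx <- match(label, register)
  if (anyNA(idx)) {
    stop("label(s) not in register: ",
         paste(label[is.na(idx)], collapse = ", "))
  }
  idx
}

# labels assigned outward from an anchor residue carrying "3a";
# offsets falling outside 1a..5g are NA (outside template coverage)
heptadFromAnchor <- function(offsets) {
  pos <- match("3a", HEPTAD_FULL) + offsets
  out <- rep(NA_character_, length(offsets))
  ok <- pos >= 1L & pos <= length(HEPTAD_FULL)
  out[ok] <- HEPTAD_FULL[pos[ok]]
  out
}
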