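# JSON serialization for derived models, so scoring models can be
# built once and shipped between the command-line steps.

#' Write a scoring model to JSON
#'
#' Serializes a [StatiumModel-class] (pairs, fingerprints, counts,
#' energies, background, metadata) or a [PssmModel-class] (score
#' matrix, reference residues) with full numeric precision.
#'
#' @param model A [StatiumModel-class] or [PssmModel-class].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
writeModelJson <- function(model, file) {
  obj <- if (is(model, "StatiumModel")) {
    pr <- modelPairs(model)
    list(type = "statium",
         receptorName = model@receptorName, variant = model@variant,
         pairs = pr,
         counts = model@counts, energies = model@energies,
         background = as.list(model@background),
         pseudocountMass = model@pseudocountMass)
  } else if (is(model, "PssmModel")) {
    list(type = "pssm", receptorName = model@receptorName,
         scores = pssmScores(model), refAa = as.list(model@refAa))
  } else {
    stop("unsupported model class: ", class(model))
  }
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(file)
}

#' Read a scoring model from JSON
#'
#' @param file Path written by [writeModelJson()].
#' @return A [StatiumModel-class] or [PssmModel-class].
#' @export
readModelJson <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (identical(obj$type, "statium")) {
    counts <- matrix(as.integer(obj$counts), ncol = 20,
                     dimnames = list(NULL, AA20))
    energies <- matrix(as.numeric(obj$energies), ncol = 20,
                       dimnames = list(NULL, AA20))
    new("StatiumModel", receptorName = obj$receptorName,
        variant = obj$variant,
        pairs = as.data.frame(obj$pairs, stringsAsFactors = FALSE),
        counts = counts, energies = energies,
        background = unlist(obj$background)[AA20],
        pseudocountMass = obj$pseudocountMass)
  } else if (identical(obj$type, "pssm")) {
    scores <- matrix(as.numeric(obj$scores), nrow = 20,
                     dimnames = list(AA20, PSSM_POSITIONS))
    new("PssmModel", receptorName = obj$receptorName, scores = scores,
        refAa = unlist(obj$refAa)[PSSM_POSITIONS])
  } else {
    stop("unrecognized model file: ", file)
  }
}
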