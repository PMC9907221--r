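#' Presentation-score contract
#'
#' A `RewardScorer` maps (peptide, allele) pairs to a presentation score in
#' `[0, 1]`: the composite probability that the peptide is processed and
#' displayed by the MHC Class I allele. Scores must be deterministic for
#' fixed inputs within one scorer instance, and batch calls return scores
#' aligned with the input order. The mutation environment and all
#' generation metrics consume this contract; shipped realizations are the
#' synthetic [HiddenMotifOracle-class], a plain [FunctionScorer-class]
#' wrapper, and the [ExternalPredictorAdapter-class] for an installed
#' external predictor.
#'
#' @export
setClass("RewardScorer", representation("VIRTUAL"))

#' Score peptides against one allele
#'
#' @param scorer A [RewardScorer-class] realization.
#' @param peptides Character vector of peptides.
#' @param allele Allele name known to the scorer.
#' @return Numeric vector in `[0, 1]`, aligned with `peptides`.
#' @export
setGeneric("presentationScores",
           function(scorer, peptides, allele)
             standardGeneric("presentationScores"))

#' Function-backed scorer
#'
#' Wraps an arbitrary `function(peptides, allele) -> scores` as a
#' [RewardScorer-class]; convenient for tests and custom predictors.
#' @slot fn The scoring function.
#' @export
setClass("FunctionScorer", contains = "RewardScorer",
         representation(fn = "function"))

#' @rdname FunctionScorer-class
#' @param fn Function of `(peptides, allele)` returning scores in `[0, 1]`.
#' @export
functionScorer <- function(fn) new("FunctionScorer", fn = fn)

setMethod("presentationScores", "FunctionScorer",
  function(scorer, peptides, allele) {
    s <- scorer@fn(peptides, allele)
    if (length(s) != length(peptides) || any(s < 0 | s > 1))
      stop("scorer function must return one score in [0,1] per peptide")
    s
  })

#' Adapter for an external presentation predictor
#'
#' Invokes an installed command-line predictor through a subprocess. The
#' command template receives a peptide file and allele and must print one
#' score per line on stdout. Optional at runtime; none of the shipped
#' analyses require it.
#'
#' @slot command Executable name.
#' @slot args Function `(peptideFile, allele) -> character` building the
#'   argument vector.
#' @export
setClass("ExternalPredictorAdapter", contains = "RewardScorer",
         representation(command = "character", args = "function"))

#' @rdname ExternalPredictorAdapter-class
#' @param command,args See slots.
#' @export
externalPredictorAdapter <- function(command, args) {
  if (Sys.which(command) == "")
    warning("external predictor '", command, "' not found on PATH")
  new("ExternalPredictorAdapter", command = command, args = args)
}

setMethod("presentationScores", "ExternalPredictorAdapter",
  function(scorer, peptides, allele) {
    tf <- tempfile(fileext = ".txt")
    on.exit(unlink(tf))
    writeLines(peptides, tf)
    out <- system2(scorer@command, scorer@args(tf, allele), stdout = TRUE)
    s <- as.numeric(out)
    if (length(s) != length(peptides) || anyNA(s))
      stop("external predictor returned ", length(s), " scores for ",
           length(peptides), " peptides")
    pmin(1, pmax(0, s))
  })
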