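#' Mutation environment configuration
#'
#' @slot maxSteps Maximum number of mutations per episode (T >= 1). An
#'   episode always terminates at this horizon.
#' @slot sigma Terminal presentation-score threshold in (0, 1): an episode
#'   ends early as soon as the mutated peptide scores strictly above it.
#'   The default 0.75 matches the qualified-peptide threshold used
#'   throughout motif building and screening.
#' @export
setClass("EnvConfig",
  representation(maxSteps = "integer", sigma = "numeric"),
  prototype(maxSteps = 8L, sigma = 0.75),
  validity = function(object) {
    if (object@maxSteps < 1L) return("maxSteps must be >= 1")
    if (object@sigma <= 0 || object@sigma >= 1)
      return("sigma must lie strictly inside (0, 1)")
    TRUE
  })

#' @param maxSteps,sigma See slots.
#' @rdname EnvConfig-class
#' @export
envConfig <- function(maxSteps = 8L, sigma = 0.75) {
  new("EnvConfig", maxSteps = as.integer(maxSteps), sigma = sigma)
}

#' Environment state: a peptide paired with an MHC allele
#'
#' @slot peptide Current peptide sequence.
#' @slot allele Allele name (passed to the scorer).
#' @slot pseudo The allele's 34-residue pseudo sequence.
#' @slot step Number of mutations applied so far.
#' @slot score Presentation score of the current peptide (`NA` before the
#'   first step; the scorer is called once per step on the mutated peptide
#'   and cached here).
#' @slot done Terminal flag.
#' @export
setClass("EnvState",
  representation(peptide = "character", allele = "character",
                 pseudo = "character", step = "integer",
                 score = "numeric", done = "logical"))

setMethod("show", "EnvState", function(object) {
  cat("EnvState:", object@peptide, "|", object@allele,
      "| step", object@step,
      if (!is.na(object@score)) paste("| score", round(object@score, 4)),
      if (object@done) "| terminal", "\n")
})

#' Start a new mutation episode
#'
#' Draws a uniform-random initial peptide (each residue uniform over the
#' alphabet) of the requested length, or of a length drawn uniformly from
#' 8..15 when `length = "sample"`. Reproducible under `set.seed()`.
#'
#' @param allele Allele name.
#' @param pseudo 34-residue pseudo sequence of the allele.
#' @param length Integer in 8..15, or `"sample"`.
#' @return An [EnvState-class] with `step = 0`.
#' @export
envReset <- function(allele, pseudo, length = "sample") {
  if (identical(length, "sample")) {
    length <- sample(8:15, 1L)
  } else {
    length <- as.integer(length)
    if (length < 8L || length > 15L)
      stop("peptide length must lie in [8, 15]; got ", length)
  }
  if (nchar(pseudo) != 34L)
    stop("pseudo sequence must have 34 residues; got ", nchar(pseudo))
  pep <- paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = "")
  new("EnvState", peptide = pep, allele = allele, pseudo = pseudo,
      step = 0L, score = NA_real_, done = FALSE)
}

#' Apply a substitution to a peptide
#'
#' @param peptide Peptide string.
#' @param position 1-based position to mutate.
#' @param residue New residue (must differ from the current one to be a
#'   genuine mutation; enforced at action sampling, not here, so that the
#'   operation stays a total function).
#' @return The mutated peptide, differing from the input at exactly
#'   `position` (or equal, if the same residue was supplied).
#' @export
applyMutation <- function(peptide, position, residue) {
  position <- as.integer(position)
  if (position < 1L || position > nchar(peptide))
    stop("position ", position, " out of bounds for a ",
         nchar(peptide), "-mer")
  aaIndex(residue)
  substr(peptide, position, position) <- residue
  peptide
}

#' Advance the environment by one mutation
#'
#' Mutates the peptide, scores the mutated peptide once, and terminates
#' when the score strictly exceeds `sigma` or the step horizon is reached.
#' Only terminal transitions carry a reward, equal to the terminal
#' presentation score; all earlier rewards are zero.
#'
#' @param state A non-terminal [EnvState-class].
#' @param position,residue The mutation action (1-based position).
#' @param scorer A [RewardScorer-class].
#' @param cfg An [EnvConfig-class].
#' @return List with `state` (next [EnvState-class]), `reward`, `done`,
#'   `score`.
#' @export
envStep <- function(state, position, residue, scorer, cfg = envConfig()) {
  if (state@done) stop("cannot step a terminal state")
  pep <- applyMutation(state@peptide, position, residue)
  score <- presentationScores(scorer, pep, state@allele)
  t1 <- state@step + 1L
  done <- (score > cfg@sigma) || (t1 >= cfg@maxSteps)
  nxt <- new("EnvState", peptide = pep, allele = state@allele,
             pseudo = state@pseudo, step = t1, score = score, done = done)
  list(state = nxt, reward = if (done) score else 0, done = done,
       score = score)
}
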