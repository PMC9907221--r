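#' Generate peptides with a trained policy
#'
#' Runs `n` independent episodes from uniform-random initial peptides,
#' sampling actions from the policy until early termination (score above
#' the environment threshold) or the step horizon. Episodes are simulated
#' in one batch, so generation is fast even for large `n`.
#'
#' @param policy A [MutationPolicy-class].
#' @param scorer A [RewardScorer-class].
#' @param allele Allele name.
#' @param pseudo The allele's 34-residue pseudo sequence.
#' @param n Number of peptides.
#' @param length Peptide length (integer in 8..15 or `"sample"`).
#' @param envCfg An [EnvConfig-class].
#' @return data.frame with columns peptide, score, steps.
#' @export
generatePeptides <- function(policy, scorer, allele, pseudo, n = 1000L,
                             length = 9L, envCfg = envConfig()) {
  if (nchar(pseudo) != 34L)
    stop("malformed pseudo sequence for ", allele, ": length ",
         nchar(pseudo))
  pseudoIdxList <- list(aaIndex(pseudo, split = TRUE))
  lens <- if (identical(length, "sample")) sample(8:15, n, TRUE)
          else rep(as.integer(length), n)
  if (any(lens < 8L | lens > 15L))
    stop("peptide length must lie in [8, 15]")
  out <- data.frame(peptide = character(n), score = numeric(n),
                    steps = integer(n))
  for (l in unique(lens)) {
    rows <- which(lens == l)
    X <- matrix(sample.int(20L, base::length(rows) * l, replace = TRUE),
                ncol = l)
    active <- seq_along(rows)
    steps <- integer(base::length(rows))
    scores <- numeric(base::length(rows))
    step <- 0L
    while (base::length(active) > 0L && step < envCfg@maxSteps) {
      step <- step + 1L
      Xa <- X[active, , drop = FALSE]
      act <- .actBatch(policy, Xa, rep(1L, nrow(Xa)), pseudoIdxList,
                       rep(FALSE, nrow(Xa)), NULL)
      Xa[cbind(seq_len(nrow(Xa)), act$pos)] <- act$res
      sc <- presentationScores(scorer, matrixToPeptides(Xa), allele)
      X[active, ] <- Xa
      steps[active] <- step
      scores[active] <- sc
      done <- sc > envCfg@sigma | step >= envCfg@maxSteps
      active <- active[!done]
    }
    out$peptide[rows] <- matrixToPeptides(X)
    out$score[rows] <- scores
    out$steps[rows] <- steps
  }
  out
}

#' sPWM baseline: sample peptides position-independently from a profile
#'
#' @param profile 20 x L probability matrix (e.g. from
#'   [expertProfile()] or [pwmMatrix()]).
#' @param n Number of peptides.
#' @return Character vector of peptides.
#' @export
spwmGenerate <- function(profile, n) {
  L <- ncol(profile)
  X <- matrix(0L, n, L)
  for (j in seq_len(L))
    X[, j] <- sample.int(20L, n, replace = TRUE, prob = profile[, j])
  matrixToPeptides(X)
}

#' Random baseline: uniform peptides of length 8-15
#'
#' @param n Number of peptides.
#' @param lengths Candidate lengths (uniform over them).
#' @return Character vector of peptides.
#' @export
randomGenerate <- function(n, lengths = 8:15) {
  lens <- if (base::length(lengths) == 1L) rep(lengths, n)
          else sample(lengths, n, replace = TRUE)
  vapply(lens, function(l)
    paste(sample(AA_ALPHABET, l, replace = TRUE), collapse = ""), "")
}

#' Evaluate a generated repertoire against a scorer
#'
#' Reports the percentage of qualified peptides (score strictly above the
#' threshold), the mean and the maximum presentation score.
#'
#' @param peptides Character vector (>= 1 peptide).
#' @param allele Allele name.
#' @param scorer A [RewardScorer-class].
#' @param threshold Qualification threshold.
#' @param method Label recorded in the report row.
#' @return One-row data.frame: method, allele, n, qualifiedPct, avgScore,
#'   maxScore.
#' @export
evaluateGeneration <- function(peptides, allele, scorer, threshold = 0.75,
                               method = "unknown") {
  if (base::length(peptides) == 0L) stop("empty peptide list")
  s <- presentationScores(scorer, peptides, allele)
  data.frame(method = method, allele = allele, n = base::length(peptides),
             qualifiedPct = 100 * mean(s > threshold),
             avgScore = mean(s), maxScore = max(s))
}
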