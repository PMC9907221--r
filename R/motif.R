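#' Position weight matrix (PWM) binding motif
#'
#' A 20 x L matrix of per-position residue probabilities, rows in canonical
#' [AA_ALPHABET] order, each column a proper probability distribution. PWMs
#' represent binding motifs built from peptide repertoires, expert-policy
#' profiles, hidden oracle motifs, and the matching-score reference used in
#' neoantigen screening.
#'
#' @slot mat Numeric 20 x L probability matrix.
#' @slot nPeptides Number of peptides supporting the matrix (`NA` if
#'   unknown, e.g. after file round-trips).
#' @export
setClass("PWM",
  representation(mat = "matrix", nPeptides = "integer"),
  validity = function(object) {
    m <- object@mat
    if (nrow(m) != 20L) return("PWM must have 20 rows")
    if (!identical(rownames(m), AA_ALPHABET))
      return("PWM rows must be named by the canonical alphabet order")
    if (any(m < 0)) return("PWM entries must be nonnegative")
    if (any(abs(colSums(m) - 1) > 1e-8))
      return("every PWM column must sum to 1")
    TRUE
  })

#' @param mat 20 x L probability matrix (rows in canonical order or
#'   unnamed, in which case canonical order is assumed).
#' @param nPeptides Supporting peptide count.
#' @rdname PWM-class
#' @export
newPWM <- function(mat, nPeptides = NA_integer_) {
  if (is.null(rownames(mat))) rownames(mat) <- AA_ALPHABET
  if (is.null(colnames(mat))) colnames(mat) <- as.character(seq_len(ncol(mat)))
  new("PWM", mat = mat, nPeptides = as.integer(nPeptides))
}

#' @rdname PWM-class
#' @param x,object A PWM.
#' @export
pwmMatrix <- function(x) x@mat

#' @rdname PWM-class
#' @export
nPeptides <- function(x) x@nPeptides

#' @rdname PWM-class
#' @export
pwmLength <- function(x) ncol(x@mat)

setMethod("show", "PWM", function(object) {
  cat("PWM motif of length", pwmLength(object),
      if (!is.na(object@nPeptides))
        paste0("(", object@nPeptides, " peptides)"), "\n")
  cons <- paste(AA_ALPHABET[apply(object@mat, 2L, which.max)], collapse = "")
  cat("  consensus:", cons, "\n")
  ic <- round(informationContent(object), 2L)
  cat("  information content (bits):", paste(ic, collapse = " "), "\n")
})

#' Keep peptides whose presentation score passes the qualification threshold
#'
#' Peptides with scores below the threshold are removed; a score exactly at
#' the threshold is retained.
#'
#' @param peptides Character vector.
#' @param scores Numeric vector aligned with `peptides`.
#' @param threshold Qualification threshold (default 0.75).
#' @return Character vector of retained peptides.
#' @export
filterQualified <- function(peptides, scores, threshold = 0.75) {
  if (length(peptides) != length(scores))
    stop("peptides and scores must be aligned (",
         length(peptides), " vs ", length(scores), ")")
  peptides[scores >= threshold]
}

#' Build a PWM from equal-length peptides
#'
#' Column j holds `(count of each residue at position j + pseudocount) /
#' (n + 20 * pseudocount)`. The default pseudocount 0 gives pure empirical
#' frequencies, appropriate for motif reporting from large generated
#' repertoires; expert profiles use pseudocount 1 instead (see
#' [buildExpertPolicy()]).
#'
#' @param peptides Character vector of equal-length peptides (>= 1).
#' @param pseudocount Nonnegative Laplace pseudocount.
#' @return A [PWM-class] object.
#' @export
buildPWM <- function(peptides, pseudocount = 0) {
  if (length(peptides) == 0L) stop("cannot build a PWM from zero peptides")
  mat <- peptideMatrix(peptides)
  n <- nrow(mat)
  counts <- apply(mat, 2L, function(col) tabulate(col, nbins = 20L))
  m <- (counts + pseudocount) / (n + 20 * pseudocount)
  newPWM(m, nPeptides = n)
}

#' Hellinger distance between two probability vectors
#'
#' `H(p, q) = (1/sqrt(2)) * || sqrt(p) - sqrt(q) ||_2`, bounded in `[0, 1]`,
#' 0 iff equal, 1 iff the supports are disjoint.
#'
#' @param p,q Numeric probability vectors of equal length.
#' @param tol Normalization tolerance.
#' @return Numeric scalar in `[0, 1]`.
#' @export
hellingerColumn <- function(p, q, tol = 1e-6) {
  if (length(p) != length(q)) stop("probability vectors differ in length")
  if (abs(sum(p) - 1) > tol || abs(sum(q) - 1) > tol ||
      any(p < -tol) || any(q < -tol))
    stop("inputs must be probability vectors (nonnegative, summing to 1)")
  min(1, sqrt(sum((sqrt(pmax(p, 0)) - sqrt(pmax(q, 0)))^2) / 2))
}

#' Motif distance and similarity between two PWMs
#'
#' The distance is the mean over positions of the column-wise Hellinger
#' distance; similarity is one minus the distance. Only motifs of equal
#' length are comparable.
#'
#' @param a,b [PWM-class] objects of the same length.
#' @return `motifDistance` returns the distance in `[0, 1]`;
#'   `motifSimilarity` returns `1 - distance`.
#' @export
motifDistance <- function(a, b) {
  ma <- pwmMatrix(a); mb <- pwmMatrix(b)
  if (ncol(ma) != ncol(mb))
    stop("cannot compare motifs of lengths ", ncol(ma), " and ", ncol(mb))
  mean(vapply(seq_len(ncol(ma)),
              function(j) hellingerColumn(ma[, j], mb[, j]), numeric(1L)))
}

#' @rdname motifDistance
#' @export
motifSimilarity <- function(a, b) 1 - motifDistance(a, b)

#' Pairwise motif distance matrix
#' @param pwms List of equal-length [PWM-class] objects.
#' @return Symmetric matrix with zero diagonal.
#' @export
pairwiseDistanceMatrix <- function(pwms) {
  n <- length(pwms)
  out <- matrix(0, n, n)
  if (!is.null(names(pwms))) dimnames(out) <- list(names(pwms), names(pwms))
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- motifDistance(pwms[[i]], pwms[[j]])
      out[i, j] <- d; out[j, i] <- d
    }
  }
  out
}

#' Per-position information content of a PWM
#'
#' `log2(20) - H(column)` bits per position, the sequence-logo letter-stack
#' height for a 20-letter alphabet.
#' @param pwm A [PWM-class] object.
#' @return Numeric vector of length `pwmLength(pwm)`.
#' @export
informationContent <- function(pwm) {
  m <- pwmMatrix(pwm)
  apply(m, 2L, function(p) {
    p <- p[p > 0]
    log2(20) + sum(p * log2(p))
  })
}

#' Motif robustness across repeated generation runs
#'
#' For each allele, generates `runs` repertoires of `nPeptides` peptides
#' from random initial states under distinct seeds, builds a per-run PWM
#' from the qualified peptides, and reports all pairwise motif similarities
#' per allele. Alleles with a run yielding zero qualified peptides are
#' flagged and excluded from the pairwise table.
#'
#' @param policy A trained [MutationPolicy-class].
#' @param scorer A [RewardScorer-class].
#' @param pseudo Named character vector of pseudo sequences for the alleles
#'   to assess.
#' @param runs Number of independent generation runs per allele.
#' @param nPeptides Peptides per run.
#' @param length Peptide length.
#' @param seeds Integer vector of `runs` seeds (default `seq_len(runs)`).
#' @param threshold Qualification threshold.
#' @param envCfg Environment configuration for generation.
#' @return List with `similarities` (data.frame allele, run_i, run_j,
#'   similarity) and `flagged` (character vector of excluded alleles).
#' @export
robustnessProtocol <- function(policy, scorer, pseudo, runs = 5L,
                               nPeptides = 1000L, length = 9L,
                               seeds = seq_len(runs), threshold = 0.75,
                               envCfg = envConfig()) {
  stopifnot(length(seeds) == runs)
  rows <- list(); flagged <- character(0)
  for (al in names(pseudo)) {
    pwms <- vector("list", runs)
    ok <- TRUE
    for (r in seq_len(runs)) {
      set.seed(seeds[r])
      gen <- generatePeptides(policy, scorer, allele = al,
                              pseudo = pseudo[[al]], n = nPeptides,
                              length = length, envCfg = envCfg)
      keep <- filterQualified(gen$peptide, gen$score, threshold)
      if (length(keep) == 0L) { ok <- FALSE; break }
      pwms[[r]] <- buildPWM(keep)
    }
    if (!ok) { flagged <- c(flagged, al); next }
    if (runs >= 2L) {
      for (i in seq_len(runs - 1L)) for (j in (i + 1L):runs) {
        rows[[length(rows) + 1L]] <- data.frame(
          allele = al, run_i = i, run_j = j,
          similarity = motifSimilarity(pwms[[i]], pwms[[j]]))
      }
    }
  }
  sims <- if (length(rows)) do.call(rbind, rows) else
    data.frame(allele = character(0), run_i = integer(0),
               run_j = integer(0), similarity = numeric(0))
  list(similarities = sims, flagged = flagged)
}
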