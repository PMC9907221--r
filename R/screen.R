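# raw matching score: sum over positions of pwm[residue_j, j], vectorized
# over an integer peptide matrix (n x L)
.matchRaw <- function(mat, pwmMat) {
  L <- ncol(mat)
  if (ncol(pwmMat) != L)
    stop("peptide length ", L, " does not match PWM length ", ncol(pwmMat))
  acc <- numeric(nrow(mat))
  for (j in seq_len(L)) acc <- acc + pwmMat[cbind(mat[, j], j)]
  acc
}

# analytic min-max normalization by the PWM's own attainable bounds
.matchNormalized <- function(mat, pwmMat) {
  raw <- .matchRaw(mat, pwmMat)
  lo <- sum(apply(pwmMat, 2L, min))
  hi <- sum(apply(pwmMat, 2L, max))
  if (hi - lo < 1e-12) return(rep(1, length(raw)))  # degenerate uniform PWM
  pmin(1, pmax(0, (raw - lo) / (hi - lo)))
}

#' Mutant sliding-window peptides around a point mutation
#'
#' Applies the mutation record to the protein and returns every k-mer window
#' of the mutated sequence that contains the mutated position; windows
#' truncated by the protein ends are omitted. Only mutant windows are
#' emitted; the unmutated reference windows never appear.
#'
#' @param protein Protein sequence string.
#' @param record One-row data.frame (or list) with `position` (1-based),
#'   `ref`, `alt` and optionally `protein_id`, `sample`.
#' @param k Window length (default 9, the dominant MHC Class I ligand
#'   length).
#' @return data.frame with columns peptide, start (1-based), offset (1-based
#'   position of the mutated residue within the window).
#' @export
windowPeptides <- function(protein, record, k = 9L) {
  pos <- as.integer(record$position)
  L <- nchar(protein)
  if (pos < 1L || pos > L)
    stop("mutation position ", pos, " outside protein of length ", L)
  refObs <- substr(protein, pos, pos)
  if (refObs != record$ref)
    stop("reference mismatch at position ", pos, ": protein has ", refObs,
         ", record says ", record$ref)
  if (record$ref == record$alt) stop("alt residue equals reference")
  mutated <- protein
  substr(mutated, pos, pos) <- as.character(record$alt)
  starts <- seq.int(max(1L, pos - k + 1L), min(pos, L - k + 1L))
  if (length(starts) == 0L || starts[1L] > min(pos, L - k + 1L))
    return(data.frame(peptide = character(0), start = integer(0),
                      offset = integer(0)))
  data.frame(
    peptide = vapply(starts, function(s) substr(mutated, s, s + k - 1L), ""),
    start = starts,
    offset = pos - starts + 1L)
}

#' PWM matching score of a peptide
#'
#' The raw score sums, over positions, the PWM probability of the peptide's
#' residue at that position. It is min-max normalized into `[0, 1]` using the
#' PWM's analytic bounds (sum of per-column minima and maxima), which makes
#' scores comparable across cohorts; set `normalization = "none"` to get raw
#' scores and normalize empirically over a screened population instead.
#' For a degenerate PWM whose bounds coincide (e.g. all-uniform), the
#' normalized score is defined as 1 and a warning is raised.
#'
#' @param peptides Character vector of peptides, all of the PWM's length.
#' @param pwm A [PWM-class].
#' @param normalization `"analytic"` or `"none"`.
#' @return data.frame with columns peptide, raw, normalized (normalized is
#'   `NA` under `"none"`).
#' @export
matchingScore <- function(peptides, pwm, normalization = c("analytic",
                                                           "none")) {
  normalization <- match.arg(normalization)
  m <- peptideMatrix(peptides)
  pm <- pwmMatrix(pwm)
  raw <- .matchRaw(m, pm)
  norm <- rep(NA_real_, length(raw))
  if (normalization == "analytic") {
    lo <- sum(apply(pm, 2L, min)); hi <- sum(apply(pm, 2L, max))
    if (hi - lo < 1e-12) {
      warning("degenerate PWM: min and max matching scores coincide; ",
              "normalized scores set to 1")
      norm <- rep(1, length(raw))
    } else norm <- pmin(1, pmax(0, (raw - lo) / (hi - lo)))
  }
  data.frame(peptide = peptides, raw = raw, normalized = norm)
}

#' Screen mutated proteins for neoantigen candidates by motif matching
#'
#' Extracts mutant k-mer windows for every mutation record, scores each
#' (peptide, allele) pair by the allele's PWM matching score, and labels it
#' with the reference scorer (label 1 when the presentation score exceeds
#' `threshold`). Duplicate (peptide, allele) pairs are deduplicated before
#' metrics. Alleles without a PWM are listed in the report and skipped.
#'
#' @param records Mutation records data.frame (see [readMutationRecords()]).
#' @param proteins Named character vector of protein sequences.
#' @param pwms Named list of [PWM-class] per allele.
#' @param scorer A [RewardScorer-class] providing reference labels.
#' @param threshold Presentation-score threshold for the neoantigen label.
#' @param k Window length (must equal each PWM's length).
#' @param normalization Passed to [matchingScore()].
#' @return List with `matches` (data.frame peptide, allele, raw, normalized,
#'   label), `perAllele` (counts and AUC per allele), `summary` (pooled AUC,
#'   two-sided Wilcoxon rank-sum p-value, group medians and counts) and
#'   `skippedAlleles`.
#' @export
screenNeoantigens <- function(records, proteins, pwms, scorer,
                              threshold = 0.75, k = 9L,
                              normalization = "analytic") {
  if (nrow(records) == 0L)
    return(list(matches = data.frame(), perAllele = data.frame(),
                summary = data.frame(), skippedAlleles = character(0)))
  cand <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    if (!rec$protein_id %in% names(proteins))
      stop("record ", i, " references unknown protein ", rec$protein_id)
    w <- windowPeptides(proteins[[rec$protein_id]], rec, k = k)
    if (nrow(w)) cand[[length(cand) + 1L]] <- w["peptide"]
  }
  peptides <- unique(do.call(rbind, cand)$peptide)
  alleles <- names(pwms)
  skipped <- alleles[vapply(pwms, is.null, TRUE)]
  alleles <- setdiff(alleles, skipped)
  rows <- list()
  for (al in alleles) {
    ms <- matchingScore(peptides, pwms[[al]], normalization = normalization)
    ref <- presentationScores(scorer, peptides, al)
    rows[[al]] <- data.frame(peptide = peptides, allele = al,
                             raw = ms$raw, normalized = ms$normalized,
                             label = as.integer(ref > threshold))
  }
  matches <- do.call(rbind, rows)
  rownames(matches) <- NULL
  matches <- unique(matches)
  perAllele <- do.call(rbind, lapply(alleles, function(al) {
    sub <- matches[matches$allele == al, ]
    ev <- tryCatch(evaluateDiscrimination(sub$normalized, sub$label),
                   error = function(e) NULL)
    data.frame(allele = al, n = nrow(sub), nNeoantigen = sum(sub$label),
               auc = if (is.null(ev)) NA_real_ else ev$auc)
  }))
  ev <- tryCatch(evaluateDiscrimination(matches$normalized, matches$label),
                 error = function(e) NULL)
  summary <- data.frame(
    n = nrow(matches), nNeoantigen = sum(matches$label),
    auc = if (is.null(ev)) NA_real_ else ev$auc,
    wilcoxonP = if (is.null(ev)) NA_real_ else ev$pValue,
    medianNeo = if (is.null(ev)) NA_real_ else ev$medianPositive,
    medianNonNeo = if (is.null(ev)) NA_real_ else ev$medianNegative)
  list(matches = matches, perAllele = perAllele, summary = summary,
       skippedAlleles = skipped)
}

#' Discrimination metrics for neoantigen screening
#'
#' AUC computed from the rank statistic (Mann-Whitney U with averaged tie
#' ranks) and the two-sided Wilcoxon rank-sum test between the score groups.
#'
#' @param scores Numeric scores (higher = more neoantigen-like).
#' @param labels 0/1 labels (1 = neoantigen).
#' @return List with auc, pValue, medianPositive, medianNegative, n1, n0.
#'   AUC requires both classes to be non-empty; otherwise an error explains
#'   which class is missing.
#' @export
evaluateDiscrimination <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: ", if (n1 == 0L) "no positive" else "no negative",
         " examples in input")
  r <- rank(scores)
  auc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  wt <- stats::wilcox.test(scores[labels == 1L], scores[labels == 0L],
                           alternative = "two.sided", exact = FALSE,
                           correct = TRUE)
  list(auc = auc, pValue = wt$p.value,
       medianPositive = stats::median(scores[labels == 1L]),
       medianNegative = stats::median(scores[labels == 0L]),
       n1 = n1, n0 = n0)
}
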