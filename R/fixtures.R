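#' Synthetic hidden-motif presentation oracle
#'
#' A self-contained [RewardScorer-class] whose ground truth is an explicit
#' per-allele, per-length PWM with a few near-point-mass anchor columns
#' (probability `kappa` on one residue) and uniform columns elsewhere. The
#' presentation score of a peptide is its analytically min-max normalized
#' PWM matching score passed through a fixed monotone logistic squashing,
#' calibrated so that uniform-random peptides score near 0, peptides with
#' any anchor column unmatched stay below the 0.75 qualification threshold,
#' and peptides matching the full anchor set score 1. Because the ground
#' truth motif is explicit, motif-recovery analyses are well posed.
#'
#' @slot pwms List: allele -> list: length (as character) -> [PWM-class].
#' @slot anchors List: allele -> list: length -> integer anchor positions.
#' @slot pseudo Named character vector of synthetic 34-mer pseudo sequences.
#' @slot squashShape,squashMid Frozen logistic squashing constants
#'   (steepness and midpoint on the normalized-match scale).
#' @export
setClass("HiddenMotifOracle", contains = "RewardScorer",
  representation(pwms = "list", anchors = "list", pseudo = "character",
                 squashShape = "numeric", squashMid = "numeric"))

#' Build a hidden-motif oracle
#'
#' @param nAlleles Number of synthetic alleles.
#' @param lengths Peptide lengths the oracle supports (default 9).
#' @param nAnchors Anchor columns per motif; must be smaller than the
#'   shortest supported length.
#' @param kappa Anchor concentration in (0.05, 1]: probability mass on the
#'   anchor residue; the remaining mass is spread evenly.
#' @param seed Integer seed for drawing anchors, anchor residues and pseudo
#'   sequences.
#' @return A [HiddenMotifOracle-class].
#' @export
makeHiddenOracle <- function(nAlleles = 3L, lengths = 9L, nAnchors = 4L,
                             kappa = 0.9, seed = 1L) {
  if (kappa <= 0.05 || kappa > 1)
    stop("kappa must lie in (0.05, 1]; got ", kappa)
  if (nAnchors >= min(lengths))
    stop("nAnchors must be smaller than the shortest supported length")
  set.seed(seed)
  alleles <- sprintf("SYN-%02d", seq_len(nAlleles))
  pwms <- anchors <- vector("list", nAlleles)
  names(pwms) <- names(anchors) <- alleles
  pseudo <- vapply(alleles, function(a)
    paste(sample(AA_ALPHABET, 34L, replace = TRUE), collapse = ""), "")
  for (a in alleles) {
    pwms[[a]] <- anchors[[a]] <- list()
    for (l in lengths) {
      anc <- sort(sample.int(l, nAnchors))
      m <- matrix(1 / 20, 20L, l)
      for (pos in anc) {
        res <- sample.int(20L, 1L)
        m[, pos] <- (1 - kappa) / 19
        m[res, pos] <- kappa
      }
      rownames(m) <- AA_ALPHABET
      key <- as.character(l)
      pwms[[a]][[key]] <- newPWM(m)
      anchors[[a]][[key]] <- anc
    }
  }
  # Frozen squashing calibration. On the analytically normalized match
  # scale a peptide matching k of the 4 anchors scores exactly k/4 (the
  # uniform non-anchor columns contribute no variation), so a midpoint of
  # 0.85 with steepness 12 places the 0.75 qualification threshold strictly
  # between "one anchor missing" (squashed ~0.27) and "all anchors matched"
  # (squashed 1): qualification means the full anchor set is matched, and
  # uniform-random peptides score near 0.
  new("HiddenMotifOracle", pwms = pwms, anchors = anchors, pseudo = pseudo,
      squashShape = 12, squashMid = 0.85)
}

#' @rdname makeHiddenOracle
#' @param oracle A [HiddenMotifOracle-class].
#' @export
oracleAlleles <- function(oracle) names(oracle@pwms)

#' @rdname makeHiddenOracle
#' @export
oraclePseudoSequences <- function(oracle) oracle@pseudo

#' @rdname makeHiddenOracle
#' @param allele Allele name.
#' @param length Peptide length.
#' @export
hiddenPWM <- function(oracle, allele, length) {
  p <- oracle@pwms[[allele]][[as.character(length)]]
  if (is.null(p))
    stop("oracle has no hidden motif for allele ", allele,
         " at length ", length)
  p
}

#' @rdname makeHiddenOracle
#' @export
hiddenAnchors <- function(oracle, allele, length) {
  oracle@anchors[[allele]][[as.character(length)]]
}

#' @rdname makeHiddenOracle
#' @export
hiddenConsensus <- function(oracle, allele, length) {
  m <- pwmMatrix(hiddenPWM(oracle, allele, length))
  paste(AA_ALPHABET[apply(m, 2L, which.max)], collapse = "")
}

# logistic squashing fixed to map 0 -> 0 and 1 -> 1
.squash <- function(s, a, b) {
  lo <- stats::plogis(-a * b)
  hi <- stats::plogis(a * (1 - b))
  (stats::plogis(a * (s - b)) - lo) / (hi - lo)
}

# vectorized oracle scoring on an integer peptide matrix (one length)
.oracleScoreMatrix <- function(oracle, mat, allele) {
  pwm <- hiddenPWM(oracle, allele, ncol(mat))
  s <- .matchNormalized(mat, pwmMatrix(pwm))
  .squash(s, oracle@squashShape, oracle@squashMid)
}

setMethod("presentationScores", "HiddenMotifOracle",
  function(scorer, peptides, allele) {
    lens <- nchar(peptides)
    out <- numeric(length(peptides))
    for (l in unique(lens)) {
      sel <- lens == l
      out[sel] <- .oracleScoreMatrix(scorer, peptideMatrix(peptides[sel]),
                                     allele)
    }
    out
  })

# uniform random peptides in index space
.randomPeptideMatrix <- function(n, length) {
  matrix(sample.int(20L, n * length, replace = TRUE), nrow = n, ncol = length)
}

#' Synthetic binding dataset from a hidden-motif oracle
#'
#' Rejection-samples peptides against the oracle until `nPerAllele`
#' qualified (score > `threshold`) records exist per allele, and keeps an
#' equal number of non-qualified records as negatives. Candidate positives
#' are proposed from the allele's hidden PWM (a qualified peptide is a rare
#' event under a uniform proposal) and candidate negatives from the uniform
#' distribution; in both cases acceptance, and the final label, come only
#' from thresholding the oracle score, never from the proposal. The
#' `measurement` column holds the oracle presentation score, so downstream
#' qualification by score thresholding reproduces the oracle labels.
#'
#' @param oracle A [HiddenMotifOracle-class].
#' @param nPerAllele Positive records required per allele.
#' @param length Peptide length to sample.
#' @param threshold Qualification threshold.
#' @param seed Integer seed.
#' @param maxAttempts Cap on sampled peptides per allele before aborting.
#' @return data.frame with columns allele, peptide, measurement.
#' @export
synthBindingDataset <- function(oracle, nPerAllele = 200L, length = 9L,
                                threshold = 0.75, seed = 1L,
                                maxAttempts = 5e6) {
  set.seed(seed)
  rows <- list()
  for (al in oracleAlleles(oracle)) {
    pwm <- pwmMatrix(hiddenPWM(oracle, al, length))
    pos <- character(0); posScore <- numeric(0)
    neg <- character(0); negScore <- numeric(0)
    attempts <- 0L
    while (length(pos) < nPerAllele || length(neg) < nPerAllele) {
      if (attempts >= maxAttempts)
        stop("acceptance rule too strict: only ", length(pos), "/",
             nPerAllele, " qualified peptides for ", al, " after ",
             attempts, " attempts")
      nb <- 2048L
      batch <- vapply(seq_len(length),
                      function(j) sample.int(20L, nb, replace = TRUE,
                                             prob = pwm[, j]),
                      integer(nb))
      attempts <- attempts + nrow(batch)
      sc <- .oracleScoreMatrix(oracle, batch, al)
      hit <- which(sc > threshold)
      if (length(hit)) {
        pos <- c(pos, matrixToPeptides(batch[hit, , drop = FALSE]))
        posScore <- c(posScore, sc[hit])
      }
      if (length(neg) < nPerAllele) {
        unif <- .randomPeptideMatrix(nb, length)
        su <- .oracleScoreMatrix(oracle, unif, al)
        miss <- which(su <= threshold)[seq_len(min(nPerAllele - length(neg),
                                                   sum(su <= threshold)))]
        neg <- c(neg, matrixToPeptides(unif[miss, , drop = FALSE]))
        negScore <- c(negScore, su[miss])
      }
    }
    keep <- seq_len(nPerAllele)
    rows[[al]] <- data.frame(
      allele = al,
      peptide = c(pos[keep], neg),
      measurement = c(posScore[keep], negScore))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic mutation cohort for neoantigen screening
#'
#' Random protein sequences plus point-mutation records whose reference
#' residues match the proteins. A controllable fraction of mutations is
#' planted so that the mutant 9-mer window equals a hidden motif consensus
#' for a randomly chosen oracle allele (a true neoantigen); the rest are
#' random substitutions.
#'
#' @param oracle A [HiddenMotifOracle-class] (supplies consensus windows).
#' @param nProteins,proteinLength,nMutations Cohort dimensions.
#' @param plantedFraction Fraction of mutations creating a consensus window.
#' @param length Window/motif length used for planting (default 9).
#' @param seed Integer seed.
#' @return List with `proteins` (named character vector) and `records`
#'   (data.frame protein_id, position, ref, alt, sample).
#' @export
synthCohort <- function(oracle, nProteins = 20L, proteinLength = 120L,
                        nMutations = 60L, plantedFraction = 0.3,
                        length = 9L, seed = 1L) {
  stopifnot(nProteins > 0L, proteinLength >= length + 2L, nMutations > 0L)
  set.seed(seed)
  prot <- lapply(seq_len(nProteins), function(i)
    sample.int(20L, proteinLength, replace = TRUE))
  names(prot) <- sprintf("PROT%03d", seq_len(nProteins))
  alleles <- oracleAlleles(oracle)
  planted <- seq_len(nMutations) <= round(plantedFraction * nMutations)
  recs <- vector("list", nMutations)
  # planted windows already written per protein; later plantings must not
  # overlap them, or they would rewrite an earlier record's reference
  used <- lapply(prot, function(p) integer(0))
  for (k in seq_len(nMutations)) {
    pid <- sample(names(prot), 1L)
    if (planted[k]) {
      al <- sample(alleles, 1L)
      cons <- aaIndex(hiddenConsensus(oracle, al, length), split = TRUE)
      for (try in seq_len(200L)) {
        pid <- sample(names(prot), 1L)
        w <- sample.int(proteinLength - length + 1L, 1L)
        if (!any(w:(w + length - 1L) %in% used[[pid]])) break
        if (try == 200L)
          stop("could not place a planted window without overlap; ",
               "increase nProteins or proteinLength")
      }
      used[[pid]] <- c(used[[pid]], w:(w + length - 1L))
      prot[[pid]][w:(w + length - 1L)] <- cons
      off <- sample.int(length, 1L)
      ref <- sample(setdiff(seq_len(20L), cons[off]), 1L)
      prot[[pid]][w + off - 1L] <- ref
      recs[[k]] <- data.frame(protein_id = pid, position = w + off - 1L,
                              ref = AA_ALPHABET[ref],
                              alt = AA_ALPHABET[cons[off]],
                              sample = sprintf("S%02d", k %% 10L + 1L))
    } else {
      pos <- sample.int(proteinLength, 1L)
      ref <- prot[[pid]][pos]
      alt <- sample(setdiff(seq_len(20L), ref), 1L)
      recs[[k]] <- data.frame(protein_id = pid, position = pos,
                              ref = AA_ALPHABET[ref], alt = AA_ALPHABET[alt],
                              sample = sprintf("S%02d", k %% 10L + 1L))
    }
  }
  proteins <- vapply(prot, function(i)
    paste(AA_ALPHABET[i], collapse = ""), "")
  list(proteins = proteins, records = do.call(rbind, recs))
}

#' Write a synthetic cohort to disk in production input formats
#' @param cohort Result of [synthCohort()].
#' @param dir Output directory (created if missing).
#' @return Paths of the FASTA and TSV files written.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "proteins.fasta")
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(cohort$proteins), fa)
  tsv <- file.path(dir, "mutations.tsv")
  utils::write.table(cohort$records, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(proteins = fa, mutations = tsv)
}
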