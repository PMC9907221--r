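#' Expert mutation policy derived from binding data
#'
#' For every allele with enough qualified peptides, stores per-length
#' per-position amino-acid distributions (Laplace-smoothed empirical
#' frequencies). The expert mutates a peptide by picking the position with
#' the largest gap between the most popular residue's probability and the
#' current residue's probability, then sampling the replacement from that
#' position's distribution (excluding the current residue). Alleles without
#' data fall back to the profile of the most BLOSUM62-similar allele that
#' has data.
#'
#' @slot profiles List: allele -> list: length (character) -> 20 x L
#'   probability matrix (rows in canonical order).
#' @slot counts List: allele -> named integer vector of supporting peptide
#'   counts per length.
#' @slot pseudo Named character vector: pseudo sequences of the
#'   data-bearing alleles, used for nearest-allele fallback.
#' @export
setClass("ExpertPolicy",
  representation(profiles = "list", counts = "list", pseudo = "character"))

setMethod("show", "ExpertPolicy", function(object) {
  cat("ExpertPolicy over", length(object@profiles), "allele(s)\n")
  for (al in names(object@profiles))
    cat("  ", al, ": lengths ",
        paste(names(object@profiles[[al]]), collapse = ", "), "\n", sep = "")
})

#' Build an expert policy from a binding dataset
#'
#' @param dataset data.frame with columns allele, peptide, measurement (see
#'   [readBindingDataset()]).
#' @param pseudo Named character vector of pseudo sequences covering (at
#'   least) the dataset's alleles; used for nearest-allele fallback.
#' @param qualify Function mapping the measurement vector to a logical
#'   "qualified binder" vector. The default treats measurements in `[0, 1]`
#'   as presentation scores/labels qualified above 0.75, and larger values
#'   as quantitative affinities in nM qualified below 500.
#' @param minCount Minimum qualified peptides per (allele, length) for the
#'   length to enter the profile.
#' @param pseudocount Laplace pseudocount added per residue cell; the
#'   default 1 guarantees every masked sampling distribution stays valid.
#' @return An [ExpertPolicy-class].
#' @export
buildExpertPolicy <- function(dataset, pseudo,
                              qualify = defaultQualify,
                              minCount = 50L, pseudocount = 1) {
  stopifnot(all(c("allele", "peptide", "measurement") %in% names(dataset)))
  ok <- qualify(dataset$measurement)
  qualified <- dataset[ok, , drop = FALSE]
  profiles <- list(); counts <- list()
  for (al in unique(qualified$allele)) {
    peps <- qualified$peptide[qualified$allele == al]
    byLen <- split(peps, nchar(peps))
    byLen <- byLen[vapply(byLen, length, 0L) >= minCount]
    if (length(byLen) == 0L) next
    profiles[[al]] <- lapply(byLen, function(p)
      pwmMatrix(buildPWM(p, pseudocount = pseudocount)))
    counts[[al]] <- vapply(byLen, length, 0L)
  }
  if (length(profiles) == 0L)
    stop("no allele has >= ", minCount,
         " qualified peptides at any length; cannot build an expert policy")
  keep <- pseudo[names(pseudo) %in% names(profiles)]
  new("ExpertPolicy", profiles = profiles, counts = counts, pseudo = keep)
}

#' Default qualification rule for binding measurements
#'
#' Measurements within `[0, 1]` are read as presentation scores or binary
#' labels and qualify when `> 0.75`; larger values are read as binding
#' affinities in nM and qualify when `< 500`.
#' @param m Numeric measurement vector.
#' @return Logical vector.
#' @export
defaultQualify <- function(m) {
  if (all(m >= 0 & m <= 1, na.rm = TRUE)) m > 0.75 else m < 500
}

#' Alleles with profile data
#' @param expert An [ExpertPolicy-class].
#' @export
expertAlleles <- function(expert) names(expert@profiles)

#' Fetch a per-position distribution matrix for an allele and length
#'
#' Resolves directly when the allele has a profile at that length;
#' otherwise falls back via [nearestAllele()] using the query pseudo
#' sequence (required in that case).
#'
#' @param expert An [ExpertPolicy-class].
#' @param allele Allele name.
#' @param length Peptide length.
#' @param pseudo Query pseudo sequence, needed only for the fallback.
#' @return 20 x length probability matrix.
#' @export
expertProfile <- function(expert, allele, length, pseudo = NULL) {
  key <- as.character(length)
  prof <- expert@profiles[[allele]][[key]]
  if (!is.null(prof)) return(prof)
  if (is.null(pseudo))
    stop("no profile for allele ", allele, " at length ", length,
         " and no pseudo sequence supplied for nearest-allele fallback")
  # restrict candidates to alleles holding this length
  has <- vapply(expert@profiles, function(p) !is.null(p[[key]]), TRUE)
  cand <- expert@pseudo[names(expert@profiles)[has]]
  if (length(cand) == 0L)
    stop("no allele has a profile at length ", length)
  nn <- nearestAllele(pseudo, cand)
  expert@profiles[[nn$allele]][[key]]
}

#' Expert position selection
#'
#' Returns the position maximizing the gap between the probability of the
#' most popular residue at that position and the probability of the
#' peptide's current residue there; ties go to the lowest index.
#'
#' @param peptide Peptide string.
#' @param profile 20 x l probability matrix for the peptide's length.
#' @return 1-based position index.
#' @export
expertSelectPosition <- function(peptide, profile) {
  idx <- aaIndex(peptide, split = TRUE)
  if (ncol(profile) != length(idx))
    stop("profile length ", ncol(profile), " does not match peptide length ",
         length(idx))
  gaps <- vapply(seq_along(idx), function(i)
    max(profile[, i]) - profile[idx[i], i], numeric(1L))
  which.max(gaps)  # which.max breaks ties at the lowest index
}

#' Expert residue sampling
#'
#' Samples the replacement residue from the position's distribution with
#' the current residue excluded and the remaining mass renormalized.
#'
#' @param position 1-based position.
#' @param profile 20 x l probability matrix.
#' @param currentResidue The residue currently at `position`.
#' @return One-letter residue code, never equal to `currentResidue`.
#' @export
expertSampleResidue <- function(position, profile, currentResidue) {
  p <- profile[, position]
  p[aaIndex(currentResidue)] <- 0
  if (sum(p) <= 0)
    stop("degenerate distribution: all mass on the current residue")
  AA_ALPHABET[sample.int(20L, 1L, prob = p)]
}

#' One full expert action
#' @inheritParams expertSelectPosition
#' @return List with `position` and `residue`.
#' @export
expertAction <- function(peptide, profile) {
  i <- expertSelectPosition(peptide, profile)
  list(position = i,
       residue = expertSampleResidue(i, profile,
                                     substr(peptide, i, i)))
}

#' Most similar data-bearing allele by BLOSUM62 pseudo-sequence similarity
#'
#' Similarity between two 34-mers is the position-wise sum of BLOSUM62
#' scores, min-max normalized to `[0, 1]` over the candidate set at query
#' time. Ties are broken lexicographically by allele name.
#'
#' @param query 34-residue pseudo sequence.
#' @param registry Named character vector of candidate pseudo sequences.
#' @return List with `allele`, `similarity` (normalized) and `rawScore`.
#' @export
nearestAllele <- function(query, registry) {
  if (length(registry) == 0L) stop("empty pseudo-sequence registry")
  if (nchar(query) != 34L)
    stop("query pseudo sequence must have 34 residues")
  B <- blosum62()
  qi <- aaIndex(query, split = TRUE)
  raw <- vapply(registry, function(ps) {
    pi <- aaIndex(ps, split = TRUE)
    sum(B[cbind(qi, pi)])
  }, numeric(1L))
  rng <- range(raw)
  norm <- if (diff(rng) < 1e-12) rep(1, length(raw)) else
    (raw - rng[1L]) / diff(rng)
  ord <- order(-norm, names(registry))
  best <- ord[1L]
  list(allele = names(registry)[best], similarity = unname(norm[best]),
       rawScore = unname(raw[best]))
}

#' Serialize expert profiles as PWM TSV files
#' @param expert An [ExpertPolicy-class].
#' @param dir Output directory; one file `<allele>_L<length>.tsv` each.
#' @export
writeExpertProfiles <- function(expert, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (al in names(expert@profiles)) {
    for (len in names(expert@profiles[[al]])) {
      pwm <- newPWM(expert@profiles[[al]][[len]],
                    nPeptides = expert@counts[[al]][[len]])
      writePWM(pwm, file.path(dir, sprintf("%s_L%s.tsv",
                                           gsub("[:*]", "", al), len)))
    }
  }
  invisible(dir)
}
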