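#' The canonical amino-acid alphabet
#'
#' All encodings, PWM rows, expert profiles and the residue action head use
#' this fixed ordering of the 20 natural amino acids. Keeping a single
#' canonical order throughout the package prevents silent row/column
#' permutation bugs between modules.
#'
#' @format A character vector of the 20 one-letter amino-acid codes, in the
#'   order `"ACDEFGHIKLMNPQRSTVWY"`.
#' @export
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# package-local cache (BLOSUM62, parsed encodings)
.pepppo_cache <- new.env(parent = emptyenv())

#' Map residues to canonical alphabet indices
#'
#' @param x Character vector of single residues, or a single peptide string
#'   (when `split = TRUE` it is split into residues first).
#' @param split Split each element of `x` into individual characters.
#' @return Integer vector of 1-based indices into [AA_ALPHABET].
#' @examples
#' aaIndex("ACD", split = TRUE)
#' @export
aaIndex <- function(x, split = FALSE) {
  if (split) x <- unlist(strsplit(x, ""), use.names = FALSE)
  idx <- match(x, AA_ALPHABET)
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    stop("unknown residue(s): ", paste(bad, collapse = ", "),
         " (only the 20 canonical amino acids are supported)")
  }
  idx
}

#' Validate peptide sequences
#'
#' Checks that every sequence uses only the 20 canonical residues and, by
#' default, that its length lies in the 8-15 range handled by MHC Class I
#' presentation.
#'
#' @param peptides Character vector of peptide sequences.
#' @param minLen,maxLen Allowed length range (set both to `NA` to skip the
#'   length check).
#' @return `peptides`, invisibly, if valid; otherwise an error.
#' @export
validatePeptides <- function(peptides, minLen = 8L, maxLen = 15L) {
  stopifnot(is.character(peptides), length(peptides) >= 1L)
  lens <- nchar(peptides)
  if (!is.na(minLen) && any(lens < minLen | lens > maxLen)) {
    bad <- which(lens < minLen | lens > maxLen)[1L]
    stop("peptide length ", lens[bad], " outside allowed range [",
         minLen, ", ", maxLen, "]: ", peptides[bad])
  }
  aaIndex(paste(peptides, collapse = ""), split = TRUE)
  invisible(peptides)
}

#' Peptides as an integer index matrix
#'
#' Internal workhorse representation: one row per peptide, entries are
#' 1-based indices into [AA_ALPHABET]. All peptides must share one length.
#' @param peptides Character vector of equal-length peptides.
#' @return Integer matrix `n x l`.
#' @export
peptideMatrix <- function(peptides) {
  lens <- unique(nchar(peptides))
  if (length(lens) != 1L)
    stop("peptides must all have the same length; got lengths ",
         paste(sort(lens), collapse = ", "))
  matrix(aaIndex(paste(peptides, collapse = ""), split = TRUE),
         nrow = length(peptides), ncol = lens, byrow = TRUE)
}

#' @rdname peptideMatrix
#' @param mat Integer index matrix as produced by [peptideMatrix()].
#' @export
matrixToPeptides <- function(mat) {
  apply(mat, 1L, function(i) paste(AA_ALPHABET[i], collapse = ""))
}

#' The BLOSUM62 substitution matrix over the canonical alphabet
#'
#' Parses the bundled NCBI-format BLOSUM62 file and returns the 20x20
#' block restricted to the canonical alphabet, reordered to match
#' [AA_ALPHABET] rows and columns.
#'
#' @return Numeric 20x20 matrix of raw (integer-valued) BLOSUM62 scores.
#' @export
blosum62 <- function() {
  if (!is.null(.pepppo_cache$blosum62)) return(.pepppo_cache$blosum62)
  path <- system.file("extdata", "BLOSUM62.txt", package = "PepPPO",
                      mustWork = TRUE)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1L])))
  rownames(m) <- vapply(rows, `[[`, "", 1L)
  colnames(m) <- header
  m <- m[AA_ALPHABET, AA_ALPHABET]
  .pepppo_cache$blosum62 <- m
  m
}
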