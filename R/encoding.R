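#' @import methods
NULL

#' Residue encoding configuration
#'
#' Each residue is encoded by concatenating up to three blocks, in this fixed
#' order: a scaled BLOSUM62 row (20 values), a one-hot indicator (20 values)
#' and a learnable embedding row (`learnedDim` values, owned by the policy
#' network). The realized per-residue width is
#' `d = 20*useBlosum + 20*useOnehot + learnedDim` and must be positive.
#'
#' @slot useBlosum Include the BLOSUM62 block.
#' @slot useOnehot Include the one-hot block.
#' @slot learnedDim Width of the learnable embedding block (>= 0).
#' @slot blosumScale Multiplier applied to raw integer BLOSUM62 scores so the
#'   block stays O(1); the raw scores themselves are in half-bit units.
#' @export
setClass("EncodingConfig",
  representation(useBlosum = "logical", useOnehot = "logical",
                 learnedDim = "integer", blosumScale = "numeric"),
  prototype(useBlosum = TRUE, useOnehot = TRUE, learnedDim = 16L,
            blosumScale = 0.1),
  validity = function(object) {
    d <- 20L * object@useBlosum + 20L * object@useOnehot + object@learnedDim
    if (object@learnedDim < 0L) return("learnedDim must be >= 0")
    if (d <= 0L) return("encoding width d must be positive")
    TRUE
  })

#' @param useBlosum,useOnehot,learnedDim,blosumScale See slot docs.
#' @rdname EncodingConfig-class
#' @export
encodingConfig <- function(useBlosum = TRUE, useOnehot = TRUE,
                           learnedDim = 16L, blosumScale = 0.1) {
  new("EncodingConfig", useBlosum = useBlosum, useOnehot = useOnehot,
      learnedDim = as.integer(learnedDim), blosumScale = blosumScale)
}

#' Realized per-residue encoding width
#' @param cfg An [EncodingConfig-class] object.
#' @return Integer width d.
#' @export
encodingWidth <- function(cfg) {
  20L * cfg@useBlosum + 20L * cfg@useOnehot + cfg@learnedDim
}

#' Per-residue encoding codebook
#'
#' Builds the 20 x d matrix whose row r is the full encoding of residue
#' `AA_ALPHABET[r]`. Encoding any sequence is then a row-indexing operation.
#'
#' @param cfg An [EncodingConfig-class].
#' @param learnedTable `20 x learnedDim` matrix of learned embeddings (the
#'   policy owns these); may be `NULL` when `learnedDim == 0`.
#' @return Numeric `20 x d` matrix.
#' @export
encodingCodebook <- function(cfg, learnedTable = NULL) {
  blocks <- list()
  if (cfg@useBlosum) blocks <- c(blocks, list(blosum62() * cfg@blosumScale))
  if (cfg@useOnehot) blocks <- c(blocks, list(diag(20)))
  if (cfg@learnedDim > 0L) {
    if (is.null(learnedTable))
      stop("learnedTable required when learnedDim > 0")
    stopifnot(nrow(learnedTable) == 20L,
              ncol(learnedTable) == cfg@learnedDim)
    blocks <- c(blocks, list(learnedTable))
  }
  cb <- do.call(cbind, blocks)
  rownames(cb) <- AA_ALPHABET
  cb
}

#' Column indices of the learned block inside the codebook
#' @inheritParams encodingCodebook
#' @return Integer vector (empty when no learned block).
#' @export
learnedColumns <- function(cfg) {
  d <- encodingWidth(cfg)
  if (cfg@learnedDim == 0L) return(integer(0))
  (d - cfg@learnedDim + 1L):d
}

#' Encode a single residue
#'
#' @param residue One-letter amino-acid code.
#' @inheritParams encodingCodebook
#' @return Numeric vector of width `encodingWidth(cfg)`, the concatenation
#'   BLOSUM block (if enabled), one-hot block (if enabled), learned block.
#' @export
encodeResidue <- function(residue, cfg, learnedTable = NULL) {
  idx <- aaIndex(residue)
  stopifnot(length(idx) == 1L)
  encodingCodebook(cfg, learnedTable)[idx, ]
}

#' Encode a peptide as an l x d matrix
#'
#' Row i is the encoding of residue i, so row order follows sequence order.
#' @param peptide Peptide string (length 8-15, canonical residues only).
#' @inheritParams encodingCodebook
#' @export
encodePeptide <- function(peptide, cfg, learnedTable = NULL) {
  validatePeptides(peptide)
  idx <- aaIndex(peptide, split = TRUE)
  encodingCodebook(cfg, learnedTable)[idx, , drop = FALSE]
}

#' Encode an MHC pseudo sequence as a 34 x d matrix
#'
#' MHC Class I proteins are represented by the 34 residues lining the
#' peptide-binding groove (the pseudo sequence); distinct alleles may share
#' a pseudo sequence and then receive identical encodings.
#' @param pseudo 34-residue pseudo sequence string.
#' @inheritParams encodingCodebook
#' @export
encodeMHC <- function(pseudo, cfg, learnedTable = NULL) {
  if (nchar(pseudo) != 34L)
    stop("MHC pseudo sequence must have exactly 34 residues; got ",
         nchar(pseudo))
  idx <- aaIndex(pseudo, split = TRUE)
  encodingCodebook(cfg, learnedTable)[idx, , drop = FALSE]
}
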