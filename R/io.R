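#' Read MHC pseudo sequences
#'
#' Accepts either FASTA (record id = allele name, sequence = 34-mer) or a
#' two-column tab-separated file `allele<TAB>pseudo_sequence` (with or
#' without a header line). Every sequence must be exactly 34 canonical
#' residues.
#'
#' @param path File path.
#' @param format `"auto"` (sniff: leading `>` means FASTA), `"fasta"` or
#'   `"tsv"`.
#' @return Named character vector: names are allele names, values are the
#'   34-residue pseudo sequences.
#' @export
readPseudoSequences <- function(path, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, ">")) "fasta" else "tsv"
  }
  if (format == "fasta") {
    ss <- Biostrings::readAAStringSet(path)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = c("allele", "pseudo"))
    # tolerate a header row
    if (identical(tolower(df$allele[1L]), "allele")) df <- df[-1L, ]
    out <- df$pseudo
    names(out) <- df$allele
  }
  bad <- nchar(out) != 34L
  if (any(bad))
    stop("pseudo sequence for ", names(out)[bad][1L], " has length ",
         nchar(out[bad][1L]), "; expected 34")
  validatePeptides(unname(out), minLen = NA)
  out
}

#' Write pseudo sequences as TSV
#' @param pseudo Named character vector (allele -> 34-mer).
#' @param path Output path.
#' @export
writePseudoSequences <- function(pseudo, path) {
  utils::write.table(
    data.frame(allele = names(pseudo), pseudo_sequence = unname(pseudo)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a binding-affinity dataset
#'
#' Tab-separated with header: `allele<TAB>peptide<TAB>measurement`. The
#' measurement column may hold a quantitative affinity (nM), a presentation
#' score, or a 0/1 label; qualification is decided downstream by
#' [buildExpertPolicy()].
#'
#' @param path File path.
#' @return data.frame with columns allele, peptide, measurement.
#' @export
readBindingDataset <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("allele", "peptide", "measurement") %in% names(df)))
  validatePeptides(df$peptide)
  df
}

#' @rdname readBindingDataset
#' @param dataset data.frame as returned by [readBindingDataset()].
#' @export
writeBindingDataset <- function(dataset, path) {
  utils::write.table(dataset, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read protein sequences from FASTA
#' @param path FASTA file.
#' @return Named character vector of protein sequences.
#' @export
readProteins <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Read point-mutation records
#'
#' MAF-like tab-separated file with header
#' `protein_id<TAB>position<TAB>ref<TAB>alt<TAB>sample` (sample optional).
#' Positions are 1-based.
#'
#' @param path File path.
#' @return data.frame with columns protein_id, position, ref, alt, sample.
#' @export
readMutationRecords <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "position", "ref", "alt") %in% names(df)))
  if (is.null(df$sample)) df$sample <- NA_character_
  df$position <- as.integer(df$position)
  if (any(df$ref == df$alt))
    stop("mutation records must have alt != ref")
  df
}

#' Write a PWM to TSV
#'
#' 20 data rows labelled by residue in canonical alphabet order, L columns
#' labelled by 1-based position, probabilities to 6 decimals.
#' @param pwm A [PWM-class] object.
#' @param path Output path.
#' @export
writePWM <- function(pwm, path) {
  m <- round(pwmMatrix(pwm), 6L)
  df <- data.frame(residue = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("residue", seq_len(ncol(m)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PWM written by [writePWM()]
#' @param path File path.
#' @return A [PWM-class] object.
#' @export
readPWM <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$residue
  m <- m[AA_ALPHABET, , drop = FALSE]
  # renormalize away the 6-decimal rounding
  m <- sweep(m, 2L, colSums(m), "/")
  newPWM(m, nPeptides = NA_integer_)
}

#' Export PWMs in MEME minimal motif format
#'
#' Write-only interoperability export; background frequencies are uniform.
#' @param pwms Named list of [PWM-class] objects (names become motif ids).
#' @param path Output path.
#' @export
writeMEME <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACDEFGHIKLMNPQRSTVWY", "",
               "Background letter frequencies",
               paste(paste(AA_ALPHABET, "0.05000"), collapse = " "), ""),
             con)
  for (nm in names(pwms)) {
    m <- pwmMatrix(pwms[[nm]])
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 20 w= %d nsites= %d E= 0",
      ncol(m), max(1L, nPeptides(pwms[[nm]]), na.rm = TRUE)), con)
    for (j in seq_len(ncol(m)))
      writeLines(paste(sprintf("%.6f", m[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}
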