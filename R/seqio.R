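# Sequence containers and standard-format I/O.
#
# Sequence sets (contigs, haplotypes, consensus loci) are named character
# vectors over {A,C,G,T,N}. Read sets are data.frames with columns
# id / seq / qual, where qual is a Sanger Phred+33 string of the same length
# as seq. Biostrings does the file-format work.

#' Convert a Phred quality score to an error probability
#'
#' A Phred score Q encodes a base-call (or genotype-call) error probability
#' of 10^(-Q/10), so Q = 20 corresponds to 0.01 and Q = 13 to ~0.05.
#'
#' @param q numeric vector of Phred scores (>= 0).
#' @return numeric vector of error probabilities.
#' @export
#' @examples
#' phred_error_prob(20)  # 0.01
phred_error_prob <- function(q) {
  if (any(q < 0)) stop("Phred scores must be >= 0")
  10^(-q / 10)
}

#' Decode a Phred+33 quality string into integer scores
#' @param qual character vector of Phred+33 strings.
#' @return list of integer vectors (one per input string).
#' @export
phred_decode <- function(qual) {
  lapply(qual, function(s) utf8ToInt(s) - 33L)
}

#' Encode integer Phred scores as a Phred+33 string
#' @param q integer vector of Phred scores.
#' @return single character string.
#' @export
phred_encode <- function(q) {
  intToUtf8(as.integer(q) + 33L)
}

#' Read a FASTA file into a named character vector
#' @param path file path (gzip transparent).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector of sequences to FASTA
#' @param seqs named character vector.
#' @param path output file path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a FASTQ file into a read-set data.frame
#'
#' @param path FASTQ path (Sanger Phred+33; gzip transparent).
#' @return data.frame with columns id, seq, qual.
#' @export
read_fastq <- function(path) {
  # the reader warns that metadata columns are dropped; that is expected
  muffle <- function(expr) withCallingHandlers(expr,
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  x <- muffle(Biostrings::readQualityScaledDNAStringSet(path))
  qual <- muffle(as.character(Biostrings::quality(x)))
  data.frame(
    id = sub("\\s.*$", "", names(x)),
    seq = as.character(x),
    qual = qual,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write a read-set data.frame to FASTQ (Sanger Phred+33)
#' @param reads data.frame with columns id, seq, qual.
#' @param path output path; a trailing `.gz` compresses.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$seq),
    Biostrings::PhredQuality(reads$qual)
  )
  names(x) <- reads$id
  Biostrings::writeQualityScaledXStringSet(x, path,
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Reverse-complement sequences
#' @param seqs character vector of DNA sequences.
#' @return character vector, names preserved.
#' @export
revcomp <- function(seqs) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  names(out) <- names(seqs)
  out
}

# IUPAC code for an unordered base pair; homozygotes map to the base itself.
iupac_code <- function(base1, base2) {
  codes <- c(
    "AA" = "A", "CC" = "C", "GG" = "G", "TT" = "T",
    "AC" = "M", "AG" = "R", "AT" = "W",
    "CG" = "S", "CT" = "Y", "GT" = "K"
  )
  key <- paste0(pmin(base1, base2), pmax(base1, base2))
  unname(codes[key])
}
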