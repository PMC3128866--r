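# Local similarity search and reciprocal-best-hit logic.
#
# An internal seed-and-extend aligner stands in for BLASTn: exact k-mer seeds
# on both strands, ungapped extension along each seeded diagonal maximising
# match - 2*mismatch, best local segment kept per query/subject pair.
# Externally produced tabular hits (BLAST outfmt 6) can be ingested instead.

#' Find local similarity hits between two sequence sets
#'
#' Seed-and-extend search: exact k-mer matches (both strands) seed ungapped
#' extension along their diagonal; per query/subject pair the best-scoring
#' local segment (match +1, mismatch -2) is reported. Any pair sharing a
#' >= 95%-identity region of at least 2k bp is found.
#'
#' @param queries,subjects named character vectors of sequences.
#' @param min_aln_len minimum aligned length (bp) to report.
#' @param min_identity minimum identity over aligned columns.
#' @param k seed length (default 16).
#' @param skip_same_id drop hits where query and subject share an id
#'   (for self-comparisons of one set).
#' @return data.frame: query, subject, identity, aln_len, q_start, q_end,
#'   s_start, s_end (half-open, 0-based; query span on the original
#'   orientation), strand, score.
#' @export
find_hits <- function(queries, subjects, min_aln_len = 30L, min_identity = 0.0,
                      k = 16L, skip_same_id = FALSE) {
  stopifnot(length(queries) > 0, length(subjects) > 0)
  if (k > min(nchar(subjects)) || k > min(nchar(queries)))
    stop("seed length k exceeds the shortest sequence")
  df <- cpp_find_hits(unname(queries), names(queries),
                      unname(subjects), names(subjects),
                      as.integer(k), as.integer(min_aln_len),
                      as.numeric(min_identity), skip_same_id, 1L, -2L)
  # deterministic order
  df[order(df$query, df$subject), , drop = FALSE]
}

#' Reduce a directed hit table to the best subject per query
#'
#' @param hits data.frame from [find_hits()] (one directed comparison).
#' @return named character vector: query id -> best subject id (max score;
#'   ties broken by lexicographically smallest subject id).
#' @export
best_hit_table <- function(hits) {
  if (nrow(hits) == 0L) return(character(0))
  ord <- order(hits$query, -hits$score, hits$subject)
  h <- hits[ord, , drop = FALSE]
  first <- !duplicated(h$query)
  stats::setNames(h$subject[first], h$query[first])
}

#' Reciprocal best hits between two samples
#'
#' @param fwd,rev best-hit maps from [best_hit_table()] for the two search
#'   directions (A vs B and B vs A).
#' @return data.frame with columns a, b: pairs where each is the other's
#'   best hit.
#' @export
reciprocal_best_hits <- function(fwd, rev) {
  if (length(fwd) == 0L || length(rev) == 0L)
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  a <- names(fwd)
  b <- unname(fwd)
  ok <- !is.na(rev[b]) & rev[b] == a
  ok[is.na(ok)] <- FALSE
  out <- data.frame(a = a[ok], b = b[ok], stringsAsFactors = FALSE)
  out[order(out$a), , drop = FALSE]
}

#' Write a hit table to TSV
#' @param hits hit data.frame.
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a hit table from TSV (native or BLAST outfmt 6)
#'
#' Native tables are those written by [write_hits()]. BLAST outfmt-6 files
#' (12 columns, no header) are mapped onto the same structure: identity is
#' rescaled to a fraction, coordinates to half-open 0-based, strand inferred
#' from subject coordinate order, and bit score rounded to integer.
#'
#' @param path TSV path.
#' @param format "native" or "blast6".
#' @return hit data.frame as from [find_hits()].
#' @export
read_hits <- function(path, format = c("native", "blast6")) {
  format <- match.arg(format)
  if (format == "native") {
    return(read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE))
  }
  b <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  names(b) <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
                "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  minus <- b$sstart > b$send
  data.frame(
    query = b$query, subject = b$subject,
    identity = b$pident / 100, aln_len = b$length,
    q_start = b$qstart - 1L, q_end = b$qend,
    s_start = ifelse(minus, b$send, b$sstart) - 1L,
    s_end = ifelse(minus, b$sstart, b$send),
    strand = ifelse(minus, "-", "+"),
    score = as.integer(round(b$bitscore)),
    stringsAsFactors = FALSE
  )
}
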