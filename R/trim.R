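# 3'-quality trimming of short reads.
#
# Reads are truncated at the first run of `consecutive` bases whose Phred
# quality drops below `q_threshold`, after stripping terminal runs of 'N'.
# Reads shorter than `min_length` after trimming are discarded.

#' Construct a read-trimming policy
#'
#' @param q_threshold Phred score below which bases count as low quality
#'   (default 20, i.e. error probability 0.01).
#' @param consecutive number of consecutive low-quality bases that triggers
#'   truncation (default 2).
#' @param min_length minimum post-trim read length in bp (default 20);
#'   shorter reads are discarded.
#' @return a `trim_policy` list.
#' @export
trim_policy <- function(q_threshold = 20L, consecutive = 2L, min_length = 20L) {
  stopifnot(q_threshold >= 0, consecutive >= 1, min_length >= 1)
  structure(list(
    q_threshold = as.integer(q_threshold),
    consecutive = as.integer(consecutive),
    min_length = as.integer(min_length)
  ), class = "trim_policy")
}

#' Trim a single read
#'
#' Strips leading/trailing runs of 'N', then scans 5' to 3' and truncates
#' immediately before the first position where `consecutive` bases in a row
#' all have quality below the threshold. A lone sub-threshold base does not
#' trigger truncation, but everything after a trigger is removed regardless
#' of quality.
#'
#' @param seq read sequence (single string).
#' @param qual Phred+33 quality string of the same length.
#' @param policy a [trim_policy()].
#' @return list with `seq`, `qual` and `kept`; `kept = FALSE` marks a
#'   discarded read (empty, or shorter than `min_length` after trimming).
#' @export
trim_read <- function(seq, qual, policy = trim_policy()) {
  if (is.na(seq) || nchar(seq) == 0L)
    return(list(seq = "", qual = "", kept = FALSE))
  if (is.na(qual) || nchar(qual) != nchar(seq))
    stop("read has missing or mismatched qualities")
  df <- trim_reads(data.frame(id = "r", seq = seq, qual = qual,
                              stringsAsFactors = FALSE), policy)
  if (nrow(df) == 0L) return(list(seq = "", qual = "", kept = FALSE))
  list(seq = df$seq, qual = df$qual, kept = TRUE)
}

#' Trim a read set
#'
#' Vectorised form of [trim_read()]: applies N-stripping, the
#' consecutive-low-quality truncation rule and the minimum-length filter to
#' every read, dropping discarded reads.
#'
#' @param reads data.frame with columns id, seq, qual.
#' @param policy a [trim_policy()].
#' @return data.frame of surviving reads (same columns).
#' @export
trim_reads <- function(reads, policy = trim_policy()) {
  if (nrow(reads) == 0L) return(reads)
  if (any(nchar(reads$qual) != nchar(reads$seq)))
    stop("reads with missing or mismatched qualities")

  # strip terminal N runs (sequence and qualities in step)
  lead <- attr(regexpr("^N+", reads$seq), "match.length")
  lead[lead < 0L] <- 0L
  trail <- attr(regexpr("N+$", reads$seq), "match.length")
  trail[trail < 0L] <- 0L
  from <- lead + 1L
  to <- nchar(reads$seq) - trail
  to <- pmax(to, from - 1L)  # all-N reads collapse to empty
  seq <- substr(reads$seq, from, to)
  qual <- substr(reads$qual, from, to)
  len <- nchar(seq)

  # first window of `consecutive` sub-threshold scores, over all reads at once
  keep_len <- len
  nz <- len > 0L
  if (any(nz)) {
    q <- utf8ToInt(paste(qual[nz], collapse = "")) - 33L
    rid <- rep.int(seq_len(sum(nz)), len[nz])
    low <- q < policy$q_threshold
    k <- policy$consecutive
    trig <- low
    if (k > 1L) {
      for (s in seq_len(k - 1L)) {
        nlow <- c(low[-seq_len(s)], rep(FALSE, s))
        nsame <- c(rid[-seq_len(s)], rep(-1L, s)) == rid
        trig <- trig & nlow & nsame
      }
    }
    pos_local <- sequence(len[nz])
    hit <- which(trig)
    if (length(hit) > 0L) {
      first <- !duplicated(rid[hit])
      cut_reads <- rid[hit][first]
      keep_len[nz][cut_reads] <- pos_local[hit][first] - 1L
    }
  }

  seq <- substr(seq, 1L, keep_len)
  qual <- substr(qual, 1L, keep_len)
  ok <- keep_len >= policy$min_length
  data.frame(id = reads$id[ok], seq = seq[ok], qual = qual[ok],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Trim paired reads, keeping only pairs where both mates survive
#'
#' Mates are trimmed independently; by default a pair is dropped when either
#' mate fails the length filter, so downstream fragment counting always sees
#' complete pairs.
#'
#' @param r1,r2 read-set data.frames (same order, matching pair ids).
#' @param policy a [trim_policy()].
#' @param orphan_policy "drop_pair" (default) or "keep_orphans".
#' @return list with trimmed `r1` and `r2` (and `orphans` when kept).
#' @export
trim_pairs <- function(r1, r2, policy = trim_policy(),
                       orphan_policy = c("drop_pair", "keep_orphans")) {
  orphan_policy <- match.arg(orphan_policy)
  stopifnot(nrow(r1) == nrow(r2))
  t1 <- trim_reads(r1, policy)
  t2 <- trim_reads(r2, policy)
  key1 <- sub("/[12]$", "", t1$id)
  key2 <- sub("/[12]$", "", t2$id)
  shared <- intersect(key1, key2)
  out <- list(r1 = t1[match(shared, key1), , drop = FALSE],
              r2 = t2[match(shared, key2), , drop = FALSE])
  rownames(out$r1) <- rownames(out$r2) <- NULL
  if (orphan_policy == "keep_orphans") {
    out$orphans <- rbind(t1[!(key1 %in% shared), , drop = FALSE],
                         t2[!(key2 %in% shared), , drop = FALSE])
    rownames(out$orphans) <- NULL
  }
  out
}
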