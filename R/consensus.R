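# Consensus transcriptome construction.
#
# From per-sample contig sets: collapse near-identical redundancy, group
# orthologs by four-way reciprocal best hits, build per-group consensus
# sequences (overhangs of the longest member retained), extend consensuses
# with unplaced contigs, join fragments that share a guide protein, admit
# long singletons with strong guide hits, and summarise assembly statistics.

#' Ortholog grouping criteria
#'
#' @param min_aln_len minimum alignment length in bp (default 200).
#' @param min_identity minimum sequence identity (default 0.90).
#' @param min_aligned_prop minimum aligned proportion of the shorter
#'   sequence (default 0.80, applied as strictly greater).
#' @return a `grouping_criteria` list.
#' @export
grouping_criteria <- function(min_aln_len = 200L, min_identity = 0.90,
                              min_aligned_prop = 0.80) {
  stopifnot(min_aln_len > 0, min_identity > 0, min_identity <= 1,
            min_aligned_prop > 0, min_aligned_prop <= 1)
  structure(list(min_aln_len = as.integer(min_aln_len),
                 min_identity = min_identity,
                 min_aligned_prop = min_aligned_prop),
            class = "grouping_criteria")
}

#' Collapse redundant contigs within a set
#'
#' Contigs shorter than `min_contig_len` are discarded. Any pair more than
#' 99% identical over at least 95% of the length of the shorter contig is
#' collapsed onto the longer contig (ties broken by lexicographic id),
#' applied transitively: contigs are processed in decreasing length order and
#' a contig is removed when it loses such a pair against a retained contig.
#'
#' @param contigs named character vector.
#' @param min_contig_len minimum contig length in bp (default 100).
#' @param min_identity identity threshold, strictly exceeded (default 0.99).
#' @param min_cover_frac required fraction of the shorter length (default 0.95).
#' @return named character vector of retained contigs.
#' @export
collapse_redundant <- function(contigs, min_contig_len = 100L,
                               min_identity = 0.99, min_cover_frac = 0.95) {
  contigs <- contigs[nchar(contigs) >= min_contig_len]
  if (length(contigs) < 2L) return(contigs)
  hits <- find_hits(contigs, contigs, min_aln_len = 30L,
                    min_identity = min_identity, skip_same_id = TRUE)
  len <- nchar(contigs)
  qual <- hits$identity > min_identity &
    hits$aln_len >= min_cover_frac * pmin(len[hits$query], len[hits$subject])
  hits <- hits[qual, , drop = FALSE]
  if (nrow(hits) == 0L) return(contigs)
  # unordered qualifying pairs
  a <- pmin(hits$query, hits$subject)
  b <- pmax(hits$query, hits$subject)
  pairs <- unique(data.frame(a = a, b = b, stringsAsFactors = FALSE))
  partners <- split(c(pairs$b, pairs$a), c(pairs$a, pairs$b))
  removed <- character(0)
  ord_ids <- names(contigs)[order(-len, names(contigs))]
  for (id in ord_ids) {   # deterministic: decreasing length, then id
    if (id %in% removed) next
    for (p in partners[[id]]) {
      loser_is_p <- len[p] < len[id] || (len[p] == len[id] && p > id)
      if (loser_is_p && !(p %in% removed)) removed <- c(removed, p)
    }
  }
  contigs[setdiff(names(contigs), removed)]
}

#' Build ortholog groups by four-way reciprocal best hits
#'
#' All pairwise sample comparisons are searched in both directions; pairs
#' that are each other's best hit and satisfy the grouping criteria
#' (alignment length, identity, aligned proportion of the shorter sequence)
#' are merged into groups by transitive closure. Groups are restricted to at
#' least `min_samples` distinct samples with at most one member per sample;
#' when a closure pulls in two contigs of one sample, the member with the
#' higher summed hit score stays and the loser returns to the leftovers.
#'
#' @param samples named list of contig sets (named character vectors);
#'   contig ids must be globally unique.
#' @param criteria a [grouping_criteria()].
#' @param min_samples minimum distinct samples per group (2 or 3, default 2).
#' @return list: `groups` (each with id, members = sample -> contig id),
#'   `leftovers` (contig ids in no group), `edges` (the filtered RBH table).
#' @export
build_groups <- function(samples, criteria = grouping_criteria(),
                         min_samples = 2L) {
  stopifnot(length(samples) >= 2L, !is.null(names(samples)))
  all_ids <- unlist(lapply(samples, names), use.names = FALSE)
  if (anyDuplicated(all_ids)) stop("contig ids must be unique across samples")
  sample_of <- rep(names(samples), vapply(samples, length, integer(1)))
  names(sample_of) <- all_ids
  seqs <- unlist(unname(samples))
  len <- nchar(seqs)

  pairs <- utils::combn(names(samples), 2, simplify = FALSE)
  edges <- list()
  for (pr in pairs) {
    A <- samples[[pr[1]]]; B <- samples[[pr[2]]]
    hf <- find_hits(A, B, min_aln_len = criteria$min_aln_len,
                    min_identity = criteria$min_identity)
    hr <- find_hits(B, A, min_aln_len = criteria$min_aln_len,
                    min_identity = criteria$min_identity)
    rbh <- reciprocal_best_hits(best_hit_table(hf), best_hit_table(hr))
    if (nrow(rbh) == 0L) next
    key <- paste(hf$query, hf$subject)
    rows <- hf[match(paste(rbh$a, rbh$b), key), , drop = FALSE]
    ok <- rows$aln_len > criteria$min_aligned_prop *
      pmin(len[rows$query], len[rows$subject])
    rows <- rows[ok, , drop = FALSE]
    if (nrow(rows) > 0L) edges[[paste(pr, collapse = "|")]] <- rows
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(query = character(0), subject = character(0),
               score = integer(0), stringsAsFactors = FALSE)
  rownames(edges) <- NULL

  # transitive closure (union-find)
  parent <- stats::setNames(seq_along(all_ids), all_ids)
  findroot <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(edges))) {
    i <- findroot(match(edges$query[r], all_ids))
    j <- findroot(match(edges$subject[r], all_ids))
    if (i != j) parent[max(i, j)] <- min(i, j)
  }
  root <- vapply(seq_along(all_ids), findroot, numeric(1))
  comp <- split(all_ids, root)
  comp <- comp[vapply(comp, length, integer(1)) >= 2L]

  score_sum <- stats::setNames(numeric(length(all_ids)), all_ids)
  for (r in seq_len(nrow(edges))) {
    score_sum[edges$query[r]] <- score_sum[edges$query[r]] + edges$score[r]
    score_sum[edges$subject[r]] <- score_sum[edges$subject[r]] + edges$score[r]
  }

  groups <- list()
  leftovers <- character(0)
  gi <- 0L
  for (members in comp[order(vapply(comp, min, character(1)))]) {
    keep <- character(0)
    for (s in unique(sample_of[members])) {
      cand <- members[sample_of[members] == s]
      best <- cand[order(-score_sum[cand], cand)][1]
      keep <- c(keep, best)
      leftovers <- c(leftovers, setdiff(cand, best))
    }
    if (length(keep) >= min_samples) {
      gi <- gi + 1L
      groups[[gi]] <- list(id = sprintf("cons%05d", gi),
                           members = stats::setNames(keep, sample_of[keep]))
    } else {
      leftovers <- c(leftovers, keep)
    }
  }
  leftovers <- sort(c(leftovers, setdiff(all_ids, unlist(lapply(comp, identity)))))
  list(groups = groups, leftovers = leftovers, edges = edges,
       sequences = seqs)
}

# orient `member` to `anchor` and return its 0-based offset on the anchor
# axis, using the best seed-and-extend hit; NULL when no hit is found
.place_on_anchor <- function(member, anchor, min_identity = 0.80) {
  h <- find_hits(stats::setNames(member, "q"), stats::setNames(anchor, "s"),
                 min_aln_len = min(30L, nchar(member), nchar(anchor)),
                 min_identity = min_identity,
                 k = min(16L, nchar(member), nchar(anchor)))
  if (nrow(h) == 0L) return(NULL)
  h <- h[which.max(h$score), ]
  if (h$strand == "+") {
    list(seq = member, offset = h$s_start - h$q_start)
  } else {
    len <- nchar(member)
    qs_rc <- len - h$q_end
    list(seq = unname(revcomp(member)), offset = h$s_start - qs_rc)
  }
}

#' Build the consensus sequence of an ortholog group
#'
#' Members are oriented to the group's longest member and placed by their
#' best ungapped alignment offset (members are >= 90% identical by
#' construction, so placement is column-exact for substitution-only data).
#' Each column takes the majority base; ties take the base of the longest
#' covering member. Overhangs of any member are retained, so the consensus
#' spans the union of the placed members.
#'
#' @param member_ids character vector of member contig ids.
#' @param seqs named character vector holding the member sequences.
#' @return a single named character vector (consensus), or NULL with a
#'   `diagnostic` attribute when a member fails to align to the anchor.
#' @export
consense <- function(member_ids, seqs) {
  ms <- seqs[member_ids]
  ord <- order(-nchar(ms), names(ms))
  ms <- ms[ord]
  anchor <- ms[[1]]
  placements <- list(list(seq = unname(anchor), offset = 0L))
  for (i in seq_along(ms)[-1]) {
    p <- .place_on_anchor(unname(ms[[i]]), unname(anchor))
    if (is.null(p)) {
      out <- NULL
      attr(out, "diagnostic") <- sprintf("member %s fails to align to anchor %s",
                                         names(ms)[i], names(ms)[1])
      return(out)
    }
    placements[[length(placements) + 1L]] <- p
  }
  offs <- vapply(placements, `[[`, numeric(1), "offset")
  lens <- vapply(placements, function(p) nchar(p$seq), numeric(1))
  lo <- min(offs); hi <- max(offs + lens)
  width <- hi - lo
  mat <- matrix(NA_character_, nrow = length(placements), ncol = width)
  for (i in seq_along(placements)) {
    p <- placements[[i]]
    cols <- (p$offset - lo) + seq_len(nchar(p$seq))
    mat[i, cols] <- strsplit(p$seq, "")[[1]]
  }
  bases <- c("A", "C", "G", "T")
  cnt <- vapply(bases, function(b) colSums(mat == b, na.rm = TRUE),
                numeric(width))
  if (width == 1L) cnt <- matrix(cnt, nrow = 1L)
  top <- max.col(cnt, ties.method = "first")
  maxn <- cnt[cbind(seq_len(width), top)]
  tied <- rowSums(cnt == maxn) > 1L
  out <- bases[top]
  out[maxn == 0] <- "N"
  for (j in which(tied & maxn > 0)) {
    for (i in seq_len(nrow(mat))) {   # rows already ordered longest first
      b <- mat[i, j]
      if (!is.na(b) && cnt[j, match(b, bases)] == maxn[j]) { out[j] <- b; break }
    }
  }
  paste(out, collapse = "")
}

#' Build all group consensus sequences
#'
#' @param grouping result of [build_groups()].
#' @return list: `consensus` (named character vector, one per group),
#'   `group_table` (group_id, sample, contig_id), `rejected` (diagnostics
#'   for groups whose members failed to align).
#' @export
consense_groups <- function(grouping) {
  consensus <- character(0)
  rows <- list()
  rejected <- character(0)
  for (g in grouping$groups) {
    cs <- consense(unname(g$members), grouping$sequences)
    if (is.null(cs)) {
      rejected[g$id] <- attr(cs, "diagnostic")
      next
    }
    consensus[g$id] <- cs
    rows[[length(rows) + 1L]] <- data.frame(
      group_id = g$id, sample = names(g$members),
      contig_id = unname(g$members), stringsAsFactors = FALSE)
  }
  list(consensus = consensus,
       group_table = if (length(rows) > 0) do.call(rbind, rows) else
         data.frame(group_id = character(0), sample = character(0),
                    contig_id = character(0), stringsAsFactors = FALSE),
       rejected = rejected)
}

# mismatch structure of `query` placed on `target` at 0-based `offset`;
# returns NULL if no overlap, else list(match = logical over overlap columns,
# from/to = 1-based target coords of the overlap)
.overlap_profile <- function(query, target, offset) {
  from <- max(0L, offset)
  to <- min(nchar(target), offset + nchar(query))
  if (to <= from) return(NULL)
  qv <- strsplit(substr(query, from - offset + 1L, to - offset), "")[[1]]
  tv <- strsplit(substr(target, from + 1L, to), "")[[1]]
  list(match = qv == tv, from = from + 1L, to = to)
}

.max_run <- function(x) {                    # longest run of TRUE
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Extend consensus sequences with unplaced contigs
#'
#' A leftover contig is merged into a consensus when its best hit has more
#' than `min_identity` identity over more than `min_overlap` bp, its aligned
#' overlap contains no unalignable block (no run of `max_mismatch_run` or
#' more consecutive mismatching columns), and its unaligned tail extends the
#' consensus beyond one end. Leftovers qualifying against two different
#' consensuses are left unmerged and logged as ambiguous; fully contained
#' leftovers are not merged. Applied iteratively until no further merges.
#'
#' @param consensus named character vector of consensus sequences.
#' @param leftovers named character vector of unplaced contigs.
#' @param min_identity identity threshold, strictly exceeded (default 0.95).
#' @param min_overlap overlap threshold in bp, strictly exceeded (default 50).
#' @param max_mismatch_run mismatch-run length treated as an unalignable
#'   segment (default 10).
#' @param max_rounds maximum extension sweeps (default 3).
#' @return list: `consensus` (updated), `placed` (merged leftover ids),
#'   `ambiguous` (skipped leftover ids), `log` (data.frame of events).
#' @export
incorporate_extensions <- function(consensus, leftovers,
                                   min_identity = 0.95, min_overlap = 50L,
                                   max_mismatch_run = 10L, max_rounds = 3L) {
  placed <- character(0); ambiguous <- character(0)
  log <- list()
  pool <- leftovers
  for (round in seq_len(max_rounds)) {
    pool <- pool[nchar(pool) > min(16L, min_overlap)]
    if (length(pool) == 0L) break
    hits <- find_hits(pool, consensus, min_aln_len = min_overlap + 1L,
                      min_identity = min_identity)
    hits <- hits[hits$identity > min_identity & hits$aln_len > min_overlap, ,
                 drop = FALSE]
    merged_this_round <- character(0)
    for (id in sort(unique(hits$query))) {
      h <- hits[hits$query == id, , drop = FALSE]
      cand <- list()
      for (r in seq_len(nrow(h))) {
        target <- h$subject[r]
        if (h$strand[r] == "+") {
          orient <- unname(pool[id]); off <- h$s_start[r] - h$q_start[r]
        } else {
          orient <- unname(revcomp(pool[id]))
          off <- h$s_start[r] - (nchar(pool[id]) - h$q_end[r])
        }
        prof <- .overlap_profile(orient, consensus[[target]], off)
        if (is.null(prof)) next
        if (.max_run(!prof$match) >= max_mismatch_run) next
        extends <- off < 0L || off + nchar(orient) > nchar(consensus[[target]])
        if (!extends) next
        cand[[length(cand) + 1L]] <- list(target = target, orient = orient,
                                          off = off)
      }
      targets <- unique(vapply(cand, `[[`, character(1), "target"))
      if (length(targets) == 0L) next
      if (length(targets) > 1L) {
        ambiguous <- c(ambiguous, id)
        log[[length(log) + 1L]] <- data.frame(
          event = "ambiguous_extension", contig = id,
          detail = paste(targets, collapse = ","), stringsAsFactors = FALSE)
        next
      }
      c1 <- cand[[1]]
      cons <- consensus[[c1$target]]
      left <- if (c1$off < 0L) substr(c1$orient, 1L, -c1$off) else ""
      rtail <- c1$off + nchar(c1$orient) - nchar(cons)
      right <- if (rtail > 0L)
        substr(c1$orient, nchar(c1$orient) - rtail + 1L, nchar(c1$orient)) else ""
      consensus[[c1$target]] <- paste0(left, cons, right)
      placed <- c(placed, id)
      merged_this_round <- c(merged_this_round, id)
      log[[length(log) + 1L]] <- data.frame(
        event = "extension", contig = id, detail = c1$target,
        stringsAsFactors = FALSE)
    }
    pool <- pool[setdiff(names(pool), c(merged_this_round, ambiguous))]
    if (length(merged_this_round) == 0L) break
  }
  list(consensus = consensus, placed = placed, ambiguous = ambiguous,
       log = if (length(log) > 0) do.call(rbind, log) else
         data.frame(event = character(0), contig = character(0),
                    detail = character(0), stringsAsFactors = FALSE))
}

# codon-table translation (Biostrings GENETIC_CODE); partial codons dropped,
# codons containing N translate to X
.translate_nt <- function(nt) {
  n <- (nchar(nt) %/% 3L) * 3L
  if (n == 0L) return("")
  codons <- substring(nt, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# identity-scored protein substitution matrix over the AA alphabet
.aa_identity_matrix <- function(match = 2L, mismatch = -1L) {
  alph <- Biostrings::AA_ALPHABET
  m <- matrix(mismatch, length(alph), length(alph),
              dimnames = list(alph, alph))
  diag(m) <- match
  m
}

#' Match sequences against guide proteins by translated alignment
#'
#' Each sequence is translated in all six frames; exact protein 8-mers
#' shortlist candidate guides, and the best candidate frame is aligned to
#' the guide by local dynamic programming (identity scoring).
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param guides named character vector of guide protein sequences.
#' @param kmer protein seed length (default 8).
#' @return data.frame: id, guide, strand, frame, g_start, g_end (1-based
#'   residue interval on the guide), aa_len, identity, score. Sequences with
#'   no candidate guide are absent.
#' @export
match_guides <- function(seqs, guides, kmer = 8L) {
  # guide k-mer index
  gl <- nchar(guides)
  keep <- gl >= kmer
  gidx <- list()
  for (gn in names(guides)[keep]) {
    n <- nchar(guides[[gn]])
    kms <- unique(substring(guides[[gn]], 1:(n - kmer + 1L), kmer:n))
    for (km in kms) gidx[[km]] <- c(gidx[[km]], gn)
  }
  submat <- .aa_identity_matrix()
  rows <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    best <- NULL
    for (strand in c("+", "-")) {
      nt <- if (strand == "+") s else unname(revcomp(s))
      for (fr in 0:2) {
        aalen <- (nchar(nt) - fr) %/% 3L
        if (aalen < kmer) next
        aa <- .translate_nt(substr(nt, fr + 1L, nchar(nt)))
        kms <- substring(aa, 1:(nchar(aa) - kmer + 1L), kmer:nchar(aa))
        cand <- unlist(gidx[unique(kms)], use.names = FALSE)
        if (is.null(cand) || length(cand) == 0L) next
        top <- names(sort(table(cand), decreasing = TRUE))[1]
        aln <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(aa), Biostrings::AAString(guides[[top]]),
          type = "local", substitutionMatrix = submat,
          gapOpening = 10, gapExtension = 4)
        sc <- Biostrings::score(aln)
        if (is.null(best) || sc > best$score) {
          pat <- as.character(Biostrings::alignedPattern(aln))
          sub <- as.character(Biostrings::alignedSubject(aln))
          pv <- strsplit(pat, "")[[1]]; sv <- strsplit(sub, "")[[1]]
          ident <- mean(pv == sv & pv != "-")
          best <- list(guide = top, strand = strand, frame = fr + 1L,
                       g_start = Biostrings::start(Biostrings::subject(aln)),
                       g_end = Biostrings::end(Biostrings::subject(aln)),
                       aa_len = length(pv), identity = ident, score = sc)
        }
      }
    }
    if (!is.null(best))
      rows[[length(rows) + 1L]] <- data.frame(id = id, best,
                                              stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(id = character(0), guide = character(0),
                      strand = character(0), frame = integer(0),
                      g_start = integer(0), g_end = integer(0),
                      aa_len = integer(0), identity = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Join consensus fragments that share a guide protein
#'
#' Consensuses whose best guide is shared, whose guide-residue intervals
#' overlap by at most `overlap_tolerance` residues, and which order
#' consistently along the guide are concatenated in guide order with an
#' N-spacer of three times the implied residue gap. Fragments with
#' conflicting order are left unjoined and logged.
#'
#' @param consensus named character vector.
#' @param guides named character vector of guide proteins.
#' @param overlap_tolerance maximum residue overlap (default 15).
#' @param guide_hits optional precomputed [match_guides()] table.
#' @return list: `consensus` (updated set), `joined` (data.frame: new_id,
#'   parts, guide), `log`.
#' @export
join_fragments <- function(consensus, guides, overlap_tolerance = 15L,
                           guide_hits = NULL) {
  if (is.null(guide_hits)) guide_hits <- match_guides(consensus, guides)
  log <- list()
  joined_rows <- list()
  if (nrow(guide_hits) == 0L)
    return(list(consensus = consensus,
                joined = data.frame(new_id = character(0), parts = character(0),
                                    guide = character(0), stringsAsFactors = FALSE),
                log = data.frame()))
  for (gn in sort(unique(guide_hits$guide))) {
    gh <- guide_hits[guide_hits$guide == gn, , drop = FALSE]
    gh <- gh[gh$id %in% names(consensus), , drop = FALSE]
    if (nrow(gh) < 2L) next
    gh <- gh[order(gh$g_start, gh$g_end, gh$id), , drop = FALSE]
    overlaps <- gh$g_end[-nrow(gh)] - gh$g_start[-1] + 1L
    consistent <- all(overlaps <= overlap_tolerance) &&
      all(diff(gh$g_end) > 0) && all(diff(gh$g_start) > 0)
    if (!consistent) {
      log[[length(log) + 1L]] <- data.frame(
        event = "order_conflict", guide = gn,
        detail = paste(gh$id, collapse = ","), stringsAsFactors = FALSE)
      next
    }
    parts <- character(nrow(gh))
    for (i in seq_len(nrow(gh))) {
      s <- consensus[[gh$id[i]]]
      parts[i] <- if (gh$strand[i] == "-") unname(revcomp(s)) else s
    }
    gaps <- pmax(0L, gh$g_start[-1] - gh$g_end[-nrow(gh)] - 1L)
    pieces <- parts[1]
    for (i in seq_along(gaps))
      pieces <- paste0(pieces, strrep("N", 3L * gaps[i]), parts[i + 1L])
    new_id <- paste0(gh$id[1], "_joined")
    consensus <- consensus[setdiff(names(consensus), gh$id)]
    consensus[new_id] <- pieces
    joined_rows[[length(joined_rows) + 1L]] <- data.frame(
      new_id = new_id, parts = paste(gh$id, collapse = ","), guide = gn,
      stringsAsFactors = FALSE)
  }
  list(consensus = consensus,
       joined = if (length(joined_rows) > 0) do.call(rbind, joined_rows) else
         data.frame(new_id = character(0), parts = character(0),
                    guide = character(0), stringsAsFactors = FALSE),
       log = if (length(log) > 0) do.call(rbind, log) else data.frame())
}

#' Admit long unplaced singletons with strong guide-protein hits
#'
#' Leftovers of at least `min_len` bp whose translated guide hit spans at
#' least `min_aa_len` residues at `min_aa_identity` identity or better are
#' appended to the consensus set; the combined set is then redundancy
#' collapsed.
#'
#' @param consensus named character vector.
#' @param leftovers named character vector of unplaced contigs.
#' @param guides named character vector of guide proteins.
#' @param min_len length threshold in bp (default 1000).
#' @param min_aa_len minimum aligned residues (default 50).
#' @param min_aa_identity minimum identity of the protein alignment
#'   (default 0.60).
#' @return list: `consensus` (collapsed combined set), `added` (singleton ids).
#' @export
add_singletons <- function(consensus, leftovers, guides, min_len = 1000L,
                           min_aa_len = 50L, min_aa_identity = 0.60) {
  long <- leftovers[nchar(leftovers) >= min_len]
  added <- character(0)
  if (length(long) > 0L) {
    gh <- match_guides(long, guides)
    ok <- gh$aa_len >= min_aa_len & gh$identity >= min_aa_identity
    added <- gh$id[ok]
  }
  combined <- c(consensus, leftovers[added])
  list(consensus = collapse_redundant(combined), added = added)
}

#' Summary statistics of a contig set
#'
#' N50 is the largest length L such that contigs of length >= L together
#' cover at least half of the total assembly length.
#'
#' @param contigs named character vector (non-empty).
#' @param stage optional stage label.
#' @return one-row data.frame: stage, n_contigs, total_length, mean_length,
#'   n50.
#' @export
transcriptome_stats <- function(contigs, stage = NA_character_) {
  if (length(contigs) == 0L) stop("empty contig set")
  len <- sort(nchar(contigs), decreasing = TRUE)
  total <- sum(len)
  n50 <- len[which(cumsum(len) >= total / 2)[1]]
  data.frame(stage = stage, n_contigs = length(contigs),
             total_length = unname(total), mean_length = unname(mean(len)),
             n50 = unname(n50), stringsAsFactors = FALSE, row.names = NULL)
}

#' Screen assembled sequences for conflicts against a trusted set
#'
#' For each assembled sequence and its best-matching trusted sequence, a
#' CONFLICT is flagged when the pair shares a region of at least
#' `strong_len` bp at `strong_ident` identity or better AND the mutual
#' overlap also contains a window of at least `weak_len` bp aligning below
#' `weak_ident` identity — the signature of a chimeric assembly.
#'
#' @param assembled named character vector.
#' @param trusted named character vector (e.g. an independent EST set).
#' @param strong_len,strong_ident thresholds for the shared region
#'   (default 100 bp, 0.95).
#' @param weak_len,weak_ident thresholds for the conflicting region
#'   (default 50 bp, 0.80).
#' @return list: `report` (assembled, trusted, conflict), `n_conflicts`.
#' @export
assess_against_reference <- function(assembled, trusted,
                                     strong_len = 100L, strong_ident = 0.95,
                                     weak_len = 50L, weak_ident = 0.80) {
  hits <- find_hits(assembled, trusted, min_aln_len = strong_len,
                    min_identity = strong_ident)
  rows <- list()
  if (nrow(hits) > 0L) {
    bh <- best_hit_table(hits)
    for (id in names(bh)) {
      h <- hits[hits$query == id & hits$subject == bh[id], , drop = FALSE]
      h <- h[which.max(h$score), ]
      if (h$strand == "+") {
        orient <- unname(assembled[id]); off <- h$s_start - h$q_start
      } else {
        orient <- unname(revcomp(assembled[id]))
        off <- h$s_start - (nchar(assembled[id]) - h$q_end)
      }
      prof <- .overlap_profile(orient, trusted[[bh[id]]], off)
      conflict <- FALSE
      if (!is.null(prof) && length(prof$match) >= weak_len) {
        # a conflicting region is a maximal low-identity block of at least
        # weak_len columns: smooth the mismatch profile over an 11-column
        # window and look for a long run of low-identity columns
        m <- prof$match
        n <- length(m)
        w <- 11L
        cs <- cumsum(c(0, m))
        lo <- pmax(0L, seq_len(n) - 1L - (w %/% 2L))
        hi <- pmin(n, seq_len(n) + (w %/% 2L))
        local_ident <- (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
        conflict <- .max_run(local_ident < weak_ident) >= weak_len
      }
      rows[[length(rows) + 1L]] <- data.frame(
        assembled = id, trusted = unname(bh[id]), conflict = conflict,
        stringsAsFactors = FALSE)
    }
  }
  report <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(assembled = character(0), trusted = character(0),
               conflict = logical(0), stringsAsFactors = FALSE)
  list(report = report, n_conflicts = sum(report$conflict))
}
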