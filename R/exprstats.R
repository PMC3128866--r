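# Expression quantification and comparison.
#
# Fragment counting from paired alignments, FPKM normalisation, log-scale
# Pearson correlation with bootstrap confidence intervals, a count-based
# exact binomial differential-expression test with Benjamini-Hochberg FDR
# control, and two-tailed Fisher's exact GO-term enrichment.

#' Count fragments per locus from paired alignments
#'
#' A fragment is counted when at least one mate maps uniquely; pairs whose
#' mates map uniquely to different loci are discarded and reported.
#'
#' @param aln1,aln2 alignment data.frames for the two mate files (same
#'   order; ids differing only in the /1 /2 suffix).
#' @param reference named character vector (defines the locus universe).
#' @return list: `counts` (named integer vector over reference loci),
#'   `total` (total counted fragments), `discordant` (fragment ids dropped
#'   for split mapping).
#' @export
count_fragments <- function(aln1, aln2, reference) {
  key1 <- sub("/1$", "", aln1$read_id)
  key2 <- sub("/2$", "", aln2$read_id)
  m <- match(key1, key2)
  l1 <- ifelse(aln1$mapped == "unique", aln1$locus_id, NA_character_)
  l2 <- ifelse(aln2$mapped == "unique", aln2$locus_id, NA_character_)[m]
  both <- !is.na(l1) & !is.na(l2)
  discordant <- both & l1 != l2
  locus <- ifelse(is.na(l1), l2, l1)
  use <- !is.na(locus) & !discordant
  counts <- stats::setNames(integer(length(reference)), names(reference))
  if (any(use)) {
    tab <- table(locus[use])
    counts[names(tab)] <- as.integer(tab)
  }
  list(counts = counts, total = sum(counts),
       discordant = key1[which(discordant)])
}

#' Fragments per kilobase per million mapped fragments
#'
#' @param count fragment count for the locus.
#' @param locus_length locus length in bp (> 0).
#' @param total_fragments total mapped fragments in the sample (> 0).
#' @return FPKM value(s).
#' @export
#' @examples
#' fpkm(100, 1000, 1e6)  # 100
fpkm <- function(count, locus_length, total_fragments) {
  if (any(locus_length <= 0) || any(total_fragments <= 0))
    stop("locus_length and total_fragments must be positive")
  count * 1e9 / (locus_length * total_fragments)
}

#' Log-scale Pearson correlation of FPKM between two samples
#'
#' By default, loci with zero FPKM in either sample are excluded and the
#' correlation is computed over log(FPKM); with a pseudocount, loci
#' expressed in at least one sample are kept and log(FPKM + pseudocount) is
#' used.
#'
#' @param fpkm_a,fpkm_b named FPKM vectors over the same loci.
#' @param pseudocount NULL (default; exclude zeros) or a positive value.
#' @return list: r, n_loci, loci (ids used).
#' @export
log_correlation <- function(fpkm_a, fpkm_b, pseudocount = NULL) {
  shared <- intersect(names(fpkm_a), names(fpkm_b))
  a <- fpkm_a[shared]; b <- fpkm_b[shared]
  if (is.null(pseudocount)) {
    use <- a > 0 & b > 0
    x <- log(a[use]); y <- log(b[use])
  } else {
    use <- a > 0 | b > 0
    x <- log(a[use] + pseudocount); y <- log(b[use] + pseudocount)
  }
  if (length(x) < 3L) stop("need at least 3 shared expressed loci")
  if (sd(x) == 0 || sd(y) == 0)
    stop("degenerate variance: log-FPKM constant in one sample")
  list(r = cor(x, y), n_loci = length(x), loci = names(a)[use])
}

#' Bootstrap percentile confidence interval for the log-scale correlation
#'
#' Resamples loci with replacement and reports the 2.5/97.5 percentile
#' interval of the correlation of the resampled log values.
#'
#' @param x,y paired log-expression vectors.
#' @param reps bootstrap replicates (>= 100; default 10000).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return list: ci_low, ci_high, reps.
#' @export
bootstrap_ci <- function(x, y, reps = 10000L, seed = 1L, conf = 0.95) {
  stopifnot(length(x) == length(y), reps >= 100L)
  set.seed(seed)
  n <- length(x)
  rs <- numeric(reps)
  for (i in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    sx <- x[idx]; sy <- y[idx]
    rs[i] <- if (sd(sx) == 0 || sd(sy) == 0) 1.0 else cor(sx, sy)
  }
  qs <- unname(quantile(rs, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  list(ci_low = qs[1], ci_high = qs[2], reps = reps)
}

#' Correlate all sample pairs with bootstrap intervals
#'
#' @param fpkm_mat matrix of FPKM (loci x samples).
#' @param reps bootstrap replicates per pair.
#' @param seed RNG seed.
#' @return data.frame: sample_a, sample_b, r, ci_low, ci_high, n_loci.
#' @export
correlate_samples <- function(fpkm_mat, reps = 10000L, seed = 1L) {
  samples <- colnames(fpkm_mat)
  rows <- list()
  for (i in seq_len(ncol(fpkm_mat) - 1)) for (j in (i + 1):ncol(fpkm_mat)) {
    a <- stats::setNames(fpkm_mat[, i], rownames(fpkm_mat))
    b <- stats::setNames(fpkm_mat[, j], rownames(fpkm_mat))
    lc <- log_correlation(a, b)
    use <- lc$loci
    ci <- bootstrap_ci(log(a[use]), log(b[use]), reps = reps,
                       seed = seed + i * 131L + j)
    rows[[length(rows) + 1L]] <- data.frame(
      sample_a = samples[i], sample_b = samples[j], r = lc$r,
      ci_low = ci$ci_low, ci_high = ci$ci_high, n_loci = lc$n_loci,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Count-based differential expression between two samples
#'
#' Per locus, a two-sided exact binomial test of the sample-A count against
#' the proportion expected from the two library totals, with
#' Benjamini-Hochberg q-values and FPKM-ratio fold changes (B over A).
#' Loci with no fragments in either sample get p = 1.
#'
#' @param counts_a,counts_b named fragment-count vectors over shared loci.
#' @param total_a,total_b library totals (mapped fragments).
#' @param lengths named locus-length vector.
#' @param fdr FDR threshold for the significance flag (default 0.05).
#' @return data.frame: locus_id, count_a, count_b, fpkm_a, fpkm_b,
#'   fold_change (B/A), infinite_fold flag, p, q, significant, direction.
#' @export
differential_expression <- function(counts_a, counts_b, total_a, total_b,
                                    lengths, fdr = 0.05) {
  stopifnot(total_a > 0, total_b > 0)
  loci <- intersect(names(counts_a), names(counts_b))
  ca <- counts_a[loci]; cb <- counts_b[loci]
  p0 <- total_a / (total_a + total_b)
  p <- vapply(seq_along(loci), function(i) {
    n <- ca[i] + cb[i]
    if (n == 0) return(1.0)
    binom.test(ca[i], n, p = p0)$p.value
  }, numeric(1))
  q <- p.adjust(p, method = "BH")
  fa <- fpkm(ca, lengths[loci], total_a)
  fb <- fpkm(cb, lengths[loci], total_b)
  fold <- fb / fa
  data.frame(
    locus_id = loci, count_a = unname(ca), count_b = unname(cb),
    fpkm_a = unname(fa), fpkm_b = unname(fb),
    fold_change = unname(fold),
    infinite_fold = is.infinite(fold) | is.nan(fold),
    p = p, q = q,
    significant = q < fdr,
    direction = ifelse(fb > fa, "up", ifelse(fb < fa, "down", "equal")),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Intersect differential-expression sets across comparisons
#'
#' Loci significant with a consistent direction in every supplied
#' comparison (e.g. each selfer versus the outcrosser).
#'
#' @param de_list list of data.frames from [differential_expression()].
#' @param direction "up", "down" or "any" (consistent but either way).
#' @return character vector of locus ids.
#' @export
intersect_de_sets <- function(de_list, direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  stopifnot(length(de_list) >= 2L)
  sets <- lapply(de_list, function(d) {
    s <- d[d$significant, c("locus_id", "direction")]
    if (direction != "any") s <- s[s$direction == direction, ]
    s
  })
  shared <- Reduce(intersect, lapply(sets, `[[`, "locus_id"))
  if (direction == "any" && length(shared) > 0L) {
    dirs <- sapply(sets, function(s) s$direction[match(shared, s$locus_id)])
    dirs <- matrix(dirs, nrow = length(shared))
    consistent <- apply(dirs, 1, function(x) length(unique(x)) == 1L)
    shared <- shared[consistent]
  }
  sort(shared)
}

#' Named contrast sets for enrichment testing
#'
#' The four standard contrasts of the selfing-syndrome comparison: loci
#' absent (zero FPKM) in every selfing genotype but expressed in the
#' outcrosser; loci absent in the outcrosser but expressed in every
#' selfer; and loci significantly low / high in all selfers relative to
#' the outcrosser (from the shared differential-expression sets).
#'
#' @param fpkm_mat FPKM matrix (loci x samples).
#' @param outcrosser column name of the outcrossing sample.
#' @param selfers column names of the selfing samples.
#' @param de_list per-selfer [differential_expression()] results
#'   (outcrosser as sample A).
#' @return named list of four locus-id vectors.
#' @export
expression_contrasts <- function(fpkm_mat, outcrosser, selfers, de_list) {
  loci <- rownames(fpkm_mat)
  in_selfers <- fpkm_mat[, selfers, drop = FALSE] > 0
  list(
    absent_in_selfers = loci[rowSums(in_selfers) == 0 &
                             fpkm_mat[, outcrosser] > 0],
    absent_in_outcrosser = loci[fpkm_mat[, outcrosser] == 0 &
                                rowSums(in_selfers) == length(selfers)],
    low_in_selfers = intersect_de_sets(de_list, "down"),
    high_in_selfers = intersect_de_sets(de_list, "up")
  )
}

#' Parse a gene-to-GO TSV map
#'
#' Lines are `gene_id<TAB>GO:NNNNNNN[,GO:...]`.
#'
#' @param path TSV path (no header).
#' @return named list: gene id -> character vector of terms.
#' @export
read_go_map <- function(path) {
  d <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                  col.names = c("gene_id", "terms"))
  stats::setNames(strsplit(d$terms, ","), d$gene_id)
}

#' Write a gene-to-GO map to TSV
#' @param go_map named list (gene id -> terms) or data.frame(gene_id, terms).
#' @param path output path.
#' @export
write_go_map <- function(go_map, path) {
  if (is.data.frame(go_map)) {
    d <- go_map
  } else {
    d <- data.frame(gene_id = names(go_map),
                    terms = vapply(go_map, paste, character(1), collapse = ","),
                    stringsAsFactors = FALSE)
  }
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' GO-term enrichment by two-tailed Fisher's exact test
#'
#' For every term annotated in the reference set, tests the 2x2 table of
#' (test vs rest) x (has-term vs not) with the standard two-tailed exact
#' convention (sum of table probabilities not exceeding the observed
#' table's), then applies Benjamini-Hochberg correction.
#'
#' @param test_set character vector of locus ids (subset of reference).
#' @param reference_set character vector of locus ids.
#' @param term_map named list: locus id -> character vector of terms.
#' @param fdr FDR threshold for the significance flag (default 0.05).
#' @return data.frame: term, test_with, test_without, rest_with,
#'   rest_without, p, q, direction (over/under), significant.
#' @export
go_enrichment <- function(test_set, reference_set, term_map, fdr = 0.05) {
  if (length(test_set) == 0L) stop("empty test set")
  if (!all(test_set %in% reference_set))
    stop("test set must be a subset of the reference set")
  ann <- term_map[intersect(reference_set, names(term_map))]
  long <- data.frame(
    gene = rep(names(ann), lengths(ann)),
    term = unlist(ann, use.names = FALSE), stringsAsFactors = FALSE)
  terms <- sort(unique(long$term))
  n_test <- length(test_set)
  n_rest <- length(reference_set) - n_test
  rows <- lapply(terms, function(tm) {
    with_term <- unique(long$gene[long$term == tm])
    a <- sum(test_set %in% with_term)
    c_ <- length(with_term) - a
    b <- n_test - a
    d <- n_rest - c_
    p <- fisher.test(matrix(c(a, b, c_, d), 2, 2,
                            byrow = TRUE))$p.value
    over <- (a / max(1, n_test)) > (c_ / max(1, n_rest))
    data.frame(term = tm, test_with = a, test_without = b,
               rest_with = c_, rest_without = d, p = p,
               direction = if (over) "over" else "under",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr
  out[order(out$p, out$term), c("term", "test_with", "test_without",
                                "rest_with", "rest_without", "p", "q",
                                "direction", "significant")]
}
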