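# Read mapping, pileups and Bayesian diploid genotype calling.
#
# Reads are placed ungapped at their minimal-mismatch position on the
# consensus transcriptome (both strands, per-read mismatch budget
# floor(0.05 * length) + 1); multi-mapped reads are excluded from pileups.
# Sites are called with a simplified Maq-style model: per-observation error
# probabilities from base qualities, a shared heterozygote prior, a
# Phred-scaled consensus quality for the call, and ambiguity below the
# coverage (> 5) and quality (Q > 13) thresholds.

DIPLOID_GENOTYPES <- c("A/A", "C/C", "G/G", "T/T",
                       "A/C", "A/G", "A/T", "C/G", "C/T", "G/T")

#' Map reads to a reference transcriptome
#'
#' Every read k-mer seeds candidate ungapped placements on both strands; the
#' placement with the fewest mismatches wins, within a budget of
#' `floor(max_mismatch_frac * length) + 1`. Reads with two or more
#' equally-best placements are marked ambiguous and excluded downstream.
#'
#' @param reads read-set data.frame (id, seq, qual).
#' @param reference named character vector of reference sequences.
#' @param max_mismatch_frac per-read mismatch budget fraction (default 0.05).
#' @param k seed length for the reference index (default 20).
#' @return data.frame: read_id, locus_id, position (0-based), strand,
#'   mismatch_count, mapped ("unique", "ambiguous" or "unmapped"), plus the
#'   read seq/qual columns carried through.
#' @export
map_reads <- function(reads, reference, max_mismatch_frac = 0.05, k = 20L) {
  bad <- grepl("[^ACGTNacgtn]", reads$seq)
  if (any(bad)) stop("reads contain non-nucleotide characters")
  if (any(grepl("[^ACGTNacgtn]", reference)))
    stop("reference contains non-nucleotide characters")
  m <- cpp_map_reads(unname(reference), reads$seq,
                     as.numeric(max_mismatch_frac), as.integer(k))
  data.frame(
    read_id = reads$id,
    locus_id = names(reference)[m$ref_idx],
    position = m$pos,
    strand = m$strand,
    mismatch_count = m$mismatches,
    mapped = c("unmapped", "unique", "ambiguous")[m$status + 1L],
    seq = reads$seq, qual = reads$qual,
    stringsAsFactors = FALSE
  )
}

#' Read alignments from a SAM file
#'
#' Parses the eleven mandatory fields (plus the NM tag when present) of a
#' text SAM file into the alignment structure used by [pileup()]. Only
#' primary alignments are kept; unmapped records are marked "unmapped",
#' mapping quality 0 with multiple hits is treated as "ambiguous" by
#' aligners that use it that way and is kept as "unique" here unless the
#' record carries flag 0x100.
#'
#' @param path SAM file path.
#' @return alignment data.frame as from [map_reads()].
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(data.frame(read_id = character(0), locus_id = character(0),
                      position = integer(0), strand = character(0),
                      mismatch_count = integer(0), mapped = character(0),
                      seq = character(0), qual = character(0),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t")
  get <- function(i) vapply(f, `[`, character(1), i)
  flag <- as.integer(get(2))
  secondary <- bitwAnd(flag, 256L) > 0L
  f <- f[!secondary]; flag <- flag[!secondary]
  get <- function(i) vapply(f, `[`, character(1), i)
  unmapped <- bitwAnd(flag, 4L) > 0L
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(tag) > 0) as.integer(sub("^NM:i:", "", tag[1])) else NA_integer_
  }, integer(1))
  # SAM stores minus-strand records in reference orientation; convert back
  # to read-as-sequenced orientation (the AlignmentRecord convention)
  minus <- !unmapped & bitwAnd(flag, 16L) > 0L
  seq <- get(10); qual <- get(11)
  if (any(minus)) {
    seq[minus] <- unname(revcomp(seq[minus]))
    qual[minus] <- vapply(strsplit(qual[minus], ""), function(x)
      paste(rev(x), collapse = ""), character(1))
  }
  data.frame(
    read_id = get(1),
    locus_id = ifelse(unmapped, NA_character_, get(3)),
    position = ifelse(unmapped, NA_integer_, as.integer(get(4)) - 1L),
    strand = ifelse(unmapped, NA_character_, ifelse(minus, "-", "+")),
    mismatch_count = nm,
    mapped = ifelse(unmapped, "unmapped", "unique"),
    seq = seq, qual = qual,
    stringsAsFactors = FALSE
  )
}

#' Write alignments to a SAM file
#' @param aln alignment data.frame from [map_reads()].
#' @param reference named character vector (for the header).
#' @param path output path.
#' @export
write_sam <- function(aln, reference, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(reference), nchar(reference)),
             con)
  ok <- aln$mapped == "unique"
  flag <- ifelse(ok & aln$strand == "-", 16L, ifelse(ok, 0L, 4L))
  seq <- ifelse(ok & aln$strand == "-", revcomp(aln$seq), aln$seq)
  qual <- ifelse(ok & aln$strand == "-",
                 vapply(strsplit(aln$qual, ""), function(x)
                   paste(rev(x), collapse = ""), character(1)), aln$qual)
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
                     aln$read_id, flag,
                     ifelse(ok, aln$locus_id, "*"),
                     ifelse(ok, aln$position + 1L, 0L),
                     ifelse(ok, 60L, 0L),
                     ifelse(ok, paste0(nchar(aln$seq), "M"), "*"),
                     seq, qual,
                     ifelse(ok, paste0("\tNM:i:", aln$mismatch_count), "")),
             con)
  invisible(path)
}

#' Build a long-format pileup from unique alignments
#'
#' @param aln alignment data.frame (only rows with mapped == "unique"
#'   contribute); alignments on the minus strand contribute
#'   reverse-complemented bases in reference orientation.
#' @param reference named character vector.
#' @return data.frame: locus_id, pos (0-based), base, qual — one row per
#'   read-base observation ('N' bases dropped).
#' @export
pileup <- function(aln, reference) {
  u <- aln[aln$mapped == "unique", , drop = FALSE]
  if (nrow(u) == 0L)
    return(data.frame(locus_id = character(0), pos = integer(0),
                      base = character(0), qual = integer(0),
                      stringsAsFactors = FALSE))
  ref_idx <- match(u$locus_id, names(reference))
  p <- cpp_pileup(ref_idx, u$position, u$strand, u$seq, u$qual)
  data.frame(
    locus_id = names(reference)[p$ref_idx],
    pos = p$pos,
    base = c("A", "C", "G", "T")[p$base + 1L],
    qual = p$qual,
    stringsAsFactors = FALSE
  )
}

# core likelihood machinery, vectorised over columns.
# obs: data.frame(key [integer column index], base [1..4], qual)
# returns matrix n_cols x 10 of posterior probabilities (columns in
# DIPLOID_GENOTYPES order), plus coverage vector
.column_posteriors <- function(key, base, qual, het_prior) {
  eps <- pmin(pmax(phred_error_prob(qual), 1e-6), 0.75)
  n_keys <- max(key)
  # per-observation log P(b | XX) for the four homozygotes
  hom_logp <- vapply(1:4, function(x)
    log(ifelse(base == x, 1 - eps, eps / 3)), numeric(length(base)))
  # per-observation P for the six heterozygotes: mean of the two homozygote
  # emission probabilities
  het_pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  hom_p <- exp(hom_logp)
  het_logp <- vapply(het_pairs, function(pr)
    log(0.5 * (hom_p[, pr[1]] + hom_p[, pr[2]])), numeric(length(base)))
  ll <- rowsum(cbind(hom_logp, het_logp), key)   # n_keys x 10
  full <- matrix(-Inf, n_keys, 10L)
  full[as.integer(rownames(ll)), ] <- ll
  prior <- c(rep(log((1 - het_prior) / 4), 4), rep(log(het_prior / 6), 6))
  lp <- sweep(full, 2, prior, `+`)
  mx <- do.call(pmax, as.data.frame(lp))
  post <- exp(lp - mx)
  post / rowSums(post)
}

#' Call the diploid genotype of one pileup column
#'
#' Bayesian call over the ten unordered diploid genotypes: each observed
#' base b with quality-implied error probability e contributes
#' P(b | XX) = 1 - e if b = X else e/3, and
#' P(b | XY) = (P(b | XX) + P(b | YY)) / 2; heterozygotes share `het_prior`
#' and homozygotes the rest, uniformly within class. The call is the
#' maximum-posterior genotype with consensus quality
#' Q = -10 log10(1 - posterior), capped at 99; the site is AMBIGUOUS when
#' coverage <= `min_coverage` or Q <= `min_quality`.
#'
#' @param bases character vector of observed bases (A/C/G/T).
#' @param quals integer vector of Phred base qualities.
#' @param het_prior prior probability of a heterozygous site (default 0.001).
#' @param min_coverage coverage must strictly exceed this (default 5).
#' @param min_quality consensus quality must strictly exceed this
#'   (default 13).
#' @return list: genotype (e.g. "A/C" or "AMBIGUOUS"), quality, coverage,
#'   posterior (named over the ten genotypes).
#' @export
call_site <- function(bases, quals, het_prior = 0.001,
                      min_coverage = 5L, min_quality = 13) {
  stopifnot(length(bases) == length(quals), length(bases) > 0)
  b <- match(bases, c("A", "C", "G", "T"))
  if (anyNA(b)) stop("bases must be A/C/G/T")
  post <- .column_posteriors(rep(1L, length(b)), b, quals, het_prior)[1, ]
  names(post) <- DIPLOID_GENOTYPES
  top <- which.max(post)
  q <- min(99, -10 * log10(max(1 - post[top], 1e-10)))
  cov <- length(bases)
  geno <- if (cov <= min_coverage || q <= min_quality) "AMBIGUOUS" else
    DIPLOID_GENOTYPES[top]
  list(genotype = geno, quality = unname(q), coverage = cov,
       posterior = post)
}

#' Call genotypes for every covered column of a pileup
#'
#' Vectorised application of the [call_site()] model across all pileup
#' columns of all loci.
#'
#' @param pile pileup data.frame from [pileup()].
#' @param het_prior,min_coverage,min_quality as in [call_site()].
#' @return data.frame: locus_id, pos, genotype, quality, coverage,
#'   ambiguous.
#' @export
call_columns <- function(pile, het_prior = 0.001, min_coverage = 5L,
                         min_quality = 13) {
  if (nrow(pile) == 0L)
    return(data.frame(locus_id = character(0), pos = integer(0),
                      genotype = character(0), quality = numeric(0),
                      coverage = integer(0), ambiguous = logical(0),
                      stringsAsFactors = FALSE))
  # keep peak memory bounded: process batches of whole loci
  if (nrow(pile) > 1.5e6) {
    idx_by_locus <- split(seq_len(nrow(pile)), pile$locus_id)
    sizes <- cumsum(lengths(idx_by_locus))
    batch <- (sizes - 1) %/% 1e6
    out <- lapply(split(idx_by_locus, batch), function(grp)
      call_columns(pile[unlist(grp, use.names = FALSE), , drop = FALSE],
                   het_prior, min_coverage, min_quality))
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    return(out)
  }
  colkey <- paste0(pile$locus_id, "\r", pile$pos)
  ukey <- unique(colkey)
  key <- match(colkey, ukey)
  b <- match(pile$base, c("A", "C", "G", "T"))
  post <- .column_posteriors(key, b, pile$qual, het_prior)
  top <- max.col(post, ties.method = "first")
  pmaxv <- post[cbind(seq_len(nrow(post)), top)]
  q <- pmin(99, -10 * log10(pmax(1 - pmaxv, 1e-10)))
  cov <- as.integer(rowsum(rep(1L, length(key)), key))
  parts <- strsplit(ukey, "\r", fixed = TRUE)
  amb <- cov <= min_coverage | q <= min_quality
  data.frame(
    locus_id = vapply(parts, `[`, character(1), 1),
    pos = as.integer(vapply(parts, `[`, character(1), 2)),
    genotype = ifelse(amb, "AMBIGUOUS", DIPLOID_GENOTYPES[top]),
    quality = q, coverage = cov, ambiguous = amb,
    stringsAsFactors = FALSE
  )
}

#' Assemble per-locus genotypes from site calls
#'
#' Builds, for every reference locus, the called sequence (homozygous calls
#' as the base, heterozygous calls as IUPAC codes, ambiguous or uncovered
#' sites as 'N'), the mean coverage across the locus (uncovered sites count
#' zero), the heterozygous-site count, and the presence flag (mean coverage
#' strictly greater than `min_mean_coverage`).
#'
#' @param calls data.frame from [call_columns()].
#' @param reference named character vector of the reference loci.
#' @param min_mean_coverage presence threshold (default 5).
#' @return list: `table` (data.frame locus_id, length, mean_coverage,
#'   het_site_count, present) and `sequences` (named character vector of
#'   called sequences with ambiguity characters).
#' @export
genotype_loci <- function(calls, reference, min_mean_coverage = 5) {
  lens <- nchar(reference)
  seqs <- stats::setNames(strrep("N", lens), names(reference))
  het_count <- stats::setNames(integer(length(reference)), names(reference))
  covsum <- stats::setNames(numeric(length(reference)), names(reference))
  if (nrow(calls) > 0L) {
    cs <- rowsum(calls$coverage, calls$locus_id)
    covsum[rownames(cs)] <- cs[, 1]
    ok <- !calls$ambiguous
    het <- ok & substr(calls$genotype, 1, 1) != substr(calls$genotype, 3, 3)
    hc <- rowsum(as.integer(het), calls$locus_id)
    het_count[rownames(hc)] <- hc[, 1]
    code <- ifelse(het,
                   iupac_code(substr(calls$genotype, 1, 1),
                              substr(calls$genotype, 3, 3)),
                   substr(calls$genotype, 1, 1))
    by_locus <- split(which(ok), calls$locus_id[ok])
    for (lid in names(by_locus)) {
      rows <- by_locus[[lid]]
      v <- strsplit(seqs[[lid]], "")[[1]]
      v[calls$pos[rows] + 1L] <- code[rows]
      seqs[lid] <- paste(v, collapse = "")
    }
  }
  mean_cov <- covsum / lens
  list(
    table = data.frame(locus_id = names(reference), length = unname(lens),
                       mean_coverage = unname(mean_cov),
                       het_site_count = unname(het_count),
                       present = unname(mean_cov > min_mean_coverage),
                       stringsAsFactors = FALSE),
    sequences = seqs
  )
}

#' Genotype one sample end to end
#'
#' Maps reads, builds the pileup, calls sites and assembles locus genotypes.
#'
#' @param reads read-set data.frame (typically trimmed).
#' @param reference named character vector.
#' @param het_prior,min_coverage,min_quality site-call parameters.
#' @param min_mean_coverage locus presence threshold.
#' @return list: `alignments`, `calls`, `table`, `sequences`.
#' @export
genotype_sample <- function(reads, reference, het_prior = 0.001,
                            min_coverage = 5L, min_quality = 13,
                            min_mean_coverage = 5) {
  aln <- map_reads(reads, reference)
  pile <- pileup(aln, reference)
  calls <- call_columns(pile, het_prior, min_coverage, min_quality)
  geno <- genotype_loci(calls, reference, min_mean_coverage)
  list(alignments = aln, calls = calls, table = geno$table,
       sequences = geno$sequences)
}

#' Flag loci for suspected read-mapping error (collapsed paralogy)
#'
#' Under predominant selfing, genotypes should be close to fully homozygous;
#' heterozygous calls recurring across multiple selfing genotypes at one
#' locus point at mis-mapped reads from a collapsed paralog rather than true
#' heterozygosity. Loci present in at most one selfer cannot be tested.
#'
#' @param tables named list (by sample) of locus tables from
#'   [genotype_loci()].
#' @param selfer_labels character vector naming the selfing samples.
#' @return data.frame: locus_id, status in {CLEAN, SUSPECT, UNTESTABLE},
#'   n_selfers_present, n_selfers_het.
#' @export
flag_mapping_errors <- function(tables, selfer_labels) {
  if (length(intersect(selfer_labels, names(tables))) == 0L)
    stop("no selfing samples labeled")
  selfers <- intersect(names(tables), selfer_labels)
  loci <- tables[[1]]$locus_id
  pres <- sapply(selfers, function(s)
    tables[[s]]$present[match(loci, tables[[s]]$locus_id)])
  hets <- sapply(selfers, function(s) {
    t <- tables[[s]]
    t$present[match(loci, t$locus_id)] &
      t$het_site_count[match(loci, t$locus_id)] >= 1L
  })
  pres <- matrix(pres, nrow = length(loci))
  hets <- matrix(hets, nrow = length(loci))
  n_pres <- rowSums(pres, na.rm = TRUE)
  n_het <- rowSums(hets, na.rm = TRUE)
  status <- ifelse(n_pres <= 1L, "UNTESTABLE",
                   ifelse(n_het >= 2L, "SUSPECT", "CLEAN"))
  data.frame(locus_id = loci, status = status,
             n_selfers_present = n_pres, n_selfers_het = n_het,
             stringsAsFactors = FALSE)
}

#' Export site calls of one sample as minimal VCF
#'
#' @param calls data.frame from [call_columns()] (ambiguous sites skipped).
#' @param reference named character vector.
#' @param sample_name sample column label.
#' @param path output path.
#' @export
write_vcf <- function(calls, reference, sample_name, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Consensus quality\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Coverage\">",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      sample_name)), con)
  ok <- !calls$ambiguous
  c2 <- calls[ok, , drop = FALSE]
  if (nrow(c2) > 0L) {
    ref_base <- substr(reference[c2$locus_id], c2$pos + 1L, c2$pos + 1L)
    a1 <- substr(c2$genotype, 1, 1); a2 <- substr(c2$genotype, 3, 3)
    alt <- vapply(seq_len(nrow(c2)), function(i) {
      alts <- setdiff(unique(c(a1[i], a2[i])), ref_base[i])
      if (length(alts) == 0) "." else paste(alts, collapse = ",")
    }, character(1))
    gt <- vapply(seq_len(nrow(c2)), function(i) {
      alleles <- c(ref_base[i], setdiff(unique(c(a1[i], a2[i])), ref_base[i]))
      paste(match(c(a1[i], a2[i]), alleles) - 1L, collapse = "/")
    }, character(1))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:GQ:DP\t%s:%d:%d",
                       c2$locus_id, c2$pos + 1L, ref_base, alt, gt,
                       as.integer(round(c2$quality)), c2$coverage), con)
  }
  invisible(path)
}
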