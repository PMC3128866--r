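# Pairwise divergence and Watterson's theta over a conservative locus set.
#
# The conservative set keeps loci present in every sample and homozygous in
# every selfer; SNPs are counted at sites where both members of a pair are
# unambiguous homozygous calls, and per-site divergence is SNPs divided by
# the number of comparable sites.

#' Select the conservative locus set
#'
#' Loci present (mean coverage rule) in all samples and with zero
#' heterozygous sites in every selfing sample. Heterozygosity in the
#' outcrosser does not exclude a locus.
#'
#' @param tables named list (by sample) of locus tables from
#'   [genotype_loci()].
#' @param selfer_labels character vector naming the selfing samples.
#' @return character vector of locus ids.
#' @export
conservative_set <- function(tables, selfer_labels) {
  loci <- tables[[1]]$locus_id
  keep <- rep(TRUE, length(loci))
  for (s in names(tables)) {
    t <- tables[[s]]
    m <- match(loci, t$locus_id)
    keep <- keep & t$present[m]
    if (s %in% selfer_labels) keep <- keep & t$het_site_count[m] == 0L
  }
  keep[is.na(keep)] <- FALSE
  loci[keep]
}

#' Count SNPs between two called samples
#'
#' Compares sites where both calls are unambiguous homozygous bases
#' (heterozygous IUPAC codes and 'N' are excluded from the comparison);
#' differing bases count one SNP each.
#'
#' @param seqs_a,seqs_b named character vectors of called sequences (IUPAC
#'   ambiguity), same locus lengths.
#' @param loci locus ids to compare (default: shared loci).
#' @return list: snp_count, site_count.
#' @export
count_snps <- function(seqs_a, seqs_b,
                       loci = intersect(names(seqs_a), names(seqs_b))) {
  if (length(loci) == 0L) return(list(snp_count = 0L, site_count = 0L))
  a <- strsplit(paste(seqs_a[loci], collapse = ""), "")[[1]]
  b <- strsplit(paste(seqs_b[loci], collapse = ""), "")[[1]]
  if (length(a) != length(b)) stop("called sequences differ in length")
  hom <- c("A", "C", "G", "T")
  comparable <- a %in% hom & b %in% hom
  list(snp_count = sum(comparable & a != b),
       site_count = sum(comparable))
}

#' Per-site divergence
#'
#' @param snp_count number of differing sites.
#' @param site_count number of comparable sites (> 0).
#' @return snp_count / site_count.
#' @export
#' @examples
#' divergence(36998, 4.2e6)   # ~0.009
divergence <- function(snp_count, site_count) {
  if (any(site_count <= 0)) stop("site_count must be positive")
  snp_count / site_count
}

#' Pairwise SNP and divergence matrix across samples
#'
#' @param sequences named list (by sample) of called-sequence vectors.
#' @param loci locus ids to compare (the conservative set).
#' @return list: `snp` (symmetric count matrix), `sites` (comparable-site
#'   matrix), `divergence` (per-site divergence matrix).
#' @export
divergence_matrix <- function(sequences, loci) {
  samples <- names(sequences)
  n <- length(samples)
  snp <- sites <- div <- matrix(0, n, n, dimnames = list(samples, samples))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cs <- count_snps(sequences[[i]], sequences[[j]], loci)
    snp[i, j] <- snp[j, i] <- cs$snp_count
    sites[i, j] <- sites[j, i] <- cs$site_count
    div[i, j] <- div[j, i] <-
      if (cs$site_count > 0) cs$snp_count / cs$site_count else NA_real_
  }
  list(snp = snp, sites = sites, divergence = div)
}

#' Watterson's theta from called sequences
#'
#' theta_W = S / (a_n * L), where S is the number of segregating sites among
#' the n sequences, L the number of columns unambiguous (homozygous base
#' call) in all n samples, and a_n the (n-1)th harmonic number.
#'
#' @param sequences named list (by sample, n >= 2) of called-sequence
#'   vectors.
#' @param loci locus ids to scan.
#' @return list: theta, S, L, a_n, n.
#' @export
watterson_theta <- function(sequences, loci) {
  n <- length(sequences)
  stopifnot(n >= 2)
  hom <- c("A", "C", "G", "T")
  mats <- lapply(sequences, function(s)
    strsplit(paste(s[loci], collapse = ""), "")[[1]])
  len <- unique(vapply(mats, length, integer(1)))
  if (length(len) != 1L) stop("called sequences differ in length")
  m <- do.call(rbind, mats)
  usable <- colSums(matrix(m %in% hom, nrow = n)) == n
  if (!any(usable)) stop("no comparable sites")
  mu <- m[, usable, drop = FALSE]
  # a column segregates iff any sequence differs from the first
  S <- sum(colSums(mu != mu[rep(1L, n), , drop = FALSE]) > 0L)
  L <- sum(usable)
  a_n <- sum(1 / seq_len(n - 1))
  list(theta = S / (a_n * L), S = S, L = L, a_n = a_n, n = n)
}

#' Format the SNP/divergence matrices in the classic two-triangle layout
#'
#' SNP counts below the diagonal, per-site divergence (3 decimals) above.
#'
#' @param dm result of [divergence_matrix()].
#' @return character matrix.
#' @export
format_divergence_table <- function(dm) {
  samples <- rownames(dm$snp)
  out <- matrix("-", length(samples), length(samples),
                dimnames = list(samples, samples))
  for (i in seq_along(samples)) for (j in seq_along(samples)) {
    if (i > j) out[i, j] <- format(dm$snp[i, j], big.mark = ",")
    if (i < j) out[i, j] <- sprintf("%.3f", dm$divergence[i, j])
  }
  out
}
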