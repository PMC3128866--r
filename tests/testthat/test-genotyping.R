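# Read mapping, pileups, the Bayesian site caller and the paralog flag.

test_that("error-free reads map uniquely to their true position", {
  set.seed(61)
  ref <- c(locA = random_seq(800), locB = random_seq(800))
  reads <- data.frame(id = "r1/1", seq = substr(ref[["locA"]], 101, 140),
                      qual = phred_encode(rep(30, 40)), stringsAsFactors = FALSE)
  aln <- map_reads(reads, ref)
  expect_equal(aln$mapped, "unique")
  expect_equal(aln$locus_id, "locA")
  expect_equal(aln$position, 100)
  expect_equal(aln$mismatch_count, 0)

  # reverse-complemented read maps to the same spot on the minus strand
  rc <- data.frame(id = "r2/1", seq = unname(revcomp(reads$seq)),
                   qual = reads$qual, stringsAsFactors = FALSE)
  aln2 <- map_reads(rc, ref)
  expect_equal(aln2$position, 100)
  expect_equal(aln2$strand, "-")
})

test_that("reads from identical paralog copies are ambiguous, diverged copies mis-map", {
  set.seed(62)
  s <- random_seq(600)
  ref_twocopy <- c(copy1 = s, copy2 = s)
  r <- data.frame(id = "p/1", seq = substr(s, 201, 240),
                  qual = phred_encode(rep(30, 40)), stringsAsFactors = FALSE)
  expect_equal(map_reads(r, ref_twocopy)$mapped, "ambiguous")

  # only one copy in the reference, read drawn from a 97%-identical paralog:
  # maps to the wrong copy, carrying mismatches
  # one diverged site inside the read window, the rest elsewhere, so a clean
  # 20-mer seed still exists within the read
  paralog <- mutate_seq(s, c(sample(setdiff(1:600, 190:260), 17), 210))
  r2 <- data.frame(id = "q/1", seq = substr(paralog, 201, 240),
                   qual = phred_encode(rep(30, 40)), stringsAsFactors = FALSE)
  aln <- map_reads(r2, c(copy1 = s))
  expect_equal(aln$mapped, "unique")
  expect_gt(aln$mismatch_count, 0)
})

test_that("pileup tallies covered positions from mapped reads only", {
  set.seed(63)
  ref <- c(loc = random_seq(200))
  reads <- data.frame(
    id = c("a/1", "b/1"),
    seq = c(substr(ref, 1, 40), substr(ref, 21, 60)),
    qual = rep(phred_encode(rep(30, 40)), 2), stringsAsFactors = FALSE)
  p <- pileup(map_reads(reads, ref), ref)
  expect_equal(nrow(p), 80)
  cov <- table(p$pos)
  expect_true(all(cov[as.character(20:39)] == 2))
  expect_true(all(cov[as.character(0:19)] == 1))
})

test_that("mean pileup coverage tracks the simulated coverage", {
  cfg <- sim_config(n_loci = 10, paralog_family_fraction = 0, seed = 64,
                    expr_sdlog = 0.2)
  truth <- simulate_transcriptome(cfg)
  reads <- simulate_reads(truth, cfg)
  ref <- truth$haplotypes$selfer1$hap1
  aln <- rbind(map_reads(reads$selfer1$r1, ref),
               map_reads(reads$selfer1$r2, ref))
  p <- pileup(aln, ref)
  mean_cov <- nrow(p) / sum(truth$loci$length)
  expect_lt(abs(mean_cov - 20) / 20, 0.2)
})

test_that("the site caller matches direct evaluation of the stated model", {
  # 10 x A at q20: confident homozygote
  cs <- call_site(rep("A", 10), rep(20, 10))
  expect_equal(cs$genotype, "A/A")
  expect_gt(cs$quality, 13)
  expect_equal(cs$posterior, oracle_posterior(rep("A", 10), rep(20, 10)),
               tolerance = 1e-9)
  expect_gt(cs$posterior[["A/A"]], 0.999)

  # balanced 5/5: heterozygote wins despite the 0.001 prior
  cs2 <- call_site(c(rep("A", 5), rep("C", 5)), rep(20, 10))
  expect_equal(cs2$genotype, "A/C")
  expect_equal(cs2$posterior,
               oracle_posterior(c(rep("A", 5), rep("C", 5)), rep(20, 10)),
               tolerance = 1e-9)

  # coverage 4 < 5: ambiguous regardless of agreement
  cs3 <- call_site(rep("A", 4), rep(30, 4))
  expect_equal(cs3$genotype, "AMBIGUOUS")

  # posterior sums to one
  set.seed(65)
  for (i in 1:25) {
    col <- simulate_column(sample(mateseq:::DIPLOID_GENOTYPES, 1), 12, 20)
    cs <- call_site(col$bases, col$quals)
    expect_equal(sum(cs$posterior), 1, tolerance = 1e-9)
  }
})

test_that("vectorised column calling agrees with single-column calls", {
  set.seed(66)
  pile <- do.call(rbind, lapply(1:30, function(i) {
    col <- simulate_column(sample(c("A/A", "C/C", "A/G"), 1),
                           sample(6:25, 1), 20)
    data.frame(locus_id = "loc", pos = i, base = col$bases, qual = col$quals,
               stringsAsFactors = FALSE)
  }))
  cc <- call_columns(pile)
  for (i in sample(30, 10)) {
    sub <- pile[pile$pos == i, ]
    single <- call_site(sub$base, sub$qual)
    row <- cc[cc$pos == i, ]
    expect_equal(row$genotype,
                 if (single$genotype == "AMBIGUOUS") "AMBIGUOUS" else single$genotype)
    expect_equal(row$quality, single$quality, tolerance = 1e-6)
    expect_equal(row$coverage, single$coverage)
  }
})

test_that("locus genotypes assemble IUPAC sequences with presence flags", {
  ref <- c(loc = strrep("A", 10))
  calls <- data.frame(
    locus_id = "loc", pos = 0:9,
    genotype = c(rep("A/A", 5), "A/C", rep("A/A", 3), "AMBIGUOUS"),
    quality = c(rep(40, 9), 5), coverage = rep(8, 10),
    ambiguous = c(rep(FALSE, 9), TRUE), stringsAsFactors = FALSE)
  g <- genotype_loci(calls, ref)
  expect_identical(g$sequences[["loc"]], "AAAAAMAAAN")
  expect_equal(g$table$het_site_count, 1)
  expect_true(g$table$present)

  # mean coverage 3: absent
  calls$coverage <- rep(3, 10)
  g2 <- genotype_loci(calls, ref)
  expect_false(g2$table$present)
})

test_that("error-free homozygous loci are called identical to truth", {
  cfg <- sim_config(n_loci = 12, read_error_rate = 0, het_rate_outcrosser = 0,
                    het_rate_selfer = 0, paralog_family_fraction = 0,
                    expr_sdlog = 0.2, seed = 67)
  truth <- simulate_transcriptome(cfg)
  reads <- simulate_reads(truth, cfg)
  ref <- truth$haplotypes$selfer1$hap1
  aln <- rbind(map_reads(reads$selfer1$r1, ref),
               map_reads(reads$selfer1$r2, ref))
  calls <- call_columns(pileup(aln, ref))
  geno <- genotype_loci(calls, ref)
  for (lid in names(ref)) {
    called <- strsplit(geno$sequences[[lid]], "")[[1]]
    tru <- strsplit(ref[[lid]], "")[[1]]
    known <- called != "N"
    expect_true(all(called[known] == tru[known]))
    # locus ends ramp down in coverage, so some terminal sites stay ambiguous
    expect_gt(mean(known), 0.8)
  }
})

test_that("the paralog flag follows the selfer-heterozygosity rule", {
  mk <- function(het, present = TRUE) data.frame(
    locus_id = "L1", length = 100, mean_coverage = if (present) 10 else 1,
    het_site_count = het, present = present, stringsAsFactors = FALSE)
  selfers <- c("s1", "s2", "s3")

  # het in two selfers: suspect
  f <- flag_mapping_errors(list(out = mk(3), s1 = mk(1), s2 = mk(2),
                                s3 = mk(0)), selfers)
  expect_equal(f$status, "SUSPECT")

  # het only in the outcrosser, present in three selfers: clean
  f2 <- flag_mapping_errors(list(out = mk(3), s1 = mk(0), s2 = mk(0),
                                 s3 = mk(0)), selfers)
  expect_equal(f2$status, "CLEAN")

  # present in one selfer only: untestable
  f3 <- flag_mapping_errors(list(out = mk(0), s1 = mk(0), s2 = mk(0, FALSE),
                                 s3 = mk(0, FALSE)), selfers)
  expect_equal(f3$status, "UNTESTABLE")

  expect_error(flag_mapping_errors(list(out = mk(0)), c("s1")), "selfing")
})

test_that("alignments round-trip through SAM", {
  set.seed(68)
  ref <- c(locA = random_seq(300))
  reads <- data.frame(
    id = c("a/1", "b/1", "c/1"),
    seq = c(substr(ref, 51, 90), unname(revcomp(substr(ref, 101, 140))),
            random_seq(40)),
    qual = rep(phred_encode(rep(30, 40)), 3), stringsAsFactors = FALSE)
  aln <- map_reads(reads, ref)
  f <- tempfile(fileext = ".sam")
  write_sam(aln, ref, f)
  back <- read_sam(f)
  expect_equal(back$read_id, aln$read_id)
  expect_equal(back$position, aln$position)
  expect_equal(back$strand, aln$strand)
  expect_equal(back$mapped == "unique", aln$mapped == "unique")
  # pileups built from the SAM ingest match the native path
  expect_equal(pileup(back, ref), pileup(aln, ref))
})

test_that("VCF export writes the called genotypes", {
  ref <- c(loc = strrep("A", 6))
  calls <- data.frame(locus_id = "loc", pos = 0:5,
                      genotype = c("A/A", "A/C", "C/C", "AMBIGUOUS", "A/A", "A/T"),
                      quality = rep(40, 6), coverage = rep(9, 6),
                      ambiguous = c(rep(FALSE, 3), TRUE, FALSE, FALSE),
                      stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".vcf")
  write_vcf(calls, ref, "sampleX", f)
  lines <- readLines(f)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 5)  # ambiguous site skipped
  expect_match(body[2], "0/1:40:9")
  expect_match(body[3], "1/1:40:9")
})
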