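# Fragment counting, FPKM, correlations with bootstrap intervals,
# differential expression and GO enrichment.

mk_aln <- function(ids, loci, mapped = "unique") data.frame(
  read_id = ids, locus_id = loci, position = 0L, strand = "+",
  mismatch_count = 0L, mapped = mapped, seq = "A", qual = "I",
  stringsAsFactors = FALSE)

test_that("fragment counting keeps proper pairs and drops split pairs", {
  ref <- c(L1 = strrep("A", 100), L2 = strrep("C", 100))
  a1 <- mk_aln(sprintf("f%02d/1", 1:10), rep("L1", 10))
  a2 <- mk_aln(sprintf("f%02d/2", 1:10), rep("L1", 10))
  cf <- count_fragments(a1, a2, ref)
  expect_equal(unname(cf$counts["L1"]), 10L)
  expect_equal(cf$total, 10L)

  # a pair split across loci is discarded and reported
  a2b <- mk_aln("f01/2", "L2")
  cf2 <- count_fragments(mk_aln("f01/1", "L1"), a2b, ref)
  expect_equal(cf2$total, 0L)
  expect_equal(cf2$discordant, "f01")

  # one mapped mate is enough
  cf3 <- count_fragments(mk_aln("f01/1", "L1"),
                         mk_aln("f01/2", NA, mapped = "unmapped"), ref)
  expect_equal(unname(cf3$counts["L1"]), 1L)
})

test_that("fragment counts are proportional to weight times length", {
  cfg <- sim_config(n_loci = 40, paralog_family_fraction = 0,
                    de_fraction = 0, seed = 81)
  truth <- simulate_transcriptome(cfg)
  reads <- simulate_reads(truth, cfg)
  cnt <- reads$outcrosser$frag_counts
  w <- truth$expression[, "outcrosser"] * truth$loci$length
  expected <- sum(cnt) * w / sum(w)
  # chi-square-style standardised residuals stay in range
  z <- (cnt - expected) / sqrt(pmax(expected, 1))
  expect_lt(max(abs(z)), 5)
})

test_that("fpkm follows the definition and its scaling law", {
  expect_equal(fpkm(100, 1000, 1e6), 100)
  expect_equal(fpkm(0, 500, 1e6), 0)
  expect_equal(fpkm(7, 700, 2e6), fpkm(7, 700, 1e6) / 2)
  expect_error(fpkm(1, 0, 100), "positive")
  expect_error(fpkm(1, 100, 0), "positive")
})

test_that("the FPKM conservation identity holds exactly", {
  set.seed(82)
  n <- 200
  counts <- stats::setNames(rpois(n, 50), sprintf("L%03d", 1:n))
  lens <- stats::setNames(sample(200:2000, n, TRUE), names(counts))
  total <- sum(counts)
  f <- fpkm(counts, lens, total)
  expect_equal(sum(f * lens) * total / 1e9, sum(counts), tolerance = 1e-6)
})

test_that("log-scale correlation handles exact and degenerate cases", {
  f <- stats::setNames(c(1, 2, 4, 8), paste0("L", 1:4))
  expect_equal(log_correlation(f, f)$r, 1.0)
  g <- stats::setNames(c(8, 4, 2, 1), paste0("L", 1:4))
  expect_equal(log_correlation(f, g)$r, -1.0)
  # zero-FPKM loci are excluded by default
  f0 <- c(f, L5 = 0); g0 <- c(g, L5 = 3)
  expect_equal(log_correlation(f0, g0)$n_loci, 4)
  expect_error(log_correlation(f[1:2], g[1:2]), "at least 3")
  const <- stats::setNames(rep(2, 4), paste0("L", 1:4))
  expect_error(log_correlation(const, f), "degenerate")
})

test_that("a generated log-scale correlation of 0.9 is recovered", {
  set.seed(83)
  n <- 2000
  lx <- rnorm(n, 3, 1)
  ly <- 3 + 0.9 * (lx - 3) + sqrt(1 - 0.81) * rnorm(n)
  fa <- stats::setNames(exp(lx), sprintf("L%04d", 1:n))
  fb <- stats::setNames(exp(ly), sprintf("L%04d", 1:n))
  expect_lt(abs(log_correlation(fa, fb)$r - 0.9), 0.03)
})

test_that("bootstrap intervals bracket the estimate and pin exact data", {
  set.seed(84)
  x <- rnorm(50); y <- x + rnorm(50, sd = 0.3)
  ci <- bootstrap_ci(x, y, reps = 500, seed = 9)
  r <- cor(x, y)
  expect_lte(ci$ci_low, r)
  expect_gte(ci$ci_high, r)
  ci_exact <- bootstrap_ci(x, x, reps = 200, seed = 9)
  expect_equal(ci_exact$ci_low, 1)
  expect_equal(ci_exact$ci_high, 1)
  # seeded: reproducible
  expect_identical(ci, bootstrap_ci(x, y, reps = 500, seed = 9))
})

test_that("differential expression flags extreme counts and spares equals", {
  loci <- sprintf("L%03d", 1:3)
  ca <- stats::setNames(c(50L, 0L, 30L), loci)
  cb <- stats::setNames(c(50L, 100L, 32L), loci)
  lens <- stats::setNames(rep(1000, 3), loci)
  de <- differential_expression(ca, cb, 1e5, 1e5, lens)
  expect_false(de$significant[de$locus_id == "L001"])
  expect_equal(de$p[de$locus_id == "L001"], 1)
  expect_true(de$significant[de$locus_id == "L002"])
  expect_true(de$infinite_fold[de$locus_id == "L002"])
  expect_equal(de$direction[de$locus_id == "L002"], "up")
  # p equals the two-sided exact binomial
  expect_equal(de$p[de$locus_id == "L003"],
               binom.test(30, 62, 0.5)$p.value)
})

test_that("the null simulation stays within the FDR budget", {
  set.seed(85)
  n <- 1000
  w <- rep(1, n)
  ca <- stats::setNames(as.integer(rmultinom(1, 2e5, w)), sprintf("L%04d", 1:n))
  cb <- stats::setNames(as.integer(rmultinom(1, 2e5, w)), sprintf("L%04d", 1:n))
  lens <- stats::setNames(rep(1000, n), names(ca))
  de <- differential_expression(ca, cb, sum(ca), sum(cb), lens)
  frac <- mean(de$significant)
  expect_lte(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / n))
  # q-values are monotone in p
  ord <- order(de$p)
  expect_true(all(diff(de$q[ord]) >= -1e-12))
  expect_true(all(de$q >= de$p))
})

test_that("DE set intersection demands consistent direction everywhere", {
  mk_de <- function(sig, dir) data.frame(
    locus_id = c("L1", "L2", "L3"), significant = sig, direction = dir,
    stringsAsFactors = FALSE)
  d1 <- mk_de(c(TRUE, TRUE, TRUE), c("up", "up", "up"))
  d2 <- mk_de(c(TRUE, FALSE, TRUE), c("up", "up", "down"))
  d3 <- mk_de(c(TRUE, TRUE, TRUE), c("up", "up", "up"))
  expect_equal(intersect_de_sets(list(d1, d2, d3), "up"), "L1")
  # L2 misses significance in one comparison; L3 conflicts in direction
  expect_equal(intersect_de_sets(list(d1, d2, d3), "any"), "L1")
  expect_equal(intersect_de_sets(list(d1, d3), "up"), c("L1", "L2", "L3"))
})

test_that("enrichment p-values equal brute-force hypergeometric enumeration", {
  reference <- sprintf("G%03d", 1:110)
  test_set <- reference[1:10]
  term_map <- lapply(stats::setNames(reference, reference),
                     function(g) "GO:0000002")
  for (g in c(reference[1:5], reference[11:20]))
    term_map[[g]] <- c("GO:0000001", "GO:0000002")
  res <- go_enrichment(test_set, reference, term_map)
  row <- res[res$term == "GO:0000001", ]
  expect_equal(row$test_with, 5)
  expect_equal(row$rest_with, 10)
  expect_equal(row$p, oracle_fisher(5, 5, 10, 90), tolerance = 1e-12)
  expect_equal(row$direction, "over")

  set.seed(86)
  for (i in 1:15) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:12, 1); d <- sample(0:12, 1)
    if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0) next
    p_pkg <- fisher.test(matrix(c(a, b, c_, d), 2, 2, byrow = TRUE))$p.value
    expect_equal(p_pkg, oracle_fisher(a, b, c_, d), tolerance = 1e-9)
  }
})

test_that("the four contrast presets partition loci as documented", {
  fp <- matrix(c(5, 0, 2, 1,   0, 3, 2, 1,   0, 4, 2, 1), nrow = 4,
               dimnames = list(paste0("L", 1:4), c("out", "s1", "s2")))
  de <- list(
    s1 = data.frame(locus_id = paste0("L", 1:4),
                    significant = c(FALSE, FALSE, TRUE, TRUE),
                    direction = c("down", "up", "down", "up"),
                    stringsAsFactors = FALSE),
    s2 = data.frame(locus_id = paste0("L", 1:4),
                    significant = c(FALSE, FALSE, TRUE, TRUE),
                    direction = c("down", "up", "down", "up"),
                    stringsAsFactors = FALSE))
  ct <- expression_contrasts(fp, "out", c("s1", "s2"), de)
  expect_equal(ct$absent_in_selfers, "L1")
  expect_equal(ct$absent_in_outcrosser, "L2")
  expect_equal(ct$low_in_selfers, "L3")
  expect_equal(ct$high_in_selfers, "L4")
})

test_that("enrichment skips absent terms and flat terms are insignificant", {
  reference <- sprintf("G%03d", 1:100)
  term_map <- lapply(stats::setNames(reference, reference),
                     function(g) "GO:0000009")
  res <- go_enrichment(reference[1:10], reference, term_map)
  expect_equal(res$p, 1)  # identical proportions
  expect_false(res$significant)
  expect_false("GO:9999999" %in% res$term)
  expect_error(go_enrichment(character(0), reference, term_map), "empty")
  expect_error(go_enrichment("nope", reference, term_map), "subset")
})
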