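# Redundancy collapse, RBH grouping, consensus building, extension,
# fragment joining, singleton admission, assembly statistics and the
# chimera screen.

test_that("redundancy collapse keeps the longer of near-identical contigs", {
  set.seed(41)
  s <- random_seq(500)
  out <- collapse_redundant(c(a = s, b = s))
  expect_identical(names(out), "a")  # equal length: lexicographic winner

  long <- random_seq(500)
  short <- substr(long, 1, 300)
  out <- collapse_redundant(c(short1 = short, long1 = long))
  expect_identical(names(out), "long1")

  # 150 bp of overlap is only 75% of a 200 bp contig: both retained
  core <- random_seq(150)
  c200 <- paste0(core, random_seq(50))
  c500 <- paste0(random_seq(350), core)
  out <- collapse_redundant(c(a200 = c200, b500 = c500))
  expect_setequal(names(out), c("a200", "b500"))

  # below the minimum contig length: discarded
  out <- collapse_redundant(c(tiny = random_seq(80), keep = random_seq(200)))
  expect_identical(names(out), "keep")
})

test_that("redundancy collapse is idempotent and order-independent", {
  set.seed(42)
  base <- random_seq(600)
  contigs <- c(a = base, b = substr(base, 1, 400),
               c = mutate_seq(base, sample(600, 2)),
               d = random_seq(300))
  once <- collapse_redundant(contigs)
  expect_identical(collapse_redundant(once), once)
  shuffled <- contigs[c(3, 1, 4, 2)]
  expect_setequal(names(collapse_redundant(shuffled)), names(once))
})

test_that("grouping joins the same sequence across all four samples", {
  set.seed(43)
  s <- random_seq(300)
  samples <- list(s1 = c(s1_c1 = s), s2 = c(s2_c1 = s),
                  s3 = c(s3_c1 = s), s4 = c(s4_c1 = s))
  g <- build_groups(samples)
  expect_length(g$groups, 1)
  expect_length(g$groups[[1]]$members, 4)
  expect_length(g$leftovers, 0)
})

test_that("pairs below the identity threshold are not grouped", {
  set.seed(44)
  s <- random_seq(300)
  s85 <- mutate_seq(s, sample(300, 45))  # ~15% divergence
  g <- build_groups(list(s1 = c(a = s), s2 = c(b = s85)))
  expect_length(g$groups, 0)
  expect_setequal(g$leftovers, c("a", "b"))
})

test_that("grouping recovers truth loci with correct membership", {
  cfg <- sim_config(n_loci = 150, seed = 45)
  truth <- simulate_transcriptome(cfg)
  asm <- emit_contigs(truth, cfg)
  collapsed <- lapply(asm, function(a) collapse_redundant(a$contigs))
  g <- build_groups(collapsed)
  maps <- do.call(rbind, lapply(asm, `[[`, "map"))
  locus_of <- stats::setNames(maps$locus_id, maps$contig_id)
  good <- 0
  for (grp in g$groups) {
    loci <- unique(locus_of[grp$members])
    if (length(loci) == 1 && !is.na(loci)) good <- good + 1
  }
  expect_gte(good / cfg$n_loci, 0.90)
  expect_gte(good / length(g$groups), 0.95)  # few spurious groups
})

test_that("consensus takes majorities and keeps the longest member's overhang", {
  set.seed(46)
  s <- random_seq(300)
  seqs <- c(m1 = s, m2 = s, m3 = s)
  expect_identical(unname(consense(names(seqs), seqs)), s)

  # 300 bp member shares a 99%-identical prefix of a 400 bp member
  long <- random_seq(400)
  short <- mutate_seq(substr(long, 1, 300), sample(300, 3))
  cs <- consense(c("a", "b"), c(a = short, b = long))
  expect_equal(nchar(cs), 400)
  expect_identical(substr(cs, 301, 400), substr(long, 301, 400))

  # column {A, A, G} -> A
  s1 <- paste0("A", substr(s, 2, 300))
  s2 <- s1
  s3 <- paste0("G", substr(s, 2, 300))
  cs <- consense(c("x", "y", "z"), c(x = s1, y = s2, z = s3))
  expect_identical(substr(cs, 1, 1), "A")
})

test_that("consensus orients minus-strand members", {
  set.seed(47)
  s <- random_seq(350)
  cs <- consense(c("f", "r"), c(f = s, r = unname(revcomp(s))))
  expect_true(cs == s || cs == unname(revcomp(s)))
})

test_that("extension merges overhanging leftovers and rejects bad joins", {
  set.seed(48)
  cons <- c(cons1 = random_seq(400))
  tail100 <- random_seq(100)
  leftover <- c(ext = paste0(substr(cons, 201, 400), tail100))
  out <- incorporate_extensions(cons, leftover)
  expect_identical(out$placed, "ext")
  expect_equal(nchar(out$consensus[["cons1"]]), 500)
  expect_identical(substr(out$consensus[["cons1"]], 401, 500), tail100)

  # internal unalignable block: rejected
  mid <- paste0(substr(cons, 101, 200), random_seq(30), substr(cons, 231, 400),
                random_seq(80))
  out2 <- incorporate_extensions(cons, c(bad = mid))
  expect_length(out2$placed, 0)

  # fully contained: not merged
  out3 <- incorporate_extensions(cons, c(inner = substr(cons, 101, 350)))
  expect_length(out3$placed, 0)

  # a leftover extending two consensuses is ambiguous and skipped
  consAB <- c(c1 = random_seq(300), c2 = random_seq(300))
  bridge <- c(amb = paste0(substr(consAB[["c1"]], 201, 300), random_seq(30),
                           substr(consAB[["c2"]], 1, 100)))
  out4 <- incorporate_extensions(consAB, bridge)
  expect_identical(out4$ambiguous, "amb")
  expect_length(out4$placed, 0)
})

test_that("fragment joining respects guide coordinates and order", {
  set.seed(49)
  # guide of 200 residues; fragments cover residues 1-100 and 120-200
  nt <- paste(sample(setdiff(as.vector(outer(outer(c("A","C","G","T"),
        c("A","C","G","T"), paste0), c("A","C","G","T"), paste0)),
        c("TAA","TAG","TGA")), 200, replace = TRUE), collapse = "")
  guide <- mateseq:::.translate_nt(nt)
  f1 <- substr(nt, 1, 300)
  f2 <- substr(nt, 358, 600)   # starts at residue 120
  jf <- join_fragments(c(p1 = f1, p2 = f2), c(g1 = guide))
  expect_equal(nrow(jf$joined), 1)
  joined <- jf$consensus[[jf$joined$new_id]]
  expect_equal(nchar(joined), 300 + 57 + 243)  # 19 missing residues x 3
  expect_identical(substr(joined, 301, 357), strrep("N", 57))

  # overlapping intervals (1-100 and 60-200, overlap 41 > 15): not joined
  f2b <- substr(nt, 178, 600)
  jf2 <- join_fragments(c(p1 = f1, p2 = f2b), c(g1 = guide))
  expect_equal(nrow(jf2$joined), 0)

  # different guides: untouched
  nt2 <- paste(sample(setdiff(as.vector(outer(outer(c("A","C","G","T"),
         c("A","C","G","T"), paste0), c("A","C","G","T"), paste0)),
         c("TAA","TAG","TGA")), 150, replace = TRUE), collapse = "")
  jf3 <- join_fragments(c(p1 = f1, q1 = nt2),
                        c(g1 = guide, g2 = mateseq:::.translate_nt(nt2)))
  expect_equal(nrow(jf3$joined), 0)
  expect_setequal(names(jf3$consensus), c("p1", "q1"))
})

test_that("singleton admission applies length and guide-hit thresholds", {
  set.seed(50)
  codons <- setdiff(as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
            paste0), c("A","C","G","T"), paste0)), c("TAA","TAG","TGA"))
  nt_long <- paste(sample(codons, 400, replace = TRUE), collapse = "")
  nt_short <- paste(sample(codons, 270, replace = TRUE), collapse = "")
  guides <- c(gl = mateseq:::.translate_nt(nt_long),
              gs = mateseq:::.translate_nt(nt_short))
  cons <- c(cons1 = random_seq(500))
  leftovers <- c(long_hit = nt_long,      # 1200 bp, strong hit -> included
                 short_hit = nt_short,    # 810 bp < 1000 -> excluded
                 long_nohit = random_seq(1200))  # no guide hit -> excluded
  out <- add_singletons(cons, leftovers, guides)
  expect_identical(out$added, "long_hit")
  expect_setequal(names(out$consensus), c("cons1", "long_hit"))
})

test_that("assembly statistics match the brute-force N50 definition", {
  lens <- c(2, 2, 2, 3, 3, 4)
  contigs <- stats::setNames(vapply(lens, random_seq, character(1)),
                             paste0("c", seq_along(lens)))
  st <- transcriptome_stats(contigs)
  expect_equal(st$n50, 3)
  expect_equal(st$total_length, 16)

  expect_equal(transcriptome_stats(c(a = random_seq(100)))$n50, 100)
  expect_equal(transcriptome_stats(c(a = random_seq(500),
                                     b = random_seq(500)))$n50, 500)
  expect_error(transcriptome_stats(character(0)), "empty")

  set.seed(51)
  for (i in 1:20) {
    lens <- sample(50:2000, sample(3:30, 1), replace = TRUE)
    contigs <- stats::setNames(strrep("A", lens), paste0("c", seq_along(lens)))
    expect_equal(transcriptome_stats(contigs)$n50, oracle_n50(lens))
  }
})

test_that("the chimera screen flags concatenated loci but not exact copies", {
  set.seed(52)
  truthA <- random_seq(600)
  truthB <- random_seq(600)
  trusted <- c(tA = truthA, tB = truthB)

  clean <- assess_against_reference(c(x = truthA), trusted)
  expect_equal(clean$n_conflicts, 0)

  chimera <- paste0(substr(truthA, 1, 300), substr(truthB, 301, 600))
  bad <- assess_against_reference(c(x = chimera), trusted)
  expect_equal(bad$n_conflicts, 1)

  # 50 bp of junk appended but only 40 bp overlapping the trusted end:
  # below the conflict window, no flag
  ok <- assess_against_reference(
    c(x = paste0(substr(truthA, 1, 560), random_seq(40))), trusted)
  expect_equal(ok$n_conflicts, 0)
})

test_that("grouping then consensus shrinks the contig count, not the N50", {
  cfg <- sim_config(n_loci = 80, seed = 53)
  truth <- simulate_transcriptome(cfg)
  asm <- emit_contigs(truth, cfg)
  collapsed <- lapply(asm, function(a) collapse_redundant(a$contigs))
  pooled <- unlist(unname(collapsed))
  g <- build_groups(collapsed)
  cg <- consense_groups(g)
  st_in <- transcriptome_stats(pooled)
  st_out <- transcriptome_stats(cg$consensus)
  expect_lt(st_out$n_contigs, st_in$n_contigs)
  expect_gte(st_out$n50, st_in$n50)
})

test_that("zero-divergence groups reconstruct every truth locus byte-exactly", {
  cfg <- sim_config(n_loci = 30, interspecific_divergence = 0,
                    intraspecific_divergence = 0, het_rate_outcrosser = 0,
                    het_rate_selfer = 0, paralog_family_fraction = 0,
                    fragmentation_rate = 0, allelic_duplicate_rate = 0,
                    junk_short_contig_rate = 0, seed = 54)
  truth <- simulate_transcriptome(cfg)
  asm <- emit_contigs(truth, cfg)
  g <- build_groups(lapply(asm, function(a) collapse_redundant(a$contigs)))
  cg <- consense_groups(g)
  expect_length(cg$consensus, 30)
  expect_setequal(unname(cg$consensus), unname(truth$ancestor))
})
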