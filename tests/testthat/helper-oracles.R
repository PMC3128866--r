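# Independent oracles and small fixtures used across the suite.

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, positions) {
  v <- strsplit(seq, "")[[1]]
  v[positions] <- vapply(v[positions], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  paste(v, collapse = "")
}

# local-alignment identity oracle: full Smith-Waterman via Biostrings
oracle_local_identity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(a, b, type = "local")
  Biostrings::pid(pa) / 100
}

# Watterson's theta by direct column scan (independent of the package path)
oracle_theta <- function(seq_list, loci) {
  n <- length(seq_list)
  S <- 0L; L <- 0L
  for (lid in loci) {
    cols <- lapply(seq_list, function(s) strsplit(s[[lid]], "")[[1]])
    for (j in seq_along(cols[[1]])) {
      col <- vapply(cols, `[`, character(1), j)
      if (all(col %in% c("A", "C", "G", "T"))) {
        L <- L + 1L
        if (length(unique(col)) > 1L) S <- S + 1L
      }
    }
  }
  list(theta = S / (sum(1 / seq_len(n - 1)) * L), S = S, L = L)
}

# two-tailed Fisher's exact p by hypergeometric enumeration
oracle_fisher <- function(a, b, c_, d) {
  m <- a + c_; n2 <- b + d; k <- a + b
  xs <- max(0, k - n2):min(k, m)
  ps <- dhyper(xs, m, n2, k)
  sum(ps[ps <= dhyper(a, m, n2, k) * (1 + 1e-7)])
}

# N50 by brute force over the definition: the largest L such that contigs
# of length >= L cover at least half the total
oracle_n50 <- function(lens) {
  total <- sum(lens)
  cand <- sort(unique(lens), decreasing = TRUE)
  for (L in cand) if (sum(lens[lens >= L]) >= total / 2) return(L)
  min(lens)
}

# direct evaluation of the site-caller model for one column (independent
# arithmetic, no shared code with the package)
oracle_posterior <- function(bases, quals, het_prior = 0.001) {
  genos <- list(c("A","A"), c("C","C"), c("G","G"), c("T","T"),
                c("A","C"), c("A","G"), c("A","T"), c("C","G"),
                c("C","T"), c("G","T"))
  lik <- vapply(genos, function(g) {
    prod(vapply(seq_along(bases), function(i) {
      e <- 10^(-quals[i] / 10)
      p1 <- if (bases[i] == g[1]) 1 - e else e / 3
      p2 <- if (bases[i] == g[2]) 1 - e else e / 3
      (p1 + p2) / 2
    }, numeric(1)))
  }, numeric(1))
  prior <- c(rep((1 - het_prior) / 4, 4), rep(het_prior / 6, 6))
  post <- lik * prior
  names(post) <- vapply(genos, paste, character(1), collapse = "/")
  post / sum(post)
}

# simulate one pileup column from a known diploid genotype
simulate_column <- function(genotype, coverage, q) {
  alleles <- strsplit(genotype, "/")[[1]]
  draw <- sample(alleles, coverage, replace = TRUE)
  e <- 10^(-q / 10)
  err <- runif(coverage) < e
  draw[err] <- vapply(draw[err], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  list(bases = draw, quals = rep(q, coverage))
}
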