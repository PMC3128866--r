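# Synthetic study generator.
#
# Emulates the study design: four floral-transcriptome genotypes — one
# heterozygous outcrosser, two independently derived near-homozygous selfers,
# and a diverged selfing outgroup species — with known ortholog/paralog
# structure, per-site genotypes and log-normal expression, from which paired
# ~40 bp reads with 3'-decaying qualities and assembler-like contig sets are
# derived. Every emitted observable traces back to the recorded truth so
# downstream modules can be scored against it.

GENOTYPES <- c("outcrosser", "selfer1", "selfer2", "outgroup")
SELFERS <- c("selfer1", "selfer2", "outgroup")
INGROUP <- c("outcrosser", "selfer1", "selfer2")

#' Simulation configuration
#'
#' Defaults describe the emulated study conditions: ~900 bp loci, 0.048
#' substitutions/site to the outgroup species, 0.010 within the ingroup,
#' heterozygosity at 20% of outcrosser loci versus 5% in selfers, 5% of loci
#' in two-copy paralog families at 97% identity, ~40 bp paired reads at
#' 20-fold coverage with a 1% error rate implied by 3'-decaying qualities.
#'
#' @param n_loci number of transcript loci.
#' @param locus_meanlog,locus_sdlog log-normal locus length parameters
#'   (defaults give a mean near 900 bp).
#' @param min_locus_length shortest locus emitted (bp).
#' @param interspecific_divergence substitutions/site separating the outgroup
#'   from the ingroup ancestor.
#' @param intraspecific_divergence expected pairwise substitutions/site
#'   between ingroup genotypes (each genotype mutates at half this rate from
#'   the shared ancestor).
#' @param ingroup_div_scale named multipliers on the per-genotype ingroup
#'   branch lengths (outcrosser, selfer1, selfer2); lets tests configure
#'   asymmetric topologies.
#' @param het_rate_outcrosser,het_rate_selfer fraction of loci carrying at
#'   least one heterozygous site, per mating system (the outgroup is a
#'   selfing species and uses the selfer rate).
#' @param het_sites_per_kb expected extra heterozygous sites per kb at a
#'   heterozygous locus (each such locus gets 1 + Poisson sites).
#' @param paralog_family_fraction fraction of loci duplicated into a two-copy
#'   family.
#' @param paralog_identity within-family sequence identity.
#' @param expr_meanlog,expr_sdlog log-scale mean/sd of expression weights.
#' @param expr_corr_ingroup,expr_corr_outgroup log-scale expression
#'   correlation between ingroup pairs, and between the outgroup and any
#'   ingroup genotype.
#' @param de_fraction fraction of loci differentially expressed in all
#'   selfing genotypes relative to the outcrosser.
#' @param de_log2fold absolute log2 fold change applied to DE loci (half up,
#'   half down).
#' @param read_length read length in bp (>= 20).
#' @param read_error_rate mean per-base error rate implied by the emitted
#'   quality profile.
#' @param mean_coverage target fold coverage per genotype.
#' @param fragment_mean,fragment_sd insert-size distribution (bp).
#' @param fragmentation_rate fraction of transcripts split into two contigs.
#' @param allelic_duplicate_rate fraction of loci emitting a second
#'   >99%-identical contig (the assembler's allelic near-duplicates).
#' @param junk_short_contig_rate extra contigs < 100 bp, as a fraction of
#'   n_loci.
#' @param seed RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_loci = 500L,
                       locus_meanlog = 6.75, locus_sdlog = 0.30,
                       min_locus_length = 300L,
                       interspecific_divergence = 0.048,
                       intraspecific_divergence = 0.010,
                       ingroup_div_scale = c(outcrosser = 1, selfer1 = 1,
                                             selfer2 = 1),
                       het_rate_outcrosser = 0.20,
                       het_rate_selfer = 0.05,
                       het_sites_per_kb = 2,
                       paralog_family_fraction = 0.05,
                       paralog_identity = 0.97,
                       expr_meanlog = 3, expr_sdlog = 1,
                       expr_corr_ingroup = 0.90,
                       expr_corr_outgroup = 0.60,
                       de_fraction = 0.05, de_log2fold = 2,
                       read_length = 40L,
                       read_error_rate = 0.01,
                       mean_coverage = 20,
                       fragment_mean = 200, fragment_sd = 20,
                       fragmentation_rate = 0.05,
                       allelic_duplicate_rate = 0.05,
                       junk_short_contig_rate = 0.05,
                       seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(het_rate_outcrosser, het_rate_selfer, paralog_family_fraction,
             paralog_identity, fragmentation_rate, allelic_duplicate_rate,
             junk_short_contig_rate, de_fraction, read_error_rate,
             expr_corr_ingroup, expr_corr_outgroup)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (interspecific_divergence < 0 || interspecific_divergence >= 1 ||
      intraspecific_divergence < 0 || intraspecific_divergence >= 1)
    stop("divergences must lie in [0, 1)")
  if (n_loci < 1) stop("n_loci must be >= 1")
  if (read_length < 20) stop("read_length must be >= 20")
  if (expr_corr_outgroup > expr_corr_ingroup)
    stop("expr_corr_outgroup must not exceed expr_corr_ingroup")
  if (paralog_family_fraction > 0 &&
      (1 - paralog_identity) <= 2 * read_error_rate)
    warning("paralog divergence (1 - paralog_identity) is within the scale ",
            "of the read error rate; paralog signal may be undetectable")
  structure(cfg, class = "sim_config")
}

# codons without stop, so guide-protein translation is clean
.sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

# mutate a sequence (char string) at per-site rate; uniform random change
.mutate <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  if (length(hit) > 0L) {
    bases <- c("A", "C", "G", "T")
    cur <- match(v[hit], bases)
    v[hit] <- bases[(cur - 1L + sample(1:3, length(hit), replace = TRUE)) %% 4L + 1L]
  }
  paste(v, collapse = "")
}

#' Simulate the four-genotype truth set
#'
#' Generates diploid haplotype pairs per locus for the outcrosser, two
#' selfers and the selfing outgroup, plus paralog families, per-site
#' heterozygous genotypes, and correlated log-normal expression weights with
#' an injected differential-expression set.
#'
#' @param config a [sim_config()].
#' @return a `truth_set` list: loci table, per-genotype haplotype pairs,
#'   heterozygous-site table, paralog family table and sequences, expression
#'   weight matrix, DE truth table, and the config used.
#' @export
simulate_transcriptome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_loci
  locus_ids <- sprintf("locus%05d", seq_len(n))

  codons <- .sense_codons()
  n_cod <- pmax(ceiling(config$min_locus_length / 3),
                round(rlnorm(n, config$locus_meanlog, config$locus_sdlog) / 3))
  lens <- n_cod * 3L
  ancestor <- vapply(n_cod, function(k)
    paste(sample(codons, k, replace = TRUE), collapse = ""), character(1))
  names(ancestor) <- locus_ids

  scale <- config$ingroup_div_scale
  branch <- c(outcrosser = config$intraspecific_divergence / 2 * scale[["outcrosser"]],
              selfer1 = config$intraspecific_divergence / 2 * scale[["selfer1"]],
              selfer2 = config$intraspecific_divergence / 2 * scale[["selfer2"]],
              outgroup = config$interspecific_divergence)
  het_rate <- c(outcrosser = config$het_rate_outcrosser,
                selfer1 = config$het_rate_selfer,
                selfer2 = config$het_rate_selfer,
                outgroup = config$het_rate_selfer)

  haplotypes <- list()
  het_rows <- list()
  for (g in GENOTYPES) {
    hap1 <- vapply(ancestor, .mutate, character(1), rate = branch[[g]])
    names(hap1) <- locus_ids
    hap2 <- hap1
    is_het <- runif(n) < het_rate[[g]]
    for (i in which(is_het)) {
      n_sites <- 1L + rpois(1L, lens[i] / 1000 * config$het_sites_per_kb)
      pos <- sort(sample.int(lens[i], min(n_sites, lens[i])))
      v <- strsplit(hap2[i], "")[[1]]
      bases <- c("A", "C", "G", "T")
      cur <- match(v[pos], bases)
      alt <- bases[(cur - 1L + sample(1:3, length(pos), replace = TRUE)) %% 4L + 1L]
      het_rows[[length(het_rows) + 1L]] <- data.frame(
        genotype = g, locus_id = locus_ids[i], pos = pos,
        allele1 = v[pos], allele2 = alt, stringsAsFactors = FALSE)
      v[pos] <- alt
      hap2[i] <- paste(v, collapse = "")
    }
    haplotypes[[g]] <- list(hap1 = hap1, hap2 = hap2)
  }
  het_sites <- if (length(het_rows) > 0) do.call(rbind, het_rows) else
    data.frame(genotype = character(0), locus_id = character(0),
               pos = integer(0), allele1 = character(0),
               allele2 = character(0), stringsAsFactors = FALSE)

  # paralog families: duplicate the ancestor before genotype divergence,
  # mutate the copy down to paralog_identity, then diverge per genotype
  n_par <- floor(config$paralog_family_fraction * n)
  par_parent <- if (n_par > 0) sort(sample(locus_ids, n_par)) else character(0)
  paralog_seqs <- list()
  if (n_par > 0) {
    par_anc <- vapply(ancestor[par_parent], .mutate, character(1),
                      rate = 1 - config$paralog_identity)
    for (g in GENOTYPES) {
      ps <- vapply(par_anc, .mutate, character(1), rate = branch[[g]])
      names(ps) <- paste0(par_parent, "_par")
      paralog_seqs[[g]] <- ps
    }
  }
  paralogs <- data.frame(
    parent_locus = par_parent,
    copy_id = if (n_par > 0) paste0(par_parent, "_par") else character(0),
    stringsAsFactors = FALSE)

  # expression: factor model giving corr r_in within the ingroup and r_out
  # between the outgroup and each ingroup genotype, on the log scale
  r_in <- config$expr_corr_ingroup
  r_out <- config$expr_corr_outgroup
  a <- rnorm(n); b <- rnorm(n)
  z <- vapply(GENOTYPES, function(g) {
    if (g == "outgroup") sqrt(r_out) * a + sqrt(1 - r_out) * rnorm(n)
    else sqrt(r_out) * a + sqrt(r_in - r_out) * b + sqrt(1 - r_in) * rnorm(n)
  }, numeric(n))
  z <- matrix(z, nrow = n, dimnames = list(NULL, GENOTYPES))
  logw <- config$expr_meanlog + config$expr_sdlog * z

  n_de <- floor(config$de_fraction * n)
  de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer(0)
  de_dir <- rep(c(1, -1), length.out = n_de)
  if (n_de > 0) {
    shift <- de_dir * config$de_log2fold * log(2)
    logw[de_idx, SELFERS] <- logw[de_idx, SELFERS] + shift
  }
  de_truth <- data.frame(locus_id = locus_ids[de_idx],
                         direction = ifelse(de_dir > 0, "up", "down"),
                         stringsAsFactors = FALSE)
  expression <- exp(logw)
  rownames(expression) <- locus_ids

  structure(list(
    config = config,
    genotypes = GENOTYPES, selfers = SELFERS, ingroup = INGROUP,
    loci = data.frame(locus_id = locus_ids, length = lens,
                      stringsAsFactors = FALSE),
    ancestor = ancestor,
    haplotypes = haplotypes,
    het_sites = het_sites,
    paralogs = paralogs,
    paralog_seqs = paralog_seqs,
    expression = expression,
    de_truth = de_truth
  ), class = "truth_set")
}

#' Count truly heterozygous loci per genotype
#' @param truth a `truth_set`.
#' @return named integer vector.
#' @export
true_het_locus_counts <- function(truth) {
  counts <- table(factor(unique(truth$het_sites[c("genotype", "locus_id")])$genotype,
                         levels = truth$genotypes))
  stats::setNames(as.integer(counts), truth$genotypes)
}

# deterministic 3'-decaying quality profile, shifted so the mean implied
# error probability matches the configured rate
.quality_profile <- function(read_length, error_rate) {
  if (error_rate <= 0) return(rep(40L, read_length))   # error-free contract
  q0 <- seq(38, 15, length.out = read_length)
  shift <- -10 * log10(error_rate / mean(phred_error_prob(q0)))
  as.integer(round(pmax(2, pmin(40, q0 - shift))))
}

#' Simulate paired-end reads for every genotype
#'
#' Fragments are sampled per locus proportional to expression weight times
#' length, insert sizes are Normal(fragment_mean, fragment_sd), each fragment
#' picks one of the two haplotypes, and both 5' mates carry the 3'-decaying
#' quality profile with per-base errors drawn at the probability each emitted
#' quality implies.
#'
#' @param truth a `truth_set` from [simulate_transcriptome()].
#' @param config the [sim_config()] used to build it.
#' @return list per genotype: `r1`, `r2` read-set data.frames,
#'   `fragments` (fragment-level truth: locus, haplotype, start, length) and
#'   `frag_counts` (named per-locus fragment counts, paralog copies
#'   included).
#' @export
simulate_reads <- function(truth, config = truth$config) {
  set.seed(config$seed + 1L)
  rl <- config$read_length
  qprof <- .quality_profile(rl, config$read_error_rate)
  qstr <- phred_encode(qprof)
  bases <- c("A", "C", "G", "T")
  out <- list()

  for (g in truth$genotypes) {
    hap1 <- truth$haplotypes[[g]]$hap1
    hap2 <- truth$haplotypes[[g]]$hap2
    seq_ids <- truth$loci$locus_id
    lens <- truth$loci$length
    w <- truth$expression[, g]
    if (nrow(truth$paralogs) > 0) {
      pseq <- truth$paralog_seqs[[g]]
      seq_ids <- c(seq_ids, names(pseq))
      lens <- c(lens, nchar(pseq))
      w <- c(w, truth$expression[truth$paralogs$parent_locus, g])
      hap1 <- c(hap1, pseq)
      hap2 <- c(hap2, pseq)
    }
    prob <- w * lens
    total_frags <- round(config$mean_coverage * sum(truth$loci$length) / (2 * rl))
    counts <- as.integer(rmultinom(1, total_frags, prob))
    names(counts) <- seq_ids

    locus_of <- rep.int(seq_ids, counts)
    len_of <- rep.int(lens, counts)
    nfrag <- length(locus_of)
    flen <- pmin(pmax(round(rnorm(nfrag, config$fragment_mean,
                                  config$fragment_sd)), rl), len_of)
    start <- floor(runif(nfrag) * (len_of - flen + 1)) + 1L
    hap_pick <- rbinom(nfrag, 1, 0.5)
    src <- ifelse(hap_pick == 0, hap1[locus_of], hap2[locus_of])
    m1 <- substring(src, start, start + rl - 1L)
    m2 <- revcomp(substring(src, start + flen - rl, start + flen - 1L))

    # per-base errors at the rate implied by the emitted qualities
    allreads <- c(m1, m2)
    eps <- phred_error_prob(qprof)
    nreads <- length(allreads)
    if (nreads > 0 && config$read_error_rate > 0) {
      chm <- matrix(unlist(strsplit(allreads, ""), use.names = FALSE),
                    ncol = rl, byrow = TRUE)
      err <- matrix(runif(nreads * rl), ncol = rl, byrow = TRUE) <
        matrix(eps, nrow = nreads, ncol = rl, byrow = TRUE)
      hit <- which(err)
      if (length(hit) > 0L) {
        cur <- match(chm[hit], bases)
        chm[hit] <- bases[(cur - 1L + sample(1:3, length(hit), replace = TRUE)) %% 4L + 1L]
      }
      allreads <- do.call(paste0, lapply(seq_len(rl), function(j) chm[, j]))
    }
    m1 <- allreads[seq_len(nfrag)]
    m2 <- allreads[nfrag + seq_len(nfrag)]

    ids <- sprintf("%s_frag%07d", g, seq_len(nfrag))
    out[[g]] <- list(
      r1 = data.frame(id = paste0(ids, "/1"), seq = m1,
                      qual = rep(qstr, nfrag), stringsAsFactors = FALSE),
      r2 = data.frame(id = paste0(ids, "/2"), seq = m2,
                      qual = rep(qstr, nfrag), stringsAsFactors = FALSE),
      fragments = data.frame(fragment = ids, locus_id = locus_of,
                             haplotype = hap_pick + 1L, start = start,
                             length = flen, stringsAsFactors = FALSE),
      frag_counts = counts
    )
  }
  out
}

#' Emit assembler-like contig sets per genotype
#'
#' One contig per locus (the haplotype-1 consensus an assembler would
#' collapse to), with a configurable fraction of transcripts split into two
#' fragments, a fraction emitting a second near-identical (allelic) contig
#' from haplotype 2, and short junk contigs. Paralog copies emit no contig of
#' their own — the family collapses onto the parent locus, which is what
#' makes mis-mapped paralog reads visible downstream.
#'
#' @param truth a `truth_set`.
#' @param config the [sim_config()] used to build it.
#' @return list per genotype: `contigs` (named character vector) and `map`
#'   (truth table: contig_id, locus_id, part).
#' @export
emit_contigs <- function(truth, config = truth$config) {
  set.seed(config$seed + 2L)
  out <- list()
  n <- nrow(truth$loci)
  for (g in truth$genotypes) {
    hap1 <- truth$haplotypes[[g]]$hap1
    hap2 <- truth$haplotypes[[g]]$hap2
    lens <- truth$loci$length
    ids <- truth$loci$locus_id
    frag <- runif(n) < config$fragmentation_rate
    dup <- runif(n) < config$allelic_duplicate_rate

    contigs <- character(0)
    map <- list()
    for (i in seq_len(n)) {
      cid <- sprintf("%s_c%05d", g, i)
      if (frag[i] && lens[i] >= 300L) {
        cut <- round(lens[i] * runif(1, 0.4, 0.6))
        gap <- sample(-30:20, 1)  # negative = overlap, positive = missing
        e1 <- max(100L, cut)
        s2 <- min(lens[i] - 100L + 1L, cut + gap + 1L)
        f1 <- substr(hap1[i], 1L, e1)
        f2 <- substr(hap1[i], s2, lens[i])
        contigs[paste0(cid, "_f1")] <- f1
        contigs[paste0(cid, "_f2")] <- f2
        map[[length(map) + 1L]] <- data.frame(
          contig_id = paste0(cid, c("_f1", "_f2")), locus_id = ids[i],
          part = c("fragment1", "fragment2"), stringsAsFactors = FALSE)
      } else {
        contigs[cid] <- hap1[i]
        map[[length(map) + 1L]] <- data.frame(
          contig_id = cid, locus_id = ids[i], part = "full",
          stringsAsFactors = FALSE)
      }
      if (dup[i] && !frag[i]) {
        contigs[paste0(cid, "_allele")] <- hap2[i]
        map[[length(map) + 1L]] <- data.frame(
          contig_id = paste0(cid, "_allele"), locus_id = ids[i],
          part = "allelic_duplicate", stringsAsFactors = FALSE)
      }
    }
    n_junk <- round(config$junk_short_contig_rate * n)
    if (n_junk > 0) {
      jl <- sample(30:99, n_junk, replace = TRUE)
      junk <- vapply(jl, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
        character(1))
      names(junk) <- sprintf("%s_junk%03d", g, seq_len(n_junk))
      contigs <- c(contigs, junk)
      map[[length(map) + 1L]] <- data.frame(
        contig_id = names(junk), locus_id = NA_character_, part = "junk",
        stringsAsFactors = FALSE)
    }
    out[[g]] <- list(contigs = contigs, map = do.call(rbind, map))
  }
  out
}

#' Emit guide proteins and a gene-to-GO map for the truth loci
#'
#' Each locus translates (frame 1, stop-free by construction) into one guide
#' protein; fragments of a locus therefore share a guide. GO terms are drawn
#' from a small flat ontology, 1-5 terms per locus.
#'
#' @param truth a `truth_set`.
#' @param n_terms size of the toy ontology.
#' @return list: `guides` (named character vector of protein sequences,
#'   guide id = g + locus number) and `go_map` (data.frame gene_id, terms —
#'   comma-separated GO ids).
#' @export
emit_annotations <- function(truth, n_terms = 30L) {
  set.seed(truth$config$seed + 3L)
  aa <- suppressWarnings(Biostrings::translate(
    Biostrings::DNAStringSet(truth$ancestor), if.fuzzy.codon = "X"))
  guides <- as.character(aa)
  names(guides) <- sub("^locus", "g", truth$loci$locus_id)
  ontology <- sprintf("GO:%07d", seq_len(n_terms))
  terms <- vapply(seq_len(nrow(truth$loci)), function(i)
    paste(sort(sample(ontology, sample(1:5, 1))), collapse = ","),
    character(1))
  list(guides = guides,
       go_map = data.frame(gene_id = truth$loci$locus_id, terms = terms,
                           stringsAsFactors = FALSE))
}

#' Write the truth tables of a simulation to TSV + FASTA
#'
#' Serialises the locus table, heterozygous-site table, paralog table,
#' expression weights and per-genotype haplotypes so downstream results can
#' be joined against them.
#'
#' @param truth a `truth_set`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(truth$loci, "loci.tsv")
  tsv(truth$het_sites, "het_sites.tsv")
  tsv(truth$paralogs, "paralogs.tsv")
  tsv(data.frame(locus_id = rownames(truth$expression), truth$expression),
      "expression_weights.tsv")
  tsv(truth$de_truth, "de_truth.tsv")
  for (g in truth$genotypes) {
    write_fasta(truth$haplotypes[[g]]$hap1,
                file.path(dir, paste0(g, "_hap1.fasta")))
    write_fasta(truth$haplotypes[[g]]$hap2,
                file.path(dir, paste0(g, "_hap2.fasta")))
  }
  invisible(dir)
}

#' Parse a flat key = value config file into a sim_config
#'
#' Lines are `key = value`; `#` comments and blank lines are ignored; vector
#' values (ingroup_div_scale) are comma-separated name=value pairs.
#'
#' @param path config file path.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, `[`, character(1), 2))
  args <- list()
  for (i in seq_along(keys)) {
    v <- vals[i]
    if (keys[i] == "ingroup_div_scale") {
      parts <- strsplit(strsplit(v, ",")[[1]], ":")
      args[[keys[i]]] <- stats::setNames(
        as.numeric(trimws(vapply(parts, `[`, character(1), 2))),
        trimws(vapply(parts, `[`, character(1), 1)))
    } else {
      num <- suppressWarnings(as.numeric(v))
      args[[keys[i]]] <- if (is.na(num)) v else num
    }
  }
  do.call(sim_config, args)
}
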