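# End-to-end pipeline over a simulated study.
#
# Runs simulate -> reads -> contigs -> trim -> collapse -> group -> consense
# -> extend -> join -> singletons -> map -> genotype -> paralog flag ->
# conservative set -> divergence + theta -> fragment counts -> FPKM ->
# correlations -> differential expression -> GO enrichment, and returns
# every intermediate needed by the reports. All computation lives in the
# module functions; this is plumbing plus a manifest.

#' Run the full pipeline on a simulated study
#'
#' @param config a [sim_config()].
#' @param bootstrap_reps bootstrap replicates for correlation intervals
#'   (default 1000 here; the per-pair function default is 10000).
#' @param enrichment whether to run the GO-enrichment contrasts.
#' @return a `pipeline_result` list; see the elements for each stage.
#' @export
run_pipeline <- function(config = sim_config(), bootstrap_reps = 1000L,
                         enrichment = TRUE) {
  truth <- simulate_transcriptome(config)
  reads <- simulate_reads(truth, config)
  asm <- emit_contigs(truth, config)
  ann <- emit_annotations(truth)

  policy <- trim_policy()
  trimmed <- lapply(reads, function(r) trim_pairs(r$r1, r$r2, policy))

  collapsed <- lapply(asm, function(a) collapse_redundant(a$contigs))

  grouping <- build_groups(collapsed)
  cg <- consense_groups(grouping)
  stats0 <- rbind(
    transcriptome_stats(unlist(unname(collapsed)), "pooled_input"),
    transcriptome_stats(cg$consensus, "reciprocal_groups"))

  leftovers <- grouping$sequences[grouping$leftovers]
  ext <- incorporate_extensions(cg$consensus, leftovers)
  stats0 <- rbind(stats0, transcriptome_stats(ext$consensus, "extension"))

  jf <- join_fragments(ext$consensus, ann$guides)
  stats0 <- rbind(stats0, transcriptome_stats(jf$consensus, "fragment_joining"))

  remaining <- leftovers[setdiff(names(leftovers), ext$placed)]
  sing <- add_singletons(jf$consensus, remaining, ann$guides)
  reference <- sing$consensus
  stats0 <- rbind(stats0, transcriptome_stats(reference, "final"))

  genotypes <- list()
  for (g in truth$genotypes) {
    aln1 <- map_reads(trimmed[[g]]$r1, reference)
    aln2 <- map_reads(trimmed[[g]]$r2, reference)
    pile <- rbind(pileup(aln1, reference), pileup(aln2, reference))
    calls <- call_columns(pile)
    geno <- genotype_loci(calls, reference)
    genotypes[[g]] <- list(aln1 = aln1, aln2 = aln2, calls = calls,
                           table = geno$table, sequences = geno$sequences)
  }
  tables <- lapply(genotypes, `[[`, "table")
  sequences <- lapply(genotypes, `[[`, "sequences")

  flags <- flag_mapping_errors(tables, truth$selfers)
  clean <- flags$locus_id[flags$status == "CLEAN"]
  cons_loci <- intersect(conservative_set(tables, truth$selfers), clean)
  dm <- if (length(cons_loci) > 0) divergence_matrix(sequences, cons_loci)
        else NULL
  theta <- if (length(cons_loci) > 0)
    watterson_theta(sequences[truth$ingroup], cons_loci) else NULL

  counts <- list(); totals <- numeric(0)
  for (g in truth$genotypes) {
    cf <- count_fragments(genotypes[[g]]$aln1, genotypes[[g]]$aln2, reference)
    counts[[g]] <- cf$counts
    totals[g] <- cf$total
  }
  lens <- stats::setNames(nchar(reference), names(reference))
  fpkm_mat <- vapply(truth$genotypes, function(g)
    fpkm(counts[[g]], lens, totals[g]), numeric(length(reference)))
  rownames(fpkm_mat) <- names(reference)

  correlations <- correlate_samples(fpkm_mat, reps = bootstrap_reps,
                                    seed = config$seed)

  de <- list()
  for (s in truth$selfers)
    de[[s]] <- differential_expression(counts[["outcrosser"]], counts[[s]],
                                       totals["outcrosser"], totals[s], lens)
  shared_up <- intersect_de_sets(de, "up")
  shared_down <- intersect_de_sets(de, "down")

  enrich <- NULL
  if (enrichment) {
    # map reference loci to truth loci for annotation via the group table
    term_map <- stats::setNames(strsplit(ann$go_map$terms, ","),
                                ann$go_map$gene_id)
    locus_of_ref <- .reference_truth_map(cg$group_table, asm, names(reference))
    ref_terms <- term_map[locus_of_ref]
    names(ref_terms) <- names(locus_of_ref)
    ref_terms <- ref_terms[!vapply(ref_terms, is.null, logical(1))]
    universe <- names(ref_terms)
    enrich <- list()
    for (set_name in c("up_in_selfers", "down_in_selfers")) {
      ids <- intersect(if (set_name == "up_in_selfers") shared_up else
                       shared_down, universe)
      enrich[[set_name]] <- if (length(ids) > 0)
        go_enrichment(ids, universe, ref_terms) else NULL
    }
  }

  structure(list(
    config = config, truth = truth, reads = reads, trimmed = trimmed,
    assemblies = asm, annotations = ann, collapsed = collapsed,
    grouping = grouping, consensus_groups = cg, extensions = ext,
    joins = jf, singletons = sing, reference = reference,
    assembly_stats = stats0, genotypes = genotypes, flags = flags,
    conservative_loci = cons_loci, divergence = dm, theta = theta,
    counts = counts, totals = totals, fpkm = fpkm_mat,
    correlations = correlations, de = de,
    shared_up = shared_up, shared_down = shared_down,
    enrichment = enrich
  ), class = "pipeline_result")
}

# best-effort map: reference (consensus/contig) id -> truth locus id, via
# the group membership table and the per-sample contig truth maps
.reference_truth_map <- function(group_table, asm, ref_ids) {
  contig2locus <- do.call(rbind, lapply(asm, `[[`, "map"))
  g2l <- stats::setNames(
    contig2locus$locus_id[match(group_table$contig_id,
                                contig2locus$contig_id)],
    group_table$group_id)
  g2l <- g2l[!is.na(g2l)]
  g2l <- g2l[!duplicated(names(g2l))]
  out <- stats::setNames(rep(NA_character_, length(ref_ids)), ref_ids)
  base_id <- sub("_joined$", "", ref_ids)
  known <- base_id %in% names(g2l)
  out[known] <- g2l[base_id[known]]
  direct <- contig2locus$locus_id[match(base_id, contig2locus$contig_id)]
  out[is.na(out)] <- direct[is.na(out)]
  out[!is.na(out)]
}

#' Assert the cross-stage invariants of a pipeline result
#'
#' Checks the properties the analysis depends on: contig count decreases and
#' N50 does not decrease from pooled input to grouped consensus; the
#' divergence matrix is symmetric with ingroup-outgroup exceeding
#' ingroup-internal divergence; the FPKM conservation identity holds per
#' sample; correlation estimates are within [-1, 1] with CIs bracketing the
#' point estimates. Stops on violation.
#'
#' @param res a `pipeline_result`.
#' @return TRUE, invisibly.
#' @export
check_invariants <- function(res) {
  st <- res$assembly_stats
  pooled <- st[st$stage == "pooled_input", ]
  grouped <- st[st$stage == "reciprocal_groups", ]
  stopifnot(grouped$n_contigs < pooled$n_contigs,
            grouped$n50 >= pooled$n50)
  if (!is.null(res$divergence)) {
    d <- res$divergence$divergence
    stopifnot(isTRUE(all.equal(d, t(d))))
    ing <- res$truth$ingroup
    in_in <- d[ing, ing][upper.tri(d[ing, ing])]
    in_out <- d[ing, "outgroup"]
    stopifnot(min(in_out) > max(in_in))
  }
  lens <- nchar(res$reference)
  for (g in names(res$counts)) {
    if (res$totals[g] == 0) next
    lhs <- sum(res$fpkm[, g] * lens) * res$totals[g] / 1e9
    stopifnot(abs(lhs - sum(res$counts[[g]])) <= 1e-6 * max(1, lhs))
  }
  with(res$correlations, stopifnot(all(r >= ci_low - 1e-9),
                                   all(r <= ci_high + 1e-9),
                                   all(abs(r) <= 1)))
  invisible(TRUE)
}

#' Write the pipeline's summary tables to a directory
#'
#' Emits the assembly-stage statistics, per-sample locus summaries, the
#' SNP/divergence table, the theta report, the correlation report, DE
#' tables and enrichment tables as TSV, plus a JSON-free manifest of inputs,
#' parameters and output hashes.
#'
#' @param res a `pipeline_result`.
#' @param dir output directory.
#' @return named character vector of written paths, invisibly.
#' @export
write_reports <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) {
    p <- file.path(dir, f)
    write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(assembly_stats = tsv(res$assembly_stats, "assembly_stats.tsv"))
  locus_summary <- do.call(rbind, lapply(names(res$genotypes), function(g) {
    t <- res$genotypes[[g]]$table
    data.frame(sample = g, n_loci = sum(t$present),
               mean_coverage = mean(t$mean_coverage),
               sd_coverage = sd(t$mean_coverage),
               n_het_loci = sum(t$present & t$het_site_count > 0),
               total_bp = sum(t$length[t$present]), stringsAsFactors = FALSE)
  }))
  paths["locus_summary"] <- tsv(locus_summary, "locus_summary.tsv")
  if (!is.null(res$divergence)) {
    paths["divergence"] <- tsv(
      data.frame(sample = rownames(res$divergence$snp),
                 format_divergence_table(res$divergence),
                 check.names = FALSE), "divergence_matrix.tsv")
  }
  if (!is.null(res$theta)) {
    paths["theta"] <- tsv(data.frame(res$theta[c("n", "S", "a_n", "L",
                                                 "theta")]), "theta.tsv")
  }
  paths["correlations"] <- tsv(res$correlations, "correlations.tsv")
  for (s in names(res$de))
    paths[paste0("de_", s)] <- tsv(res$de[[s]], paste0("de_", s, ".tsv"))
  if (!is.null(res$enrichment)) {
    for (nm in names(res$enrichment))
      if (!is.null(res$enrichment[[nm]]))
        paths[paste0("enrich_", nm)] <- tsv(res$enrichment[[nm]],
                                            paste0("enrich_", nm, ".tsv"))
  }
  manifest <- data.frame(
    file = basename(unname(paths)),
    md5 = unname(tools::md5sum(unname(paths))),
    seed = res$config$seed, n_loci = res$config$n_loci,
    stringsAsFactors = FALSE)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
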