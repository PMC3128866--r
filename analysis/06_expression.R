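# Stage 6: fragment counts per locus, FPKM, log-scale expression
# correlations with bootstrap 95% intervals, and differential expression of
# each selfing genotype against the outcrosser with BH FDR control.

source("analysis/00_config.R")
st <- load_state("01_simulate", "analysis/01_simulate.R")
cons <- load_state("03_consensus", "analysis/03_consensus.R")
gt <- load_state("04_genotype", "analysis/04_genotype.R")

reference <- cons$reference
lens <- stats::setNames(nchar(reference), names(reference))

counts <- list(); totals <- numeric(0)
for (g in st$truth$genotypes) {
  cf <- count_fragments(gt$genotypes[[g]]$aln1, gt$genotypes[[g]]$aln2,
                        reference)
  counts[[g]] <- cf$counts
  totals[g] <- cf$total
}
fpkm_mat <- vapply(st$truth$genotypes, function(g)
  fpkm(counts[[g]], lens, totals[g]), numeric(length(reference)))
rownames(fpkm_mat) <- names(reference)
write_result(data.frame(locus_id = rownames(fpkm_mat), round(fpkm_mat, 3)),
             "fpkm_matrix.tsv")

correlations <- correlate_samples(fpkm_mat, reps = 10000L,
                                  seed = ANALYSIS_SEED)
write_result(correlations, "correlations.tsv")
message("expression correlations (r, 95% CI):")
for (i in seq_len(nrow(correlations)))
  message(sprintf("  %s - %s: %.3f [%.3f, %.3f]",
                  correlations$sample_a[i], correlations$sample_b[i],
                  correlations$r[i], correlations$ci_low[i],
                  correlations$ci_high[i]))

de <- list()
for (s in st$truth$selfers) {
  de[[s]] <- differential_expression(counts[["outcrosser"]], counts[[s]],
                                     totals["outcrosser"], totals[s], lens)
  write_result(de[[s]], paste0("de_outcrosser_vs_", s, ".tsv"))
}
shared_up <- intersect_de_sets(de, "up")
shared_down <- intersect_de_sets(de, "down")
writeLines(shared_up, file.path(RESULTS_DIR, "de_up_in_all_selfers.txt"))
writeLines(shared_down, file.path(RESULTS_DIR, "de_down_in_all_selfers.txt"))
message(length(shared_up), " loci up and ", length(shared_down),
        " down in all selfing genotypes vs the outcrosser")

save_state(list(counts = counts, totals = totals, fpkm = fpkm_mat, de = de,
                shared_up = shared_up, shared_down = shared_down),
           "06_expression")
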