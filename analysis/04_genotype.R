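# Stage 4: map trimmed reads back to the consensus reference, call diploid
# genotypes per site (coverage > 5, consensus quality Q > 13), summarise
# loci per sample, and flag suspected read-mapping errors from residual
# selfer heterozygosity.

source("analysis/00_config.R")
trimmed <- load_state("02_trim", "analysis/02_trim.R")
cons <- load_state("03_consensus", "analysis/03_consensus.R")
st <- load_state("01_simulate", "analysis/01_simulate.R")

reference <- cons$reference
genotypes <- list()
for (g in st$truth$genotypes) {
  aln1 <- map_reads(trimmed[[g]]$r1, reference)
  aln2 <- map_reads(trimmed[[g]]$r2, reference)
  calls <- call_columns(rbind(pileup(aln1, reference),
                              pileup(aln2, reference)))
  geno <- genotype_loci(calls, reference)
  write_fasta(geno$sequences,
              file.path(STATE_DIR, paste0(g, "_called.fasta")))
  genotypes[[g]] <- list(aln1 = aln1, aln2 = aln2, table = geno$table,
                         sequences = geno$sequences)
  message(g, ": ", sum(geno$table$present), " loci present, ",
          sum(geno$table$present & geno$table$het_site_count > 0),
          " heterozygous")
}

locus_summary <- do.call(rbind, lapply(names(genotypes), function(g) {
  t <- genotypes[[g]]$table
  data.frame(sample = g, n_loci = sum(t$present),
             mean_coverage = round(mean(t$mean_coverage), 1),
             sd_coverage = round(sd(t$mean_coverage), 1),
             n_het_loci = sum(t$present & t$het_site_count > 0),
             total_bp = sum(t$length[t$present]), stringsAsFactors = FALSE)
}))
write_result(locus_summary, "locus_summary.tsv")

flags <- flag_mapping_errors(lapply(genotypes, `[[`, "table"),
                             st$truth$selfers)
write_result(flags, "mapping_error_flags.tsv")
message("paralogy screen: ", paste(names(table(flags$status)),
        table(flags$status), collapse = ", ", sep = "="))

save_state(list(genotypes = genotypes, flags = flags), "04_genotype")
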