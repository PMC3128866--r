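# Stage 5: conservative locus set (present everywhere, homozygous in all
# selfers, clean paralogy screen), pairwise SNP/divergence matrix in the
# two-triangle layout, and Watterson's theta for the ingroup.

source("analysis/00_config.R")
st <- load_state("01_simulate", "analysis/01_simulate.R")
gt <- load_state("04_genotype", "analysis/04_genotype.R")

tables <- lapply(gt$genotypes, `[[`, "table")
sequences <- lapply(gt$genotypes, `[[`, "sequences")

clean <- gt$flags$locus_id[gt$flags$status == "CLEAN"]
cons_loci <- intersect(conservative_set(tables, st$truth$selfers), clean)
writeLines(cons_loci, file.path(RESULTS_DIR, "conservative_loci.txt"))
message(length(cons_loci), " loci in the conservative set")

dm <- divergence_matrix(sequences, cons_loci)
write_result(data.frame(sample = rownames(dm$snp),
                        format_divergence_table(dm), check.names = FALSE),
             "divergence_matrix.tsv")

theta <- watterson_theta(sequences[st$truth$ingroup], cons_loci)
write_result(data.frame(theta[c("n", "S", "a_n", "L", "theta")]),
             "theta.tsv")
message(sprintf("theta_W = %.4f over %d sites (S = %d)",
                theta$theta, theta$L, theta$S))

save_state(list(cons_loci = cons_loci, divergence = dm, theta = theta),
           "05_popgen")
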