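# Stage 1: simulate the four-genotype study (truth, paired reads,
# assembler-like contigs, guide proteins and GO map) and persist the truth
# tables so every later stage can be scored against them.

source("analysis/00_config.R")

cfg <- analysis_config()
truth <- simulate_transcriptome(cfg)
reads <- simulate_reads(truth, cfg)
asm <- emit_contigs(truth, cfg)
ann <- emit_annotations(truth)

write_truth(truth, file.path(STATE_DIR, "truth"))  # bulky: stays in scratch
for (g in truth$genotypes) {
  write_fastq(reads[[g]]$r1, file.path(STATE_DIR, paste0(g, "_1.fastq")))
  write_fastq(reads[[g]]$r2, file.path(STATE_DIR, paste0(g, "_2.fastq")))
  write_fasta(asm[[g]]$contigs, file.path(STATE_DIR, paste0(g, "_contigs.fasta")))
}
write_fasta(truth$ancestor, file.path(STATE_DIR, "truth_loci.fasta"))
write_go_map(ann$go_map, file.path(STATE_DIR, "go_map.tsv"))

save_state(list(cfg = cfg, truth = truth, reads = reads, asm = asm,
                ann = ann), "01_simulate")

message(sprintf("simulated %d loci across 4 genotypes; %d truly het loci in the outcrosser vs %d / %d in the selfers; %d paralog families",
                cfg$n_loci,
                true_het_locus_counts(truth)[["outcrosser"]],
                true_het_locus_counts(truth)[["selfer1"]],
                true_het_locus_counts(truth)[["selfer2"]],
                nrow(truth$paralogs)))
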