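# Stage 3: build the consensus reference transcriptome — per-sample
# redundancy collapse, four-way RBH grouping, consensus with overhang
# retention, extension with unplaced contigs, protein-guided fragment
# joining, singleton admission — and track the assembly statistics through
# each stage, mirroring the progressive-summary view of the analysis.

source("analysis/00_config.R")
st <- load_state("01_simulate", "analysis/01_simulate.R")

collapsed <- lapply(st$asm, function(a) collapse_redundant(a$contigs))
stats <- transcriptome_stats(unlist(unname(collapsed)), "pooled_input")

grouping <- build_groups(collapsed)
cg <- consense_groups(grouping)
stats <- rbind(stats, transcriptome_stats(cg$consensus, "reciprocal_groups"))

leftovers <- grouping$sequences[grouping$leftovers]
ext <- incorporate_extensions(cg$consensus, leftovers)
stats <- rbind(stats, transcriptome_stats(ext$consensus, "extension"))

jf <- join_fragments(ext$consensus, st$ann$guides)
stats <- rbind(stats, transcriptome_stats(jf$consensus, "fragment_joining"))

remaining <- leftovers[setdiff(names(leftovers), ext$placed)]
sing <- add_singletons(jf$consensus, remaining, st$ann$guides)
reference <- sing$consensus
stats <- rbind(stats, transcriptome_stats(reference, "final"))

write_result(stats, "assembly_stats.tsv")
write_result(cg$group_table, "ortholog_groups.tsv")
write_fasta(reference, file.path(STATE_DIR, "reference.fasta"))

# accuracy check against the trusted truth loci (the stand-in for an
# independently sequenced EST set)
conflicts <- assess_against_reference(reference, st$truth$ancestor)
write_result(conflicts$report, "assembly_conflicts.tsv")

save_state(list(reference = reference, stats = stats, grouping = grouping,
                group_table = cg$group_table), "03_consensus")

message(sprintf("reference: %d contigs, N50 %d bp, %d conflicts vs truth",
                length(reference), stats$n50[stats$stage == "final"],
                conflicts$n_conflicts))
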