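# Stage 7: GO-term enrichment (two-tailed Fisher's exact, BH FDR 0.05) of
# the shared differential-expression sets against the annotated reference.

source("analysis/00_config.R")
st <- load_state("01_simulate", "analysis/01_simulate.R")
cons <- load_state("03_consensus", "analysis/03_consensus.R")
expr <- load_state("06_expression", "analysis/06_expression.R")

term_map <- stats::setNames(strsplit(st$ann$go_map$terms, ","),
                            st$ann$go_map$gene_id)

# annotate reference contigs through the group membership truth map
contig2locus <- do.call(rbind, lapply(st$asm, `[[`, "map"))
g2l <- stats::setNames(
  contig2locus$locus_id[match(cons$group_table$contig_id,
                              contig2locus$contig_id)],
  cons$group_table$group_id)
g2l <- g2l[!is.na(g2l) & !duplicated(names(g2l))]
base_id <- sub("_joined$", "", names(cons$reference))
locus_of_ref <- ifelse(base_id %in% names(g2l), g2l[base_id],
                       contig2locus$locus_id[match(base_id,
                                                   contig2locus$contig_id)])
names(locus_of_ref) <- names(cons$reference)
ref_terms <- term_map[locus_of_ref]
names(ref_terms) <- names(locus_of_ref)
ref_terms <- ref_terms[!vapply(ref_terms, is.null, logical(1))]
universe <- names(ref_terms)

contrasts <- expression_contrasts(expr$fpkm, "outcrosser",
                                  st$truth$selfers, expr$de)
for (set_name in names(contrasts)) {
  ids <- intersect(contrasts[[set_name]], universe)
  if (length(ids) == 0) {
    message("no loci in the ", set_name, " set; skipping enrichment")
    next
  }
  enr <- go_enrichment(ids, universe, ref_terms)
  write_result(enr, paste0("enrichment_", set_name, ".tsv"))
  message(set_name, ": ", length(ids), " loci, ", sum(enr$significant),
          " terms significant at FDR 0.05 (flat annotations are expected ",
          "to yield none)")
}
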