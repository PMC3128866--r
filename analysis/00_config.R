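# Shared settings for the analysis scripts. Each numbered script reads the
# state written by its predecessor from scratch/analysis/ and writes its
# tables under results/. Run them in order:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_trim.R
#   ... up to analysis/07_enrichment.R

library(mateseq)

ANALYSIS_SEED <- 20260920L
N_LOCI <- 300L
STATE_DIR <- "scratch/analysis"
RESULTS_DIR <- "results"
dir.create(STATE_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

analysis_config <- function() sim_config(n_loci = N_LOCI, seed = ANALYSIS_SEED)

load_state <- function(stage, producer) {
  path <- file.path(STATE_DIR, paste0(stage, ".rds"))
  if (!file.exists(path))
    stop("missing upstream output '", stage, "': run ", producer, " first",
         call. = FALSE)
  readRDS(path)
}

save_state <- function(obj, stage) {
  saveRDS(obj, file.path(STATE_DIR, paste0(stage, ".rds")))
}

write_result <- function(x, name) {
  path <- file.path(RESULTS_DIR, name)
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
}
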