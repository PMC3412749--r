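# Shared settings for the analysis scripts.  Every script is a thin
# driver over the ugtfam package; re-running any of them with this seed
# reproduces its outputs byte for byte.

library(ugtfam)

ANALYSIS_SEED <- 20L
RESULTS <- "results"
dir.create(RESULTS, showWarnings = FALSE)

res_path <- function(...) file.path(RESULTS, ...)

# the simulation is fully determined by the seed, so downstream scripts
# can rebuild the ground truth instead of serializing it
study_family <- function() {
  simulate_family(n_leaves = 20, seed = ANALYSIS_SEED,
                  dir = res_path("sim_inputs"))
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
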