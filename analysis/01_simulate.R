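#!/usr/bin/env Rscript
# Build the study system: a 20-gene UGT-like family evolved along a known
# tree, with planted motif, intron history, decoys, tissue-weighted ESTs
# and qPCR truth.  Writes the raw inputs consumed by the later scripts.

source("analysis/00_config.R")

sim <- study_family()
tr <- sim$truth

ests <- simulate_ests(tr, n_ests = 2000, error_rate = 0.01,
                      seed = ANALYSIS_SEED + 1)
write_est_fasta(ests, res_path("sim_inputs", "ests.fasta"))
write_tsv(attr(ests, "library_map"), res_path("sim_inputs", "library_map.tsv"))

ct <- simulate_qpcr(tr, n_bio = 3, n_tech = 2, sd_ct = 0.1,
                    seed = ANALYSIS_SEED + 2)
write_ct_tsv(ct, res_path("sim_inputs", "ct.tsv"))

write_newick(tr$tree, res_path("sim_inputs", "true_tree.nwk"))
write_alignment(tr$true_alignment, res_path("sim_inputs", "true_alignment.fasta"))
write_tsv(tr$intron_positions, res_path("sim_inputs", "true_introns.tsv"))
write_tsv(tr$decoys, res_path("sim_inputs", "true_decoys.tsv"))

cat(sprintf("Simulated %d family genes + %d decoys on %d contigs.\n",
            length(tr$family_genes), nrow(tr$decoys),
            length(tr$family_genes) + nrow(tr$decoys)))
cat(sprintf("Planted %d intron classes (%d ancestral), %d ESTs, %d qPCR genes.\n",
            nrow(tr$intron_history),
            sum(tr$intron_history$gain_node ==
                  length(tr$family_genes) + 1L),
            nrow(ests), nrow(tr$qpcr_truth)))
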