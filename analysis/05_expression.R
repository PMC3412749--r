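#!/usr/bin/env Rscript
# Digital expression: map the simulated ESTs back onto the family CDS
# set, summarize counts per gene / group / tissue, and order the count
# matrix by correlation-based hierarchical clustering.

source("analysis/00_config.R")

sim <- study_family()
tr <- sim$truth
ests <- read_est_fasta(res_path("sim_inputs", "ests.fasta"),
                       utils::read.delim(res_path("sim_inputs",
                                                  "library_map.tsv")))

mp <- map_ests(ests, tr$cds, k = 11, min_identity = 0.95,
               min_match_len = 100,
               tissues = colnames(tr$expression_weights))
write_expression_tsv(mp$counts, res_path("est_counts.tsv"))

summ <- expression_summary(mp$counts, group_map = tr$groups)
write_tsv(summ$per_group, res_path("expression_per_group.tsv"))
write_tsv(summ$per_tissue, res_path("expression_per_tissue.tsv"))

heat <- cluster_expression(mp$counts)
write_tsv(data.frame(order = heat$order), res_path("heatmap_order.tsv"))

cat(sprintf("%d/%d ESTs mapped (%d unmapped, %d ties discarded).\n",
            sum(mp$counts$values), nrow(ests), mp$n_unmapped,
            mp$discarded_ties))
cat(sprintf("%d of %d genes expressed (%.2f%%), mean %.2f ESTs per expressed gene.\n",
            summ$n_expressed, summ$n_genes, summ$pct_expressed,
            summ$mean_per_expressed))
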