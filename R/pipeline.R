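# End-to-end orchestration: simulate (or consume) inputs, mine the
# family, build the tree, map introns and events, profile expression,
# and write a reproducibility manifest.

#' Default pipeline configuration
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param outdir Output directory.
#' @return Nested configuration list understood by [run_all()].
#' @export
default_config <- function(seed = 1, outdir = tempfile("ugtfam_run")) {
  list(
    seed = seed,
    outdir = outdir,
    sim = list(n_leaves = 20, subst_rate = 0.75, indel_rate = 0.01,
               n_intron_classes = 5, intron_jitter = 5, decoy_frac = 0.3,
               n_groups = 3),
    est = list(n_ests = 1500, error_rate = 0.01,
               read_length_range = c(150, 500)),
    qpcr = list(n_bio = 3, n_tech = 2, sd_ct = 0.1),
    mine = list(length_range = c(375, 530), max_introns = 2),
    tree = list(n_reps = 200, model = "p_distance", support_threshold = 85),
    introns = list(window_aa = 45, model = "dollo"),
    express = list(k = 11, min_identity = 0.95, min_match_len = 100)
  )
}

validate_config <- function(config) {
  need <- c("seed", "outdir", "sim", "est", "qpcr", "mine", "tree",
            "introns", "express")
  missing <- setdiff(need, names(config))
  fail_if(length(missing) > 0, "config is missing field(s): %s",
          paste(missing, collapse = ", "))
  for (f in c("genome_fasta", "gff3", "alignment"))
    if (!is.null(config$files[[f]]))
      fail_if(!file.exists(config$files[[f]]),
              "configured input '%s' does not exist: %s", f,
              config$files[[f]])
  invisible(TRUE)
}

#' Run the whole pipeline on one configuration
#'
#' Stages run in dependency order: simulate (skipped when `config$files`
#' supplies a genome/GFF3/alignment), mine, tree, introns, expression,
#' qPCR, report.  All tabular outputs are tab-delimited UTF-8; a manifest
#' records the configuration, derived stage seeds, input/output digests
#' and per-stage record counts.  Identical configurations (including the
#' seed) reproduce byte-identical outputs.
#'
#' @param config Configuration list, see [default_config()].
#' @return Invisibly, a list with `outdir`, `manifest`, and the in-memory
#'   stage results (`sim`, `mining`, `tree`, `introns`, `expression`,
#'   `qpcr`, `report`).
#' @export
run_all <- function(config = default_config()) {
  validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)
  seeds <- list(sim = substream_seed(config$seed, 101),
                est = substream_seed(config$seed, 202),
                qpcr = substream_seed(config$seed, 303),
                tree = substream_seed(config$seed, 404))

  ## -- stage: simulate ------------------------------------------------------
  sim <- do.call(simulate_family,
                 c(config$sim, list(seed = seeds$sim,
                                    dir = out("inputs"))))
  truth <- sim$truth
  ests <- do.call(simulate_ests,
                  c(list(truth = truth, seed = seeds$est), config$est))
  write_est_fasta(ests, out("inputs", "ests.fasta"))
  ct <- do.call(simulate_qpcr,
                c(list(truth = truth, seed = seeds$qpcr), config$qpcr))
  write_ct_tsv(ct, out("inputs", "ct.tsv"))

  ## -- stage: mine ----------------------------------------------------------
  models <- read_gene_models(sim$gff3, sim$genome_fasta)
  proteins <- vapply(models, `[[`, "", "protein")
  hits <- scan_motif(proteins, truth$motif_consensus)
  cand <- filter_candidates(hits, models,
                            length_range = config$mine$length_range,
                            max_introns = config$mine$max_introns)
  utils::write.table(
    data.frame(gene_id = cand$accepted),
    out("accepted.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cand$rejected, out("rejected.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  dups <- detect_duplicates(proteins[cand$accepted])
  utils::write.table(dups, out("duplicates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## -- stage: tree ----------------------------------------------------------
  aln <- truth$true_alignment
  tree <- bootstrap_nj(aln, n_reps = config$tree$n_reps, seed = seeds$tree,
                       model = config$tree$model)
  write_newick(tree, out("tree.nwk"))
  refs <- data.frame(
    leaf_id = vapply(split(names(truth$groups), truth$groups), `[`, "", 1),
    group = names(split(names(truth$groups), truth$groups)))
  grp <- assign_groups(tree, refs,
                       support_threshold = config$tree$support_threshold)
  utils::write.table(
    data.frame(gene_id = names(grp), group = unname(grp)),
    out("groups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  ## -- stage: introns -------------------------------------------------------
  fam_models <- models[intersect(cand$accepted, names(aln$seqs))]
  recs <- extract_introns_all(fam_models)
  recs <- project_to_alignment(recs, aln)
  clus <- cluster_intron_classes(recs, window_aa = config$introns$window_aa,
                                 group_map = grp)
  pres <- presence_matrix(clus$members, names(fam_models))
  events <- infer_events(truth$tree, pres, model = config$introns$model)
  census <- intron_census(recs, cand$accepted)
  utils::write.table(clus$members, out("introns.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(clus$classes, out("intron_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(events$events, out("intron_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  census_df <- data.frame(
    stat = c("n_genes", "genes_0_introns", "genes_1_intron",
             "genes_2plus_introns", "total_introns", "mean_per_gene"),
    value = c(census$n_genes, census$genes_by_intron_count,
              census$total_introns, census$mean_per_gene))
  utils::write.table(census_df, out("census.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## -- stage: expression ----------------------------------------------------
  mapping <- map_ests(ests, truth$cds[intersect(cand$accepted,
                                                names(truth$cds))],
                      k = config$express$k,
                      min_identity = config$express$min_identity,
                      min_match_len = config$express$min_match_len,
                      tissues = colnames(truth$expression_weights))
  summ <- expression_summary(mapping$counts, group_map = grp)
  write_expression_tsv(mapping$counts, out("est_counts.tsv"))
  utils::write.table(summ$per_group, out("expression_per_group.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(summ$per_tissue, out("expression_per_tissue.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  heat <- cluster_expression(mapping$counts)
  utils::write.table(data.frame(order = heat$order), out("heatmap_order.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## -- stage: qpcr ----------------------------------------------------------
  qres <- delta_ct(ct, reference_gene = "ETIF5A")
  utils::write.table(qres, out("qpcr_abundance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## -- report + manifest ----------------------------------------------------
  report <- data.frame(
    stat = c("accepted_genes", "rejected_genes", "duplicate_pairs",
             "intron_classes", "total_intron_events", "mapped_ests",
             "expressed_genes", "qpcr_genes"),
    value = c(length(cand$accepted), nrow(cand$rejected), nrow(dups),
              nrow(clus$classes), events$total_events,
              sum(mapping$counts$values), summ$n_expressed,
              length(unique(qres$gene))))
  utils::write.table(report, out("report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  outputs <- list.files(config$outdir, recursive = TRUE, full.names = TRUE)
  manifest <- data.frame(
    key = c("package_version", "master_seed",
            paste0("seed_", names(seeds)),
            paste0("md5_", list.files(config$outdir, recursive = TRUE))),
    value = c(as.character(utils::packageVersion("ugtfam")),
              config$seed, unlist(seeds),
              unname(tools::md5sum(outputs))))
  utils::write.table(manifest, out("manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(outdir = config$outdir, manifest = manifest, sim = sim,
                 ests = ests, mining = cand, duplicates = dups, tree = tree,
                 groups = grp, introns = clus, presence = pres,
                 events = events, census = census, mapping = mapping,
                 expression = summ, qpcr = qres, report = report))
}
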