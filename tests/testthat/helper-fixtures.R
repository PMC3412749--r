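# Shared fixtures.  The reference simulation is built once per test run
# and reused by every recovery test (12 genes, fixed seed).

.fixture_cache <- new.env()

ref_sim <- function() {
  if (is.null(.fixture_cache$sim))
    .fixture_cache$sim <- simulate_family(n_leaves = 12, seed = 7,
                                          dir = file.path(tempdir(), "refsim"))
  .fixture_cache$sim
}

ref_models <- function() {
  if (is.null(.fixture_cache$models)) {
    sim <- ref_sim()
    .fixture_cache$models <- read_gene_models(sim$gff3, sim$genome_fasta)
  }
  .fixture_cache$models
}

ref_boot <- function() {
  if (is.null(.fixture_cache$boot)) {
    sim <- ref_sim()
    .fixture_cache$boot <- bootstrap_nj(sim$truth$true_alignment,
                                        n_reps = 200, seed = 11)
  }
  .fixture_cache$boot
}

# Write a one-contig genome + GFF3 for hand-specified gene structures.
# genes: list of list(id, strand, cds = data.frame(start, end))
tiny_genome <- function(contig_seq, genes, dir = tempfile("tiny")) {
  dir.create(dir, showWarnings = FALSE)
  fa <- file.path(dir, "genome.fasta")
  writeLines(c(">chr1", contig_seq), fa)
  gff <- file.path(dir, "genes.gff3")
  con <- file(gff, "w")
  writeLines("##gff-version 3", con)
  for (g in genes) {
    span <- range(c(g$cds$start, g$cds$end))
    writeLines(sprintf("chr1\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s.g",
                       span[1], span[2], g$strand, g$id), con)
    writeLines(sprintf("chr1\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s.g",
                       span[1], span[2], g$strand, g$id, g$id), con)
    for (i in seq_len(nrow(g$cds))) {
      writeLines(sprintf("chr1\ttest\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                         g$cds$start[i], g$cds$end[i], g$strand, g$id), con)
      writeLines(sprintf("chr1\ttest\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                         g$cds$start[i], g$cds$end[i], g$strand, g$id), con)
    }
  }
  close(con)
  list(fasta = fa, gff3 = gff)
}

random_aa_string <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"),
               n, replace = TRUE), collapse = "")
}
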