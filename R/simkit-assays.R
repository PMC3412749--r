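# Tissue-weighted EST sampling and qPCR CT simulation over a family_sim.

#' Simulate tissue-tagged ESTs from a simulated family
#'
#' Each EST is a uniformly placed substring of one gene's CDS; the gene is
#' drawn per tissue according to the truth's expression weights, and
#' per-base substitution errors are applied at `error_rate`.  Tissues are
#' drawn uniformly.
#'
#' @param truth The `truth` element of a [simulate_family()] result.
#' @param n_ests Number of ESTs to draw (> 0).
#' @param read_length_range Length-2 integer vector, inclusive range of
#'   EST lengths in nt (reads are capped at the CDS length).
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return Data frame with columns `est_id`, `sequence`, `library_id`,
#'   `tissue` plus attributes `sampled_counts` (gene x tissue matrix of
#'   planted draws) and `library_map`.
#' @export
simulate_ests <- function(truth, n_ests = 2000,
                          read_length_range = c(150, 500),
                          error_rate = 0.01, seed = 1) {
  fail_if(n_ests <= 0, "n_ests must be positive")
  fail_if(error_rate < 0 || error_rate >= 1, "error_rate must be in [0, 1)")
  set.seed(seed)
  w <- truth$expression_weights
  tissues <- colnames(w)
  genes <- rownames(w)
  cds <- truth$cds

  tissue_draw <- sample(tissues, n_ests, replace = TRUE)
  counts <- matrix(0L, length(genes), length(tissues),
                   dimnames = dimnames(w))
  seqs <- character(n_ests); gene_draw <- character(n_ests)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n_ests)) {
    tt <- tissue_draw[i]
    g <- sample(genes, 1, prob = w[, tt])
    gene_draw[i] <- g
    counts[g, tt] <- counts[g, tt] + 1L
    full <- cds[[g]]
    len <- min(sample(read_length_range[1]:read_length_range[2], 1),
               nchar(full))
    start <- sample.int(nchar(full) - len + 1L, 1)
    s <- strsplit(substr(full, start, start + len - 1L), "")[[1]]
    err <- which(stats::runif(len) < error_rate)
    for (j in err) s[j] <- sample(setdiff(bases, s[j]), 1)
    seqs[i] <- paste(s, collapse = "")
  }
  out <- data.frame(
    est_id = sprintf("est%06d", seq_len(n_ests)),
    sequence = seqs,
    library_id = paste0("LIB", tissue_draw),
    tissue = tissue_draw,
    stringsAsFactors = FALSE
  )
  attr(out, "sampled_counts") <- counts
  attr(out, "sampled_genes") <- gene_draw
  attr(out, "library_map") <- data.frame(
    library_id = paste0("LIB", tissues), tissue = tissues,
    stringsAsFactors = FALSE)
  out
}

#' Simulate a qPCR CT table with known relative abundances
#'
#' For each (gene, tissue) in the truth's qPCR table, reference-gene CTs
#' are drawn around `baseline` and target CTs around
#' `CT_ref - log2(relative abundance)`, each with Gaussian noise `sd_ct`
#' per technical replicate.
#'
#' @param truth The `truth` element of a [simulate_family()] result
#'   (uses `qpcr_truth`, a gene x tissue matrix of relative abundances).
#' @param reference_gene Id used for the reference rows (default
#'   `"ETIF5A"`, a translation initiation factor commonly used as a
#'   stable reference).
#' @param n_bio,n_tech Numbers of biological and technical replicates
#'   (defaults 3 and 2).
#' @param sd_ct Gaussian CT noise per technical replicate (cycles, >= 0).
#' @param baseline Reference-gene CT baseline (default 20 cycles).
#' @param seed Integer seed.
#' @return CT data frame with columns `gene`, `tissue`, `bio_rep`,
#'   `tech_rep`, `ct`, containing both target and reference rows.
#' @export
simulate_qpcr <- function(truth, reference_gene = "ETIF5A", n_bio = 3,
                          n_tech = 2, sd_ct = 0.1, baseline = 20, seed = 1) {
  fail_if(sd_ct < 0, "sd_ct must be non-negative")
  qt <- truth$qpcr_truth
  fail_if(any(qt <= 0), "relative abundances must be positive")
  set.seed(seed)
  rows <- list()
  for (tt in colnames(qt)) {
    for (b in seq_len(n_bio)) {
      for (k in seq_len(n_tech)) {
        rows[[length(rows) + 1]] <- data.frame(
          gene = reference_gene, tissue = tt, bio_rep = b, tech_rep = k,
          ct = baseline + stats::rnorm(1, 0, sd_ct))
      }
      for (g in rownames(qt)) {
        for (k in seq_len(n_tech)) {
          rows[[length(rows) + 1]] <- data.frame(
            gene = g, tissue = tt, bio_rep = b, tech_rep = k,
            ct = baseline - log2(qt[g, tt]) + stats::rnorm(1, 0, sd_ct))
        }
      }
    }
  }
  do.call(rbind, rows)
}
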