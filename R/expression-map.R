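# Digital expression: map ESTs onto CDS sequences by exact k-mer seeding
# with ungapped extension, and count per (gene, tissue).

#' Map ESTs to gene coding sequences
#'
#' Exact k-mers of each EST are looked up in an index of the CDS
#' sequences; seeded diagonals are extended without gaps over the full
#' EST/CDS overlap, and the EST is assigned to the single gene with the
#' highest identity x matched-length score meeting the thresholds.
#' Equal-best ties across different genes are discarded and counted.
#'
#' @param ests EST data frame (`est_id`, `sequence`, `tissue`), e.g. from
#'   [read_est_fasta()] or [simulate_ests()].
#' @param cds Named character vector of CDS (mRNA-sense) sequences.
#' @param k Seed length (>= 8; default 11).
#' @param min_identity Minimum ungapped identity over the matched region
#'   (default 0.95).
#' @param min_match_len Minimum matched length in nt (default 100), or
#'   the full EST length for shorter ESTs.
#' @param tissues Tissue levels for the count matrix (default: those seen
#'   in `ests`).
#' @return List with `assignments` (data frame `est_id`, `gene_id` (NA =
#'   unmapped), `identity`, `matched_length`), `counts` (an
#'   [expression_table()] of kind `est_counts`), `n_unmapped`,
#'   `discarded_ties`.
#' @export
map_ests <- function(ests, cds, k = 11, min_identity = 0.95,
                     min_match_len = 100,
                     tissues = sort(unique(ests$tissue))) {
  fail_if(k < 8, "seed length k must be >= 8 (got %d)", k)
  fail_if(length(cds) == 0, "empty gene set")
  genes <- names(cds)

  idx <- data.table::rbindlist(lapply(genes, function(g) {
    s <- cds[[g]]
    n <- nchar(s) - k + 1L
    if (n < 1) return(NULL)
    data.table::data.table(kmer = substring(s, 1:n, k:(n + k - 1L)),
                           gene = g, pos = 1:n)
  }))
  data.table::setkey(idx, kmer)
  cds_len <- nchar(cds)

  n_est <- nrow(ests)
  gene_hit <- rep(NA_character_, n_est)
  ident <- rep(NA_real_, n_est)
  mlen <- rep(NA_integer_, n_est)
  ties <- 0L

  cds_chars <- lapply(cds, function(s) strsplit(s, "")[[1]])

  for (i in seq_len(n_est)) {
    es <- ests$sequence[i]
    le <- nchar(es)
    if (le < k) next
    nq <- le - k + 1L
    q <- data.table::data.table(kmer = substring(es, 1:nq, k:(nq + k - 1L)),
                                qpos = 1:nq)
    hits <- idx[q, on = "kmer", nomatch = NULL]
    if (!nrow(hits)) next
    hits[, diag := pos - qpos]
    cand <- unique(hits[, .(gene, diag)])
    ech <- strsplit(es, "")[[1]]
    best <- NULL
    for (r in seq_len(nrow(cand))) {
      g <- cand$gene[r]; d <- cand$diag[r]
      lo <- max(1L, 1L - d)
      hi <- min(le, cds_len[[g]] - d)
      ov <- hi - lo + 1L
      if (ov < min(min_match_len, le)) next
      idn <- mean(ech[lo:hi] == cds_chars[[g]][(lo + d):(hi + d)])
      if (idn < min_identity) next
      sc <- idn * ov
      rec <- list(gene = g, identity = idn, mlen = ov, score = sc)
      if (is.null(best) || sc > best$score) best <- c(rec, tie = FALSE)
      else if (sc == best$score && g != best$gene) best$tie <- TRUE
    }
    if (is.null(best)) next
    if (isTRUE(best$tie)) { ties <- ties + 1L; next }
    gene_hit[i] <- best$gene
    ident[i] <- best$identity
    mlen[i] <- best$mlen
  }

  counts <- matrix(0L, length(genes), length(tissues),
                   dimnames = list(genes, tissues))
  mapped <- !is.na(gene_hit)
  if (any(mapped)) {
    tab <- table(factor(gene_hit[mapped], levels = genes),
                 factor(ests$tissue[mapped], levels = tissues))
    counts <- counts + as.integer(tab)
    dim(counts) <- c(length(genes), length(tissues))
    dimnames(counts) <- list(genes, tissues)
  }
  list(assignments = data.frame(est_id = ests$est_id, gene_id = gene_hit,
                                identity = ident, matched_length = mlen,
                                stringsAsFactors = FALSE),
       counts = expression_table(counts, "est_counts"),
       n_unmapped = sum(!mapped) - ties,
       discarded_ties = ties)
}
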