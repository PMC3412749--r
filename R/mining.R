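# Family mining: ungapped 44-residue motif scan plus candidate filters.

#' Substitution matrix by name
#'
#' @param name `"BLOSUM62"` or `"PAM250"` (the matrices shipped with
#'   Biostrings, in half-bit units).
#' @return Numeric substitution matrix.
#' @export
substitution_matrix <- function(name = c("BLOSUM62", "PAM250")) {
  name <- match.arg(name)
  get_submat(name)
}

#' Self-score of a motif under a substitution matrix
#'
#' The score of the motif aligned to itself; used to express scan
#' thresholds as a fraction of the attainable maximum.
#'
#' @param motif Amino-acid string.
#' @param matrix Substitution matrix (default BLOSUM62).
#' @return Numeric score.
#' @export
motif_self_score <- function(motif, matrix = substitution_matrix("BLOSUM62")) {
  ch <- strsplit(motif, "")[[1]]
  sum(matrix[cbind(ch, ch)])
}

#' Scan proteins for the best-scoring ungapped motif window
#'
#' Slides the 44-residue consensus over every protein and reports, per
#' protein, the maximal-scoring ungapped window (sum of per-column
#' substitution scores), provided it reaches `min_score`.  Ties are broken
#' by the smallest offset.  Proteins shorter than the motif yield no hit.
#'
#' @param proteins Named character vector of protein sequences.
#' @param motif 44-residue consensus string.
#' @param matrix Substitution matrix (default BLOSUM62).
#' @param min_score Minimum reported score; default 50% of the consensus
#'   self-score.
#' @return Data frame with columns `gene_id`, `offset` (1-based window
#'   start), `score`, `window`.
#' @export
scan_motif <- function(proteins, motif = pspg_consensus(),
                       matrix = substitution_matrix("BLOSUM62"),
                       min_score = 0.5 * motif_self_score(motif, matrix)) {
  fail_if(nchar(motif) != 44, "motif must be exactly 44 residues (got %d)",
          nchar(motif))
  fail_if(!isTRUE(all.equal(matrix, t(matrix))),
          "substitution matrix must be symmetric")
  mch <- strsplit(motif, "")[[1]]
  L <- length(mch)
  hits <- lapply(names(proteins), function(g) {
    p <- proteins[[g]]
    n <- nchar(p)
    if (n < L) return(NULL)
    ch <- strsplit(p, "")[[1]]
    ch[!ch %in% rownames(matrix)] <- "X"
    # column scores for every protein position against every motif column,
    # then window sums via a running difference
    persite <- matrix[cbind(rep(mch, each = n - L + 1),
                            ch[outer(seq_len(n - L + 1), seq_len(L) - 1L, "+")])]
    scores <- rowSums(matrix(persite, nrow = n - L + 1))
    best <- which.max(scores)   # first maximum = smallest offset
    if (scores[best] < min_score) return(NULL)
    data.frame(gene_id = g, offset = as.integer(best),
               score = scores[best],
               window = substr(p, best, best + L - 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(gene_id = character(0), offset = integer(0),
                      score = numeric(0), window = character(0))
  out
}

#' Apply the candidate filters to motif hits
#'
#' A gene is accepted when it has a motif hit, its protein length falls in
#' `length_range` (inclusive) and it has at most `max_introns`
#' CDS-interrupting introns.  Rejected genes carry the first failing check
#' in the order `no_motif`, `length`, `intron_count`.
#'
#' @param hits Motif hits from [scan_motif()].
#' @param gene_models Named list of [gene_model()]s covering every scanned
#'   gene.
#' @param length_range Inclusive protein-length bounds, default
#'   `c(375, 530)` residues.
#' @param max_introns Maximum intron count, default 2.
#' @return List with `accepted` (character vector of gene ids, in input
#'   order) and `rejected` (data frame `gene_id`, `reason`).
#' @export
filter_candidates <- function(hits, gene_models,
                              length_range = c(375, 530), max_introns = 2) {
  missing <- setdiff(hits$gene_id, names(gene_models))
  fail_if(length(missing) > 0, "no gene model for: %s",
          paste(missing, collapse = ", "))
  ids <- names(gene_models)
  accepted <- character(0)
  rej_id <- character(0); rej_why <- character(0)
  for (g in ids) {
    len <- nchar(gene_models[[g]]$protein)
    ni <- n_introns(gene_models[[g]])
    why <- if (!(g %in% hits$gene_id)) "no_motif"
      else if (len < length_range[1] || len > length_range[2]) "length"
      else if (ni > max_introns) "intron_count"
      else NA_character_
    if (is.na(why)) accepted <- c(accepted, g)
    else { rej_id <- c(rej_id, g); rej_why <- c(rej_why, why) }
  }
  list(accepted = accepted,
       rejected = data.frame(gene_id = rej_id, reason = rej_why,
                             stringsAsFactors = FALSE))
}
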