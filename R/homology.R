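# Pairwise homology: global alignment, duplicate pairs, best-hit
# orthologs and lineage-diverged genes.

#' Globally align two proteins and summarize the homology
#'
#' Optimal global (Needleman-Wunsch) alignment with affine gaps, scored
#' with a substitution matrix.  Identity is the fraction of matching
#' columns among columns where both sequences have a residue (gapped
#' columns excluded).  The E-value uses the ungapped Karlin-Altschul form
#' `E = K * m * n * exp(-lambda * S)` with configurable constants and
#' search space; it reproduces BLAST-like orderings at desk scale without
#' BLAST's heuristics.
#'
#' @param a_protein,b_protein Non-empty amino-acid strings.
#' @param gap_open,gap_extend Affine gap penalties (positive costs;
#'   defaults 10 and 0.5).
#' @param matrix Substitution matrix (default BLOSUM62, half-bit units).
#' @param ka_lambda,ka_k Karlin-Altschul constants (defaults 0.318 and
#'   0.13, the ungapped BLOSUM62 half-bit values).
#' @param search_space Effective search-space size `m * n`; defaults to
#'   `nchar(a) * nchar(b)`.
#' @return List with `query_len`, `subject_len`, `score`, `identity`,
#'   `n_matches`, `aligned_cols`, `e_value`.
#' @export
align_pair <- function(a_protein, b_protein, gap_open = 10, gap_extend = 0.5,
                       matrix = substitution_matrix("BLOSUM62"),
                       ka_lambda = 0.318, ka_k = 0.13,
                       search_space = NULL) {
  fail_if(nchar(a_protein) == 0 || nchar(b_protein) == 0,
          "cannot align an empty sequence")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a_protein), Biostrings::AAString(b_protein),
    type = "global", substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  both <- pa != "-" & sa != "-"
  n_match <- sum(pa[both] == sa[both])
  identity <- if (any(both)) n_match / sum(both) else 0
  if (is.null(search_space))
    search_space <- as.numeric(nchar(a_protein)) * nchar(b_protein)
  e_value <- ka_k * search_space * exp(-ka_lambda * Biostrings::score(al))
  list(query_len = nchar(a_protein), subject_len = nchar(b_protein),
       score = Biostrings::score(al), identity = identity,
       n_matches = n_match, aligned_cols = sum(both), e_value = e_value)
}

#' Detect duplicated gene pairs by global identity
#'
#' All unordered pairs of proteins whose global-alignment identity reaches
#' `min_identity`; each pair is reported once.
#'
#' @param proteins Named character vector of accepted family proteins.
#' @param min_identity Identity threshold in `[0, 1]`, default 0.90.
#' @param ... Passed to [align_pair()].
#' @return Data frame with columns `gene_a`, `gene_b`, `identity`
#'   (gene_a < gene_b lexicographically).
#' @export
detect_duplicates <- function(proteins, min_identity = 0.90, ...) {
  ids <- sort(names(proteins))
  rows <- list()
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in (i + 1):length(ids)) {
        h <- align_pair(proteins[[ids[i]]], proteins[[ids[j]]], ...)
        if (h$identity >= min_identity)
          rows[[length(rows) + 1]] <- data.frame(
            gene_a = ids[i], gene_b = ids[j], identity = h$identity,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      identity = numeric(0)))
  do.call(rbind, rows)
}

#' Best-hit orthologs across comparator proteomes and diverged genes
#'
#' For every query and every comparator proteome, the best-scoring global
#' alignment with `e_value < e_max` is reported; queries with no
#' qualifying hit in any comparator form the diverged set.
#'
#' @param queries Named character vector of query proteins.
#' @param comparator_proteomes Named list of named character vectors.
#' @param e_max E-value cutoff, default `1e-100`.
#' @param ... Passed to [align_pair()].
#' @return List with `hits` (data frame `query`, `comparator`, `subject`,
#'   `score`, `identity`, `e_value`, qualifying best hits only) and
#'   `diverged` (character vector of query ids).
#' @export
detect_orthologs <- function(queries, comparator_proteomes, e_max = 1e-100,
                             ...) {
  rows <- list()
  has_hit <- stats::setNames(rep(FALSE, length(queries)), names(queries))
  for (cmp in names(comparator_proteomes)) {
    prot <- comparator_proteomes[[cmp]]
    if (!length(prot)) {
      warning(sprintf("comparator '%s' is empty; skipped", cmp), call. = FALSE)
      next
    }
    subj <- Biostrings::AAStringSet(prot)
    for (q in names(queries)) {
      al <- Biostrings::pairwiseAlignment(
        subj, Biostrings::AAString(queries[[q]]), type = "global",
        substitutionMatrix = substitution_matrix("BLOSUM62"),
        gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE)
      best <- which.max(al)
      h <- align_pair(queries[[q]], prot[[best]], ...)
      if (h$e_value < e_max) {
        has_hit[q] <- TRUE
        rows[[length(rows) + 1]] <- data.frame(
          query = q, comparator = cmp, subject = names(prot)[best],
          score = h$score, identity = h$identity, e_value = h$e_value,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(0), comparator = character(0),
               subject = character(0), score = numeric(0),
               identity = numeric(0), e_value = numeric(0))
  list(hits = hits, diverged = names(queries)[!has_hit])
}
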