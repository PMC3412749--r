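# Newick trees, expression matrices, EST FASTA and qPCR CT tables.

#' Default EST tissue vocabulary
#'
#' Fifteen tissue codes for the EST libraries of a flax-style expression
#' panel: flower, embryo stages, seed coats, endosperm, seedling and
#' vegetative tissues.
#'
#' @return Named character vector mapping tissue code to description.
#' @export
default_tissues <- function() {
  c(FL = "flower",
    GE = "globular embryo",
    HE = "heart embryo",
    TE = "torpedo embryo",
    BE = "bent embryo",
    ME = "mature embryo",
    GC = "seed coat, globular stage",
    TC = "seed coat, torpedo stage",
    EN = "pooled endosperm",
    ES = "etiolated seedling",
    ST = "stem",
    LE = "leaf",
    PS = "peeled stem",
    BO = "bolls, 12 days after flowering",
    OS = "outer fibrous stem")
}

#' Read / write a Newick tree
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] so every
#' stage of the pipeline goes through one documented entry point.
#'
#' @param path File path.
#' @return `read_newick`: an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @return `write_newick`: invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Construct an expression table
#'
#' Gene x tissue matrix of either non-negative integer EST counts or real
#' log2 intensities.
#'
#' @param values Numeric matrix with row names (genes) and column names
#'   (tissues).
#' @param kind `"est_counts"` or `"log2_intensity"`.
#' @return An object of class `expression_table`.
#' @export
expression_table <- function(values, kind = c("est_counts", "log2_intensity")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  stopifnot(!is.null(rownames(values)), !is.null(colnames(values)))
  if (kind == "est_counts") {
    fail_if(any(values < 0) || any(values != round(values)),
            "est_counts values must be non-negative integers")
    storage.mode(values) <- "integer"
  }
  structure(list(genes = rownames(values), tissues = colnames(values),
                 values = values, kind = kind),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %d genes x %d tissues (%s)\n",
              length(x$genes), length(x$tissues), x$kind))
  invisible(x)
}

#' Read / write a tab-delimited expression matrix
#'
#' The TSV has a header row of tissue ids and one row per gene, first
#' column the gene id.
#'
#' @param path File path.
#' @param kind `"est_counts"` or `"log2_intensity"`.
#' @return `read_expression_tsv`: an [expression_table()].
#' @export
read_expression_tsv <- function(path, kind = c("est_counts", "log2_intensity")) {
  kind <- match.arg(kind)
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  expression_table(m, kind)
}

#' @rdname read_expression_tsv
#' @param tab An `expression_table`.
#' @return `write_expression_tsv`: invisibly, `path`.
#' @export
write_expression_tsv <- function(tab, path) {
  d <- data.frame(gene = tab$genes, tab$values, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an EST FASTA with library tags
#'
#' EST deflines carry a `lib=<library_id>` token; the library is resolved
#' to a tissue code through `library_map`.  Records whose library cannot be
#' resolved are skipped with a warning and counted in the `n_skipped`
#' attribute.
#'
#' @param path EST FASTA path.
#' @param library_map Data frame with columns `library_id` and `tissue`.
#' @return Data frame with columns `est_id`, `sequence`, `library_id`,
#'   `tissue`; attribute `n_skipped` counts unresolvable records.
#' @export
read_est_fasta <- function(path, library_map) {
  stopifnot(all(c("library_id", "tissue") %in% names(library_map)))
  x <- Biostrings::readDNAStringSet(path)
  defs <- names(x)
  est_id <- sub("\\s.*$", "", defs)
  lib <- ifelse(grepl("lib=", defs), sub(".*lib=([^ ]+).*", "\\1", defs),
                NA_character_)
  tissue <- library_map$tissue[match(lib, library_map$library_id)]
  bad <- is.na(tissue)
  if (any(bad))
    warning(sprintf("%d EST record(s) skipped: unresolvable library id", sum(bad)),
            call. = FALSE)
  out <- data.frame(est_id = est_id[!bad], sequence = as.character(x)[!bad],
                    library_id = lib[!bad], tissue = tissue[!bad],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Write EST records as FASTA
#'
#' @param ests Data frame as returned by [read_est_fasta()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_est_fasta <- function(ests, path) {
  x <- Biostrings::DNAStringSet(ests$sequence)
  names(x) <- paste0(ests$est_id, " lib=", ests$library_id)
  Biostrings::writeXStringSet(x, path, width = 80)
  invisible(path)
}

#' Read / write a qPCR CT table
#'
#' Tab-delimited with columns `gene`, `tissue`, `bio_rep`, `tech_rep`,
#' `ct` (threshold cycles, positive reals).
#'
#' @param path File path.
#' @return `read_ct_tsv`: the CT data frame.
#' @export
read_ct_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "tissue", "bio_rep", "tech_rep", "ct")
  fail_if(!all(need %in% names(d)), "CT table must have columns %s",
          paste(need, collapse = ", "))
  fail_if(any(d$ct <= 0), "CT values must be positive")
  d
}

#' @rdname read_ct_tsv
#' @param ct_table CT data frame.
#' @return `write_ct_tsv`: invisibly, `path`.
#' @export
write_ct_tsv <- function(ct_table, path) {
  utils::write.table(ct_table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
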