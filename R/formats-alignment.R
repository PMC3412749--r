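# Protein multiple alignments with residue <-> column maps.

#' Construct a protein alignment
#'
#' @param seqs Named character vector of aligned rows (gap `-`), all the
#'   same length.
#' @return An object of class `protein_alignment`.
#' @export
protein_alignment <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    bad <- names(seqs)[lens != lens[1]]
    stop("alignment rows differ in length: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(seqs = seqs, ncol = lens[1]), class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("<protein_alignment> %d sequences x %d columns\n",
              length(x$seqs), x$ncol))
  invisible(x)
}

#' Read an aligned protein FASTA
#'
#' @param fasta_path Path to an aligned FASTA (all rows equal length,
#'   gap character `-`).
#' @return A [protein_alignment()].
#' @export
read_alignment <- function(fasta_path) {
  aa <- Biostrings::readAAStringSet(fasta_path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))
  protein_alignment(seqs)
}

#' Write an alignment as FASTA
#'
#' @param aln A `protein_alignment`.
#' @param fasta_path Output path.
#' @return Invisibly, `fasta_path`.
#' @export
write_alignment <- function(aln, fasta_path) {
  x <- Biostrings::AAStringSet(aln$seqs)
  Biostrings::writeXStringSet(x, fasta_path, width = 80)
  invisible(fasta_path)
}

#' Ungapped sequences of an alignment
#'
#' @param aln A `protein_alignment`.
#' @return Named character vector with gaps removed.
#' @export
aln_ungapped <- function(aln) {
  gsub("-", "", aln$seqs, fixed = TRUE)
}

aln_row_chars <- function(aln, id) {
  fail_if(!(id %in% names(aln$seqs)), "sequence '%s' absent from alignment", id)
  strsplit(aln$seqs[[id]], "", fixed = TRUE)[[1]]
}

#' Map an ungapped residue index to its alignment column
#'
#' @param aln A `protein_alignment`.
#' @param id Row identifier.
#' @param pos 1-based residue index in the ungapped sequence (vectorized).
#' @return Integer alignment column(s).
#' @export
aln_pos_to_col <- function(aln, id, pos) {
  ch <- aln_row_chars(aln, id)
  resno <- cumsum(ch != "-")
  cols <- match(seq_len(max(resno, 0L)), resno)
  fail_if(any(pos < 1 | pos > max(resno, 0L)),
          "residue index out of range for '%s'", id)
  cols[pos]
}

#' Map an alignment column to the ungapped residue index
#'
#' @param aln A `protein_alignment`.
#' @param id Row identifier.
#' @param col 1-based alignment column (vectorized).
#' @return Integer residue index, or `NA` where the row has a gap.
#' @export
aln_col_to_pos <- function(aln, id, col) {
  ch <- aln_row_chars(aln, id)
  fail_if(any(col < 1 | col > length(ch)), "column out of range for '%s'", id)
  resno <- cumsum(ch != "-")
  out <- resno[col]
  out[ch[col] == "-"] <- NA_integer_
  out
}

#' Alignment as a character matrix
#'
#' @param x A `protein_alignment`.
#' @param ... Unused.
#' @return Character matrix, rows = sequences, columns = alignment columns.
#' @method as.matrix protein_alignment
#' @export
as.matrix.protein_alignment <- function(x, ...) {
  do.call(rbind, lapply(x$seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]]))
}
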