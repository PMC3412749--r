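# Gene models: exon/CDS structure plus the spliced, translated protein.
#
# Coordinates follow the GFF3 convention throughout: 1-based, inclusive,
# genomic.  Minus-strand models are normalized to transcription order at
# parse time, so downstream code never sees genomic orientation.

#' Construct a gene model
#'
#' A gene model couples one mRNA's exon and CDS intervals (1-based,
#' inclusive, in transcription order) with the protein translated from its
#' spliced CDS.  Models whose CDS length is not a multiple of three are
#' flagged incomplete and excluded from intron-phase analysis downstream.
#'
#' @param gene_id Gene/mRNA identifier.
#' @param seq_id Source contig or scaffold name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column data frame (`start`, `end`) of exon intervals in
#'   transcription order.
#' @param cds Two-column data frame (`start`, `end`) of CDS intervals in
#'   transcription order.
#' @param protein Amino-acid string (trailing stop removed).
#' @param complete `TRUE` when the CDS length is divisible by three.
#' @param had_stop `TRUE` when a trailing stop codon was present and removed.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, seq_id, strand, exons, cds, protein,
                       complete = TRUE, had_stop = TRUE) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.data.frame(exons)[, c("start", "end")]
  cds <- as.data.frame(cds)[, c("start", "end")]
  exons[] <- lapply(exons, as.integer)
  cds[] <- lapply(cds, as.integer)
  structure(list(
    gene_id = gene_id, seq_id = seq_id, strand = strand,
    exons = exons, cds = cds, protein = protein,
    cds_length = sum(cds$end - cds$start + 1L),
    complete = complete, had_stop = had_stop
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s on %s(%s): %d exon(s), %d CDS segment(s), %d nt CDS, %d aa%s\n",
              x$gene_id, x$seq_id, x$strand, nrow(x$exons), nrow(x$cds),
              x$cds_length, nchar(x$protein),
              if (x$complete) "" else " [incomplete]"))
  invisible(x)
}

#' Number of CDS-interrupting introns in a gene model
#'
#' @param model A `gene_model`.
#' @return Integer count of gaps between consecutive CDS intervals.
#' @export
n_introns <- function(model) {
  max(nrow(model$cds) - 1L, 0L)
}

# Splice genomic intervals (transcription order) out of a contig sequence
# and return the mRNA-sense nucleotide string.
splice_intervals <- function(contig_seq, intervals, strand) {
  if (nrow(intervals) == 0) return("")
  genomic <- intervals[order(intervals$start), , drop = FALSE]
  parts <- Biostrings::extractAt(
    contig_seq,
    IRanges::IRanges(start = genomic$start, end = genomic$end)
  )
  joined <- unlist(parts)
  if (strand == "-") joined <- Biostrings::reverseComplement(joined)
  as.character(joined)
}

translate_cds <- function(nt) {
  usable <- nchar(nt) - nchar(nt) %% 3
  if (usable == 0) return(list(protein = "", had_stop = FALSE))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1, usable)),
    if.fuzzy.codon = "solve", no.init.codon = TRUE
  ))
  had_stop <- grepl("\\*$", aa)
  if (had_stop) aa <- sub("\\*$", "", aa)
  list(protein = aa, had_stop = had_stop)
}

#' Read gene models from GFF3 and a genome FASTA
#'
#' Parses gene/mRNA/exon/CDS features (linked by `Parent`), splices each
#' mRNA's CDS out of the genome, reverse-complements minus-strand models,
#' and translates with the standard genetic code.  A trailing stop codon is
#' removed from the protein and recorded in the model's `had_stop` flag.
#'
#' @param gff3_path Path to a GFF3 file with gene/mRNA/exon/CDS features.
#' @param genome_fasta_path Path to the genome FASTA covering all `seqid`s.
#' @return Named list of [gene_model()] objects, one per mRNA.  Models with
#'   CDS length not divisible by 3 are flagged `complete = FALSE` (with a
#'   warning) but retained.
#' @export
read_gene_models <- function(gff3_path, genome_fasta_path) {
  gff <- ape::read.gff(gff3_path)
  gff$type <- as.character(gff$type)
  gff$strand <- as.character(gff$strand)
  gff$seqid <- as.character(gff$seqid)
  genome <- Biostrings::readDNAStringSet(genome_fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))

  attr_field <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
  }

  mrna <- gff[gff$type %in% c("mRNA", "transcript"), , drop = FALSE]
  mrna$id <- attr_field(mrna$attributes, "ID")
  kids <- gff[gff$type %in% c("exon", "CDS"), , drop = FALSE]
  kids$parent <- attr_field(kids$attributes, "Parent")

  models <- lapply(seq_len(nrow(mrna)), function(i) {
    m <- mrna[i, ]
    fail_if(!(m$seqid %in% names(genome)),
            "contig '%s' for mRNA '%s' missing from genome FASTA", m$seqid, m$id)
    sub <- kids[kids$parent == m$id, , drop = FALSE]
    to_tx_order <- function(d) {
      d <- d[order(d$start), c("start", "end"), drop = FALSE]
      if (m$strand == "-") d <- d[rev(seq_len(nrow(d))), , drop = FALSE]
      rownames(d) <- NULL
      d
    }
    exons <- to_tx_order(sub[sub$type == "exon", , drop = FALSE])
    cds <- to_tx_order(sub[sub$type == "CDS", , drop = FALSE])
    if (nrow(exons) == 0) exons <- cds
    nt <- splice_intervals(genome[[m$seqid]], cds, m$strand)
    complete <- nchar(nt) %% 3 == 0
    if (!complete)
      warning(sprintf("CDS of '%s' is not a multiple of 3; model flagged incomplete", m$id),
              call. = FALSE)
    tr <- translate_cds(nt)
    gene_model(m$id, m$seqid, m$strand, exons, cds, tr$protein,
               complete = complete, had_stop = tr$had_stop)
  })
  names(models) <- mrna$id
  models
}

#' Write gene models as GFF3
#'
#' Emits gene/mRNA/exon/CDS features with `ID`/`Parent` links, suitable for
#' re-reading with [read_gene_models()].
#'
#' @param models Named list of `gene_model` objects.
#' @param gff3_path Output path.
#' @return Invisibly, `gff3_path`.
#' @export
write_gene_models <- function(models, gff3_path) {
  con <- file(gff3_path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in models) {
    span <- range(c(m$exons$start, m$exons$end, m$cds$start, m$cds$end))
    gid <- paste0(m$gene_id, ".gene")
    line <- function(type, s, e, attrs, phase = ".") {
      sprintf("%s\tugtfam\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              m$seq_id, type, s, e, m$strand, phase, attrs)
    }
    writeLines(line("gene", span[1], span[2], paste0("ID=", gid)), con)
    writeLines(line("mRNA", span[1], span[2],
                    paste0("ID=", m$gene_id, ";Parent=", gid)), con)
    ex <- m$exons[order(m$exons$start), , drop = FALSE]
    for (j in seq_len(nrow(ex)))
      writeLines(line("exon", ex$start[j], ex$end[j],
                      paste0("Parent=", m$gene_id)), con)
    # GFF3 CDS phase: bases to remove from the segment start to reach a
    # codon boundary, accumulated in transcription order.
    cds_tx <- m$cds
    phases <- integer(nrow(cds_tx))
    off <- 0L
    for (j in seq_len(nrow(cds_tx))) {
      phases[j] <- (3L - off %% 3L) %% 3L
      off <- off + (cds_tx$end[j] - cds_tx$start[j] + 1L)
    }
    ord <- order(cds_tx$start)
    if (m$strand == "-") stopifnot(all(ord == rev(seq_len(nrow(cds_tx)))))
    for (j in ord)
      writeLines(line("CDS", cds_tx$start[j], cds_tx$end[j],
                      paste0("Parent=", m$gene_id), phase = phases[j]), con)
  }
  invisible(gff3_path)
}
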