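# Comparative CT (delta-CT) relative quantification.

#' Relative transcript abundance by the comparative CT method
#'
#' Technical replicates are averaged within each biological replicate;
#' per biological replicate, `dCT = mean CT(target) - mean CT(reference)`
#' in the same tissue, and the relative abundance is `2^(-dCT)`.  The
#' mean and standard error across biological replicates are reported.
#'
#' @param measurements CT data frame with columns `gene`, `tissue`,
#'   `bio_rep`, `tech_rep`, `ct` (see [read_ct_tsv()]).
#' @param reference_gene Id of the reference (housekeeping) gene; it must
#'   be measured in every (tissue, bio_rep) combination used by targets.
#'   Biological replicates without a reference measurement are dropped
#'   with a warning; a target with no usable replicate is an error.
#' @return Data frame with columns `gene`, `tissue`, `n_bio`,
#'   `abundance`, `se` (standard error across biological replicates;
#'   `0` for a single replicate).
#' @export
delta_ct <- function(measurements, reference_gene) {
  stopifnot(all(c("gene", "tissue", "bio_rep", "tech_rep", "ct") %in%
                  names(measurements)))
  fail_if(!reference_gene %in% measurements$gene,
          "reference gene '%s' absent from measurements", reference_gene)
  # average technical replicates
  agg <- stats::aggregate(ct ~ gene + tissue + bio_rep, measurements, mean)
  ref <- agg[agg$gene == reference_gene, ]
  targets <- agg[agg$gene != reference_gene, ]
  out <- list()
  for (g in unique(targets$gene)) {
    for (tt in unique(targets$tissue[targets$gene == g])) {
      tg <- targets[targets$gene == g & targets$tissue == tt, ]
      rf <- ref[ref$tissue == tt, c("bio_rep", "ct")]
      merged <- merge(tg, rf, by = "bio_rep", suffixes = c("", "_ref"))
      dropped <- nrow(tg) - nrow(merged)
      if (dropped > 0)
        warning(sprintf(
          "%d biological replicate(s) of %s/%s dropped: no reference CT",
          dropped, g, tt), call. = FALSE)
      fail_if(nrow(merged) == 0,
              "no usable biological replicate for %s in %s", g, tt)
      ra <- 2^(-(merged$ct - merged$ct_ref))
      se <- if (length(ra) > 1) stats::sd(ra) / sqrt(length(ra)) else 0
      out[[length(out) + 1]] <- data.frame(
        gene = g, tissue = tt, n_bio = nrow(merged),
        abundance = mean(ra), se = se, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
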