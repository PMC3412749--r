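# Summaries of digital expression counts, per gene, group and tissue.

#' Summarize EST counts per gene, group and tissue
#'
#' @param counts An [expression_table()] of kind `est_counts`.
#' @param group_map Optional named vector gene -> group; genes without a
#'   group are summarized under `"(ungrouped)"`.
#' @param digits Decimal places for printed means/percentages (default 2).
#' @param mode `"round"` (half-up, default) or `"truncate"`, matching the
#'   two conventions found in published tables.
#' @return List with `n_genes`, `total_ests`, `n_expressed`,
#'   `pct_expressed`, `mean_per_expressed`, `per_gene`, `per_group`,
#'   `per_tissue` data frames, and `mode`.  Per-tissue percentages are
#'   reported under both denominators (share of all ESTs, and share of
#'   the family expressed in that tissue).
#' @export
expression_summary <- function(counts, group_map = NULL, digits = 2,
                               mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(counts, "expression_table"), counts$kind == "est_counts")
  v <- counts$values
  gene_tot <- rowSums(v)
  n_genes <- length(counts$genes)
  total <- sum(v)
  expressed <- gene_tot > 0
  n_expr <- sum(expressed)
  pct_expr <- if (n_genes) round_mode(100 * n_expr / n_genes, digits, mode) else 0
  mean_expr <- if (n_expr) round_mode(total / n_expr, digits, mode) else 0

  per_gene <- data.frame(gene_id = counts$genes, total = as.integer(gene_tot),
                         expressed = expressed, row.names = NULL)

  if (is.null(group_map)) group_map <- character(0)
  grp <- ifelse(counts$genes %in% names(group_map),
                group_map[counts$genes], "(ungrouped)")
  per_group <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    sel <- grp == g
    ge <- sum(v[sel, , drop = FALSE])
    ne <- sum(expressed[sel])
    data.frame(group = g,
               n_members = sum(sel),
               total_ests = as.integer(ge),
               n_expressed = ne,
               pct_members_expressed =
                 round_mode(100 * ne / sum(sel), digits, mode),
               mean_per_expressed =
                 if (ne) round_mode(ge / ne, digits, mode) else 0,
               row.names = NULL)
  }))

  tis_tot <- colSums(v)
  tis_genes <- colSums(v > 0)
  per_tissue <- data.frame(
    tissue = counts$tissues,
    total_ests = as.integer(tis_tot),
    pct_of_ests = if (total) round_mode(100 * tis_tot / total, digits, mode)
                  else 0,
    n_genes_expressed = as.integer(tis_genes),
    pct_of_family = if (n_genes)
      round_mode(100 * tis_genes / n_genes, digits, mode) else 0,
    row.names = NULL)

  list(n_genes = n_genes, total_ests = as.integer(total),
       n_expressed = n_expr, pct_expressed = pct_expr,
       mean_per_expressed = mean_expr,
       per_gene = per_gene, per_group = per_group, per_tissue = per_tissue,
       mode = mode)
}

#' Expression-evidence percentage from explicit counts
#'
#' Convenience for recomputing headline ratios (e.g. expressed genes over
#' family size) under a stated rounding convention.
#'
#' @param numerator,denominator Counts.
#' @param digits Decimal places (default 2).
#' @param mode `"round"` or `"truncate"`.
#' @param percent Multiply by 100 first (default TRUE).
#' @return The formatted ratio.
#' @export
ratio_stat <- function(numerator, denominator, digits = 2,
                       mode = c("round", "truncate"), percent = TRUE) {
  mode <- match.arg(mode)
  x <- numerator / denominator
  if (percent) x <- 100 * x
  round_mode(x, digits, mode)
}
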