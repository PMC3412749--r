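# Correlation-based hierarchical clustering of an expression matrix, with
# a canonical (permutation-invariant) leaf order for heat-map rendering.

#' Cluster an expression matrix by correlation
#'
#' Distance is `1 - Pearson r` between gene rows; agglomeration is
#' average linkage by default.  EST-count tables are transformed with
#' `log2(x + 1)` first (flagged in the result).  Rows with zero variance
#' have undefined correlation; they are assigned the maximum distance (2)
#' to every other row and flagged.  The returned leaf order is
#' canonicalized so that at every merge the subtree containing the
#' lexicographically smallest gene id comes first, which makes the order
#' invariant to input row permutation up to that convention.
#'
#' @param tab An [expression_table()] (kind `log2_intensity`, or
#'   `est_counts` which is log-transformed with a flag).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param expressed_threshold Intensity cutoff defining the expressed
#'   set (default 6.96 on the log2 scale): genes whose maximum value
#'   reaches it are reported as expressed.
#' @return List with `order` (gene ids, canonical leaf order), `hclust`
#'   (the [stats::hclust] object), `distance` (the distance matrix),
#'   `expressed` (gene ids over the threshold), `flagged_constant`
#'   (zero-variance gene ids), `log_transformed`.
#' @export
cluster_expression <- function(tab, linkage = "average",
                               expressed_threshold = 6.96) {
  stopifnot(inherits(tab, "expression_table"))
  v <- tab$values
  log_transformed <- FALSE
  if (tab$kind == "est_counts") {
    v <- log2(v + 1)
    log_transformed <- TRUE
  }
  sds <- apply(v, 1, stats::sd)
  flat <- rownames(v)[sds == 0]
  cc <- suppressWarnings(stats::cor(t(v)))
  d <- 1 - cc
  d[is.na(d)] <- 2           # undefined correlation -> maximal distance
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  ord_idx <- canonical_order(hc)
  list(order = hc$labels[ord_idx],
       hclust = hc,
       distance = d,
       expressed = rownames(v)[apply(v, 1, max) >= expressed_threshold],
       flagged_constant = flat,
       log_transformed = log_transformed)
}

# Leaf order with, at every merge, the subtree holding the
# lexicographically smallest label first.
canonical_order <- function(hc) {
  n <- length(hc$labels)
  rec <- function(node) {
    if (node < 0) return(-node)
    a <- rec(hc$merge[node, 1])
    b <- rec(hc$merge[node, 2])
    if (min(hc$labels[a]) <= min(hc$labels[b])) c(a, b) else c(b, a)
  }
  rec(nrow(hc$merge))
}
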