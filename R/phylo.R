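# Family phylogeny: distances, neighbour-joining, bootstrap supports,
# Fitch parsimony scoring and reference-anchored group assignment.

#' Pairwise distances from a protein alignment
#'
#' Sites where either sequence has a gap are excluded pairwise.  The
#' p-distance is mismatches over compared sites; the Dayhoff-corrected
#' distance applies `-ln(1 - p - 0.2 p^2)`, falling back to `p` (flagged)
#' where the argument is non-positive.
#'
#' @param aln A [protein_alignment()] with at least 3 sequences.
#' @param model `"p_distance"` or `"dayhoff_corrected"`.
#' @param on_empty What to do for a pair with zero comparable sites:
#'   `"error"` (default) or `"max"` (assign the maximum p of 0.75 before
#'   correction; used by the bootstrap resampler).
#' @return Symmetric numeric matrix with zero diagonal; attribute
#'   `flagged` lists pairs where the Dayhoff correction saturated.
#' @export
pairwise_distances <- function(aln, model = c("p_distance", "dayhoff_corrected"),
                               on_empty = c("error", "max")) {
  model <- match.arg(model)
  on_empty <- match.arg(on_empty)
  fail_if(length(aln$seqs) < 3, "need at least 3 sequences (got %d)",
          length(aln$seqs))
  m <- as.matrix(aln)
  ids <- rownames(m)
  n <- nrow(m)
  gap <- m == "-"
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  flagged <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) {
        fail_if(on_empty == "error",
                "no comparable sites between '%s' and '%s'", ids[i], ids[j])
        p <- 0.75
      } else {
        p <- sum(m[i, ok] != m[j, ok]) / sum(ok)
      }
      if (model == "dayhoff_corrected") {
        arg <- 1 - p - 0.2 * p^2
        if (arg <= 0) {
          flagged <- c(flagged, paste(ids[i], ids[j], sep = ":"))
          dd <- p
        } else dd <- -log(arg)
      } else dd <- p
      d[i, j] <- d[j, i] <- dd
    }
  }
  attr(d, "flagged") <- flagged
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration via [ape::nj()]; negative branch-
#' length estimates are clamped to zero and counted in the `n_clamped`
#' attribute.
#'
#' @param d Symmetric distance matrix (>= 3 taxa).
#' @return Unrooted `phylo` tree.
#' @export
build_nj <- function(d) {
  fail_if(nrow(as.matrix(d)) < 3, "neighbour-joining needs >= 3 taxa")
  tree <- ape::nj(stats::as.dist(d))
  neg <- tree$edge.length < 0
  tree$edge.length[neg] <- 0
  attr(tree, "n_clamped") <- sum(neg)
  tree
}

#' Neighbour-joining tree with bootstrap supports
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_reps` times; each internal edge's support is the
#' percentage of replicate trees containing its bipartition.  Replicate
#' `r` uses a substream seeded from `(seed, r)`, so supports for early
#' replicates do not change when `n_reps` grows.
#'
#' @param aln A [protein_alignment()].
#' @param n_reps Number of bootstrap replicates (>= 1; default 1000).
#' @param seed Integer seed.
#' @param model Distance model, see [pairwise_distances()].
#' @return The full-data NJ tree with `node.label` set to supports in
#'   `[0, 100]` (root label empty).
#' @export
bootstrap_nj <- function(aln, n_reps = 1000, seed = 1,
                         model = "p_distance") {
  fail_if(n_reps < 1, "n_reps must be >= 1")
  full <- build_nj(pairwise_distances(aln, model))
  cols <- as.matrix(aln)
  boot_trees <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(substream_seed(seed, r))
    take <- sample.int(ncol(cols), replace = TRUE)
    rows <- apply(cols[, take, drop = FALSE], 1, paste, collapse = "")
    aln_r <- protein_alignment(rows)
    boot_trees[[r]] <- build_nj(
      pairwise_distances(aln_r, model, on_empty = "max"))
  }
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(full, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / n_reps
  full$node.label <- c("", formatC(support[-1], format = "fg"))
  attr(full, "support") <- support
  full
}

#' Fitch small-parsimony score of a tree given an alignment
#'
#' Minimum number of state changes summed over columns, counting gaps and
#' non-standard residues as missing data (a leaf with missing data never
#' forces a change).  Polytomies are resolved arbitrarily with zero-length
#' branches first, which leaves the score unchanged.
#'
#' @param tree A `phylo` tree whose tips equal the alignment ids.
#' @param aln A [protein_alignment()].
#' @return Integer parsimony score.
#' @export
parsimony_score <- function(tree, aln) {
  fail_if(!setequal(tree$tip.label, names(aln$seqs)),
          "tree tips and alignment ids differ")
  m <- as.matrix(aln)[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)
  total <- 0L
  for (col in seq_len(ncol(m))) {
    states <- m[, col]
    obs <- setdiff(sort(unique(states[states %in% LETTERS])), "X")
    if (length(obs) < 2) next
    bit <- stats::setNames(bitwShiftL(1L, seq_along(obs) - 1L), obs)
    full <- sum(bit)
    tipset <- ifelse(states %in% obs, bit[states], full)
    total <- total + fitch_changes(tree, as.integer(tipset))
  }
  total
}

# Fitch up-pass change count for one column.  Child sets are folded into
# the parent pairwise in postorder; at a multifurcation this equals Fitch
# on a zero-length binary resolution.
fitch_changes <- function(tree, tipset) {
  ntip <- length(tree$tip.label)
  node_set <- integer(ntip + tree$Nnode)
  node_set[seq_len(ntip)] <- tipset
  changes <- 0L
  for (e in ape::postorder(tree)) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    cs <- node_set[child]
    if (node_set[par] == 0L) {
      node_set[par] <- cs
    } else {
      inter <- bitwAnd(node_set[par], cs)
      if (inter == 0L) {
        node_set[par] <- bitwOr(node_set[par], cs)
        changes <- changes + 1L
      } else node_set[par] <- inter
    }
  }
  changes
}

#' Assign leaves to named groups via reference anchors
#'
#' After midpoint rooting, every non-reference leaf receives the label of
#' the smallest well-supported clade (bootstrap support at or above
#' `support_threshold`) that contains it together with reference leaves
#' of exactly one group; leaves in no such clade are `"unassigned"`.
#'
#' @param tree A `phylo` tree with bootstrap supports in `node.label`.
#' @param reference_map Data frame with columns `leaf_id`, `group`; every
#'   group has at least one reference leaf present in the tree.
#' @param support_threshold Minimum support, default 85.
#' @return Named character vector: leaf id -> group label (references map
#'   to their own group).
#' @export
assign_groups <- function(tree, reference_map, support_threshold = 85) {
  stopifnot(all(c("leaf_id", "group") %in% names(reference_map)))
  absent <- setdiff(reference_map$leaf_id, tree$tip.label)
  fail_if(length(absent) > 0, "reference leaf absent from tree: %s",
          paste(absent, collapse = ", "))
  rooted <- phangorn::midpoint(tree, node.labels = "support")
  ntip <- length(rooted$tip.label)
  supp <- suppressWarnings(as.numeric(rooted$node.label))
  internal <- (ntip + 1):(ntip + rooted$Nnode)
  clades <- lapply(internal, function(nd) descendant_leaves(rooted, nd))
  sizes <- lengths(clades)
  ref_group <- stats::setNames(reference_map$group, reference_map$leaf_id)

  out <- stats::setNames(rep("unassigned", ntip), rooted$tip.label)
  out[names(ref_group)] <- ref_group
  for (leaf in setdiff(rooted$tip.label, names(ref_group))) {
    cand <- which(vapply(clades, function(cl) leaf %in% cl, TRUE))
    # smallest first
    cand <- cand[order(sizes[cand])]
    for (ci in cand) {
      s <- supp[ci]
      is_root <- internal[ci] == ntip + 1L
      if (!is_root && (is.na(s) || s < support_threshold)) next
      refs <- intersect(clades[[ci]], names(ref_group))
      if (!length(refs)) next
      gs <- unique(ref_group[refs])
      if (length(gs) == 1) { out[leaf] <- gs; break }
      break  # smallest clade with references already spans several groups
    }
  }
  out
}
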