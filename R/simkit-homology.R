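# Controlled-divergence mutants and comparator proteomes for testing the
# duplicate / ortholog / diverged-gene detectors.

#' Mutate a protein to a target divergence
#'
#' Substitutes an exact number of positions, `round(divergence * length)`,
#' drawing replacements from the PAM-like kernel, so the resulting
#' ungapped identity to the input is `1 - divergence` up to rounding.
#'
#' @param protein Amino-acid string.
#' @param divergence Fraction of positions substituted, in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Mutated amino-acid string.
#' @export
mutate_protein <- function(protein, divergence, seed = NULL) {
  fail_if(divergence < 0 || divergence > 1, "divergence must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(protein, "")[[1]]
  n_mut <- round(divergence * length(ch))
  if (n_mut == 0) return(protein)
  kernel <- pam_kernel()
  idx <- sample(seq_along(ch), n_mut)
  for (i in idx) {
    a <- match(ch[i], AA20)
    if (is.na(a)) a <- sample(20, 1)
    # force a different residue
    p <- kernel[a, ]; p[a] <- 0
    ch[i] <- sample(AA20, 1, prob = p)
  }
  paste(ch, collapse = "")
}

#' Simulate comparator proteomes with planted diverged clades
#'
#' Builds `n_comparators` proteomes, each containing one mutated copy
#' (divergence `divergence`) of every family gene except those in a
#' planted diverged clade, plus unrelated random proteins.  The diverged
#' clade is a small monophyletic group of the truth tree whose members
#' therefore have no close hit in any comparator.
#'
#' @param truth The `truth` element of a [simulate_family()] result.
#' @param n_comparators Number of comparator proteomes (default 2).
#' @param divergence Divergence of the ortholog copies (default 0.25,
#'   i.e. 75 per cent identity, typical of orthologs between dicot
#'   families that diverged on the order of 100 My ago).
#' @param clade_size_range Inclusive size range for the diverged
#'   subfamily, default `c(1, 5)` genes (singleton diverged genes are
#'   legitimate).
#' @param n_random Unrelated random proteins added per comparator
#'   (default 5).
#' @param seed Integer seed.
#' @return List with `proteomes` (named list of named character vectors)
#'   and `diverged` (character vector of planted diverged gene ids).
#' @export
simulate_comparators <- function(truth, n_comparators = 2, divergence = 0.25,
                                 clade_size_range = c(1, 5), n_random = 5,
                                 seed = 1) {
  set.seed(seed)
  tree <- truth$tree
  ntip <- length(tree$tip.label)
  # candidate clades (tips count as singleton subfamilies) of the
  # requested size; take the one whose stem attaches deepest (closest to
  # the root), i.e. the most isolated subfamily, so its members genuinely
  # lack close comparator homologs.  Falls back to the smaller root child.
  all_nodes <- setdiff(seq_len(ntip + tree$Nnode), ntip + 1L)
  sizes <- vapply(all_nodes, function(nd)
    length(descendant_leaves(tree, nd)), 0L)
  ok <- all_nodes[sizes >= clade_size_range[1] & sizes <= clade_size_range[2]]
  root_kids <- tree$edge[tree$edge[, 1] == ntip + 1L, 2]
  if (length(ok)) {
    depth <- ape::node.depth.edgelength(tree)
    parent_depth <- vapply(ok, function(nd)
      depth[tree$edge[tree$edge[, 2] == nd, 1]], 0)
    diverged <- descendant_leaves(tree, ok[which.min(parent_depth)])
  } else {
    small <- root_kids[which.min(vapply(root_kids, function(nd)
      length(descendant_leaves(tree, nd)), 0L))]
    diverged <- descendant_leaves(tree, small)
  }
  kept <- setdiff(tree$tip.label, diverged)
  proteomes <- lapply(seq_len(n_comparators), function(ci) {
    copies <- vapply(kept, function(g)
      mutate_protein(truth$proteins[[g]], divergence), "")
    names(copies) <- sprintf("cmp%d_%s", ci, kept)
    rand <- vapply(seq_len(n_random), function(i) random_protein(400), "")
    names(rand) <- sprintf("cmp%d_rand%02d", ci, seq_len(n_random))
    c(copies, rand)
  })
  names(proteomes) <- sprintf("comparator%d", seq_len(n_comparators))
  list(proteomes = proteomes, diverged = diverged)
}
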