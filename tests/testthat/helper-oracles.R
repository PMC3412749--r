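# Independent brute-force oracles.  Each recomputes a quantity by direct
# enumeration, sharing no code with the implementation it checks.

# Best 44-mer window by explicit per-window summation.
oracle_scan <- function(protein, motif, matrix) {
  L <- nchar(motif)
  n <- nchar(protein)
  if (n < L) return(NULL)
  mch <- strsplit(motif, "")[[1]]
  best_s <- -Inf; best_o <- NA
  for (o in 1:(n - L + 1)) {
    w <- strsplit(substr(protein, o, o + L - 1), "")[[1]]
    s <- 0
    for (i in seq_len(L)) s <- s + matrix[mch[i], w[i]]
    if (s > best_s) { best_s <- s; best_o <- o }
  }
  list(offset = best_o, score = best_s)
}

# Global affine-gap alignment score by exhaustive enumeration of all
# alignments (three-way recursion over end states; no DP tables).
oracle_global_score <- function(a, b, gap_open, gap_extend, matrix) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1, "m") + matrix[av[i], bv[j]])
    if (i > 0) {
      cost <- if (state == "u") gap_extend else gap_open + gap_extend
      best <- max(best, rec(i - 1, j, "u") - cost)
    }
    if (j > 0) {
      cost <- if (state == "l") gap_extend else gap_open + gap_extend
      best <- max(best, rec(i, j - 1, "l") - cost)
    }
    best
  }
  rec(length(av), length(bv), "m")
}

# Minimum changes for one column over all internal-state assignments.
oracle_parsimony_column <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  obs <- sort(unique(tip_states[!is.na(tip_states)]))
  if (length(obs) < 2) return(0L)
  internal <- (ntip + 1):(ntip + tree$Nnode)
  grid <- expand.grid(rep(list(obs), length(internal)),
                      stringsAsFactors = FALSE)
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    assign_state <- function(nd) {
      if (nd <= ntip) tip_states[tree$tip.label[nd]]
      else grid[r, nd - ntip][[1]]
    }
    ch <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      s1 <- assign_state(tree$edge[e, 1]); s2 <- assign_state(tree$edge[e, 2])
      if (!is.na(s1) && !is.na(s2) && s1 != s2) ch <- ch + 1L
      # a missing tip matches anything: contributes no change
      if (is.na(s2)) ch <- ch
    }
    best <- min(best, ch)
  }
  as.integer(best)
}

# Minimum Dollo losses: enumerate 0/1 assignments over internal nodes,
# keep those with exactly one gain (root presence counts as the gain) and
# matching leaves; minimize the number of loss (1 -> 0) edges.
oracle_dollo <- function(tree, have) {
  ntip <- length(tree$tip.label)
  internal <- (ntip + 1):(ntip + tree$Nnode)
  combos <- expand.grid(rep(list(c(0L, 1L)), length(internal)))
  state_of <- function(nd, r) {
    if (nd <= ntip) as.integer(have[tree$tip.label[nd]])
    else combos[r, nd - ntip]
  }
  best <- NULL
  for (r in seq_len(nrow(combos))) {
    gains <- 0L; losses <- 0L; gain_node <- NA; loss_nodes <- integer(0)
    root_state <- combos[r, 1]
    if (root_state == 1L) { gains <- 1L; gain_node <- ntip + 1L }
    ok <- TRUE
    for (e in seq_len(nrow(tree$edge))) {
      s1 <- state_of(tree$edge[e, 1], r); s2 <- state_of(tree$edge[e, 2], r)
      if (s1 == 0L && s2 == 1L) { gains <- gains + 1L
                                  gain_node <- tree$edge[e, 2] }
      if (s1 == 1L && s2 == 0L) { losses <- losses + 1L
                                  loss_nodes <- c(loss_nodes, tree$edge[e, 2]) }
    }
    if (gains != 1L) ok <- FALSE
    if (ok && (is.null(best) || losses < best$losses))
      best <- list(losses = losses, gain_node = gain_node,
                   loss_nodes = loss_nodes)
  }
  best
}

# Average-linkage agglomeration by direct recomputation of all cluster
# pair mean distances at every step.
oracle_average_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        md <- mean(d[clusters[[i]], clusters[[j]]])
        if (is.null(best) || md < best$h) best <- list(i = i, j = j, h = md)
      }
    }
    merges[[length(merges) + 1]] <-
      list(members = sort(c(clusters[[best$i]], clusters[[best$j]])),
           height = best$h)
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  merges
}

# Minimal contiguous partition of sorted positions such that within each
# block consecutive gaps stay within the window, by exhaustive cuts.
oracle_1d_partition <- function(cols, window) {
  cols <- sort(cols)
  n <- length(cols)
  if (n == 1) return(list(n_blocks = 1L, blocks = list(cols)))
  best <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    blocks <- lapply(seq_len(length(bounds) - 1), function(b)
      cols[(bounds[b] + 1):bounds[b + 1]])
    feasible <- all(vapply(blocks, function(bl)
      length(bl) == 1 || all(diff(bl) <= window), TRUE))
    if (feasible && (is.null(best) || length(blocks) < best$n_blocks))
      best <- list(n_blocks = length(blocks), blocks = blocks)
  }
  best
}
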