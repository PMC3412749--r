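# Synthetic gene-family generator with full ground truth.
#
# Proteins evolve along a simulated birth-death tree under a PAM-like
# substitution kernel; a 44-residue signature motif evolves at a reduced
# rate and is protected from indels, so every family gene keeps exactly
# one recognizable motif window.  Indel history is tracked through real-
# valued column keys, which makes the implied true alignment exact.

#' Consensus of the 44-residue plant UGT signature motif (PSPG box)
#'
#' @return A single 44-character amino-acid string.
#' @export
pspg_consensus <- function() {
  "WAPQVEVLAHPAVGCFVTHCGWNSTLESISAGVPMVAWPFFADQ"
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# 20x20 replacement kernel: P(a -> b) proportional to exp(S_ab/2) over b != a,
# with S the PAM250 exchange scores.  A crude stationary process, adequate
# for generating recoverable phylogenetic signal.
pam_kernel <- function() {
  sm <- get_submat("PAM250")[AA20, AA20]
  K <- exp(sm / 2)
  diag(K) <- 0
  sweep(K, 1, rowSums(K), "/")
}

get_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# One evolutionary step along a branch of length t.
# seq: data.frame(key, aa, motif).  Returns the mutated child sequence.
evolve_branch <- function(seq, t, subst_rate, indel_rate, motif_rate_frac,
                          kernel) {
  rate <- ifelse(seq$motif, subst_rate * motif_rate_frac, subst_rate)
  p_sub <- 1 - exp(-rate * t)
  hit <- stats::runif(nrow(seq)) < p_sub
  if (any(hit)) {
    idx <- which(hit)
    cur <- match(seq$aa[idx], AA20)
    seq$aa[idx] <- vapply(cur, function(a) sample(AA20, 1, prob = kernel[a, ]),
                          "")
  }
  n_events <- stats::rpois(1, indel_rate * t * nrow(seq))
  for (e in seq_len(n_events)) {
    free <- which(!seq$motif)
    free <- free[free > 1]            # keep the initiator residue
    if (length(free) < 4) break
    if (stats::runif(1) < 0.5) {
      # insertion of 1-3 residues after a non-motif position
      at <- sample(free, 1)
      len <- sample(1:3, 1)
      k1 <- seq$key[at]
      k2 <- if (at < nrow(seq)) seq$key[at + 1] else k1 + 1
      new <- data.frame(
        key = k1 + (k2 - k1) * sort(stats::runif(len, 0.001, 0.999)),
        aa = sample(AA20, len, replace = TRUE),
        motif = FALSE
      )
      seq <- rbind(seq[1:at, ], new,
                   if (at < nrow(seq)) seq[(at + 1):nrow(seq), ])
    } else {
      # deletion of a short run of consecutive non-motif residues
      at <- sample(free, 1)
      len <- sample(1:3, 1)
      run <- at:min(at + len - 1, nrow(seq))
      run <- run[!seq$motif[run]]
      if (!length(run) || length(run) >= nrow(seq) - 50) next
      seq <- seq[-run, ]
    }
  }
  rownames(seq) <- NULL
  seq
}

# Dollo presence: leaves below the gain edge minus leaves below loss edges.
# Edges are identified by their child node number in the ape phylo tree;
# 0 denotes the root (present everywhere unless lost).
descendant_leaves <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node == 0) return(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tree$tip.label[unlist(phangorn_free_descendants(tree, node))]
}

# sample() without the length-1 surprise
sample_one <- function(x) x[sample.int(length(x), 1)]

# minimal descendant-tips helper (avoids a phangorn dependency in R/)
phangorn_free_descendants <- function(tree, node) {
  ntip <- length(tree$tip.label)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    tips <- kids[kids <= ntip]
    out <- c(out, tips)
    stack <- c(stack, kids[kids > ntip])
  }
  list(out)
}

#' Simulate a gene family with known evolutionary ground truth
#'
#' Evolves a protein family along a birth-death tree, plants a conserved
#' 44-residue motif, inserts introns according to a known gain/loss
#' history, back-translates to CDS with canonical GT..AG introns, appends
#' decoy genes that fail the mining filters in known ways, and writes the
#' result as a genome FASTA plus GFF3.
#'
#' @param n_leaves Number of family genes (tree tips), at least 3.
#' @param birth,death Birth-death rates for [ape::rphylo()].
#' @param subst_rate Expected substitutions per site over one unit of tree
#'   depth (the tree is rescaled to depth 1).
#' @param indel_rate Expected indel events per site per unit depth.
#' @param motif_consensus 44-residue motif planted near the C terminus.
#' @param seed Integer seed; all outputs are deterministic given it.
#' @param dir Output directory for `genome.fasta` and `genes.gff3`.
#' @param root_length Root protein length in residues.
#' @param motif_rate_frac Fraction of `subst_rate` applying inside the
#'   motif window (default 0.15).
#' @param n_intron_classes Number of intron classes planted (default 5;
#'   the first two are ancestral, i.e. gained at the root).
#' @param intron_jitter Uniform positional jitter (residues, default 5)
#'   applied per gene to each planted intron position.
#' @param n_losses Number of loss branches planted per ancestral class
#'   (default 1).
#' @param decoy_frac Fraction of all emitted genes that are decoys
#'   (default 0.3), split across the three failure modes: no motif,
#'   out-of-range length, too many introns.
#' @param n_groups Number of ground-truth phylogenetic groups (default 3).
#' @param tissues Tissue codes for the expression truth (default 5 codes
#'   from [default_tissues()]).
#' @param unexpressed_frac Fraction of family genes given zero expression
#'   weight in every tissue (default 0.3).
#' @return An object of class `family_sim`: paths `genome_fasta` and
#'   `gff3`, plus `truth`, a list holding the generating tree with group
#'   labels, the true alignment, per-gene motif windows, the planted
#'   intron history and presence matrix, per-gene intron positions, CDS
#'   sequences, expression weights, qPCR truth and the decoy table.
#' @export
simulate_family <- function(n_leaves = 20, birth = 1, death = 0,
                            subst_rate = 0.75, indel_rate = 0.01,
                            motif_consensus = pspg_consensus(),
                            seed = 1, dir = tempfile("famsim"),
                            root_length = 470, motif_rate_frac = 0.15,
                            n_intron_classes = 5, intron_jitter = 5,
                            n_losses = 1, decoy_frac = 0.3, n_groups = 3,
                            tissues = c("FL", "GE", "TC", "ST", "LE"),
                            unexpressed_frac = 0.3) {
  fail_if(n_leaves < 3, "n_leaves must be >= 3 (got %d)", n_leaves)
  fail_if(subst_rate < 0 || indel_rate < 0, "rates must be non-negative")
  fail_if(nchar(motif_consensus) != 44,
          "motif consensus must be exactly 44 residues (got %d)",
          nchar(motif_consensus))
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  ## -- tree ----------------------------------------------------------------
  tree <- ape::rphylo(n_leaves, birth = birth, death = death)
  tree <- stats::reorder(tree, "cladewise")  # parents precede children
  tree$tip.label <- sprintf("g%03d", seq_len(n_leaves))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  ntip <- length(tree$tip.label)

  ## ground-truth groups: monophyletic cuts of the ultrametric tree
  k <- min(n_groups, n_leaves)
  cl <- stats::cutree(stats::hclust(stats::as.dist(
    ape::cophenetic.phylo(tree)), method = "average"), k = k)
  groups <- stats::setNames(LETTERS[cl], names(cl))

  ## -- root protein with planted motif -------------------------------------
  motif_start <- root_length - 44 - 30
  aa <- strsplit(random_protein(root_length), "")[[1]]
  aa[1] <- "M"
  aa[motif_start:(motif_start + 43)] <- strsplit(motif_consensus, "")[[1]]
  root_seq <- data.frame(key = as.numeric(seq_len(root_length)), aa = aa,
                         motif = seq_len(root_length) %in%
                           motif_start:(motif_start + 43))

  ## -- evolve along the tree ------------------------------------------------
  kernel <- pam_kernel()
  nodes <- vector("list", ntip + tree$Nnode)
  root <- ntip + 1L
  nodes[[root]] <- root_seq
  for (i in seq_len(nrow(tree$edge))) {  # ape edges are in preorder
    par <- tree$edge[i, 1]; child <- tree$edge[i, 2]
    nodes[[child]] <- evolve_branch(nodes[[par]], tree$edge.length[i],
                                    subst_rate, indel_rate, motif_rate_frac,
                                    kernel)
  }
  leaf_seqs <- nodes[seq_len(ntip)]
  names(leaf_seqs) <- tree$tip.label

  ## true alignment from the union of column keys
  all_keys <- sort(unique(unlist(lapply(leaf_seqs, `[[`, "key"))))
  aln_rows <- vapply(leaf_seqs, function(s) {
    row <- rep("-", length(all_keys))
    row[match(s$key, all_keys)] <- s$aa
    paste(row, collapse = "")
  }, "")
  true_alignment <- protein_alignment(aln_rows)

  proteins <- vapply(leaf_seqs, function(s) paste(s$aa, collapse = ""), "")
  motif_window <- data.frame(
    gene_id = names(leaf_seqs),
    start = vapply(leaf_seqs, function(s) which(s$motif)[1], 0L)
  )

  ## -- intron history -------------------------------------------------------
  # The family's architecture caps every gene at 2 introns: two "ancestral"
  # classes partition the deep clades (one gained at the root, one on a
  # deep stem), and younger classes are gained only where the resulting
  # per-gene load stays within 2.  Losses are placed so the surviving
  # leaves keep the gain branch as their MRCA, making the planted history
  # Dollo-identifiable.
  root <- ntip + 1L
  n_cl <- n_intron_classes
  # codon-aligned anchors on the root protein, spaced widely enough that
  # jittered positions stay separable, and clear of the motif window
  lo <- 15; hi <- motif_start - 15
  anchors <- round(seq(lo, hi, length.out = max(n_cl, 2)))[seq_len(n_cl)]
  phases <- sample(c(0L, 1L, 1L, 2L), n_cl, replace = TRUE)
  gain_edge <- integer(n_cl)   # gain node (clade root); root node = ancestral
  loss_edges <- vector("list", n_cl)

  root_kids <- tree$edge[tree$edge[, 1] == root, 2]
  clade_size <- function(nd) length(descendant_leaves(tree, nd))
  cA <- root_kids[which.max(vapply(root_kids, clade_size, 0L))]
  cB <- setdiff(root_kids, cA)[1]
  # nodes strictly inside a clade (proper descendants of its children)
  proper_inside <- function(top) {
    kids <- tree$edge[tree$edge[, 1] == top, 2]
    unlist(lapply(kids, function(kk) {
      below <- setdiff(gain_clade_nodes(tree, kk), kk)
      below
    }))
  }
  if (n_cl >= 1) {           # class 1: gained at the root, lost inside B
    gain_edge[1] <- root
    cand <- if (cB <= ntip) integer(0) else proper_inside(cB)
    loss_edges[[1]] <- if (n_losses > 0 && length(cand))
      sample_one(cand) else integer(0)
  }
  if (n_cl >= 2) {           # class 2: gained on A's stem, rare loss inside
    gain_edge[2] <- cA
    cand <- if (cA <= ntip) integer(0) else {
      akids <- tree$edge[tree$edge[, 1] == cA, 2]
      unlist(lapply(akids[akids > ntip], function(kk)
        setdiff(gain_clade_nodes(tree, kk), kk)))
    }
    loss_edges[[2]] <- if (n_losses > 0 && length(cand))
      sample_one(cand) else integer(0)
  }
  presence <- matrix(FALSE, ntip, n_cl,
                     dimnames = list(tree$tip.label,
                                     paste0("class", seq_len(n_cl), recycle0 = TRUE)))
  apply_class <- function(cc) {
    have <- descendant_leaves(tree, gain_edge[cc])
    for (l in loss_edges[[cc]])
      have <- setdiff(have, descendant_leaves(tree, l))
    presence[have, cc] <<- TRUE
  }
  for (cc in seq_len(min(2, n_cl))) apply_class(cc)
  # younger classes: any clade whose every leaf still has load <= 1
  if (n_cl > 2) {
    all_nodes <- setdiff(seq_len(ntip + tree$Nnode), root)
    for (cc in 3:n_cl) {
      load <- rowSums(presence)
      ok <- all_nodes[vapply(all_nodes, function(nd)
        max(load[descendant_leaves(tree, nd)]) <= 1, TRUE)]
      ok <- setdiff(ok, gain_edge[seq_len(cc - 1)])
      if (!length(ok)) next
      gain_edge[cc] <- sample_one(ok)
      loss_edges[[cc]] <- integer(0)
      apply_class(cc)
    }
  }
  # drop classes never realized (no gain found or lost everywhere)
  keep <- colSums(presence) > 0
  presence <- presence[, keep, drop = FALSE]
  gain_edge <- gain_edge[keep]; loss_edges <- loss_edges[keep]
  anchors <- anchors[keep]; phases <- phases[keep]
  n_cl <- sum(keep)
  colnames(presence) <- paste0("class", seq_len(n_cl), recycle0 = TRUE)

  intron_history <- data.frame(
    class_id = seq_len(n_cl), anchor_pos = anchors, phase = phases,
    gain_node = gain_edge,
    loss_nodes = I(loss_edges)
  )

  ## per-gene intron positions (anchor key projected to leaf + jitter)
  anchor_keys <- as.numeric(anchors)
  intron_positions <- do.call(rbind, lapply(tree$tip.label, function(g) {
    s <- leaf_seqs[[g]]
    cls <- which(presence[g, ])
    if (!length(cls)) return(NULL)
    pos <- vapply(cls, function(cc) {
      p <- sum(s$key <= anchor_keys[cc])            # residue index at anchor
      p <- p + sample(-intron_jitter:intron_jitter, 1)
      max(2L, min(nrow(s) - 1L, p))
    }, 0L)
    data.frame(gene_id = g, class_id = cls, protein_pos = pos,
               phase = phases[cls])
  }))
  if (is.null(intron_positions))
    intron_positions <- data.frame(gene_id = character(0),
                                   class_id = integer(0),
                                   protein_pos = integer(0),
                                   phase = integer(0))
  rownames(intron_positions) <- NULL

  ## -- decoys ---------------------------------------------------------------
  n_decoys <- round(decoy_frac / (1 - decoy_frac) * n_leaves)
  modes <- rep(c("no_motif", "length", "intron_count"), length.out = n_decoys)
  decoy_rows <- list()
  for (i in seq_along(modes)) {
    id <- sprintf("d%03d", i)
    src <- sample(proteins, 1)
    prot <- switch(modes[i],
      no_motif = random_protein(450),
      length = paste0(random_protein(270), motif_consensus,
                      random_protein(16)),          # 330 aa, motif intact
      intron_count = src)
    n_int <- if (modes[i] == "intron_count") 3L else 0L
    decoy_rows[[i]] <- list(gene_id = id, reason = modes[i], protein = prot,
                            n_introns = n_int)
  }
  decoys <- data.frame(
    gene_id = vapply(decoy_rows, `[[`, "", "gene_id"),
    reason = vapply(decoy_rows, `[[`, "", "reason"),
    stringsAsFactors = FALSE
  )

  ## -- back-translation and genome layout -----------------------------------
  all_ids <- c(tree$tip.label, decoys$gene_id)
  all_prot <- c(proteins, stats::setNames(
    vapply(decoy_rows, `[[`, "", "protein"), decoys$gene_id))
  gene_introns <- lapply(stats::setNames(all_ids, all_ids), function(g) {
    if (g %in% tree$tip.label) {
      d <- intron_positions[intron_positions$gene_id == g, , drop = FALSE]
      if (!nrow(d)) return(data.frame(protein_pos = integer(0),
                                      phase = integer(0)))
      d[order(3 * (d$protein_pos - 1) + d$phase),
        c("protein_pos", "phase"), drop = FALSE]
    } else {
      n_int <- decoy_rows[[match(g, decoys$gene_id)]]$n_introns
      if (n_int == 0) return(data.frame(protein_pos = integer(0),
                                        phase = integer(0)))
      len <- nchar(all_prot[[g]])
      data.frame(protein_pos = sort(sample(10:(len - 10), n_int)),
                 phase = sample(0:2, n_int, replace = TRUE))
    }
  })

  cds_seqs <- vapply(all_ids, function(g)
    back_translate(all_prot[[g]]), "")

  contigs <- character(0); gff_models <- list()
  strands <- rep(c("+", "-"), length.out = length(all_ids))
  for (i in seq_along(all_ids)) {
    g <- all_ids[i]
    built <- build_gene_locus(g, cds_seqs[[g]], gene_introns[[g]],
                              strand = strands[i])
    contigs[built$contig_name] <- built$contig_seq
    gff_models[[g]] <- built$model
  }

  genome_fasta <- file.path(dir, "genome.fasta")
  gff3 <- file.path(dir, "genes.gff3")
  ctg <- Biostrings::DNAStringSet(contigs)
  Biostrings::writeXStringSet(ctg, genome_fasta, width = 80)
  write_gene_models(gff_models, gff3)

  ## -- expression / qPCR truth ----------------------------------------------
  n_unexpr <- round(unexpressed_frac * n_leaves)
  unexpressed <- sample(tree$tip.label, n_unexpr)
  expressed <- setdiff(tree$tip.label, unexpressed)
  w <- matrix(0, n_leaves, length(tissues),
              dimnames = list(tree$tip.label, tissues))
  for (tt in tissues) {
    raw <- stats::rgamma(length(expressed), shape = 0.5)
    w[expressed, tt] <- raw / sum(raw)
  }
  qpcr_genes <- sample(expressed, min(6, length(expressed)))
  qt <- matrix(2^stats::runif(length(qpcr_genes) * length(tissues), -4, 4),
               length(qpcr_genes), length(tissues),
               dimnames = list(qpcr_genes, tissues))

  truth <- list(
    tree = tree, groups = groups, true_alignment = true_alignment,
    proteins = proteins, motif_window = motif_window,
    intron_history = intron_history, presence = presence,
    intron_positions = intron_positions,
    cds = stats::setNames(cds_seqs[tree$tip.label], tree$tip.label),
    expression_weights = w, qpcr_truth = qt,
    decoys = decoys, family_genes = tree$tip.label,
    motif_consensus = motif_consensus
  )
  structure(list(dir = dir, genome_fasta = genome_fasta, gff3 = gff3,
                 truth = truth),
            class = "family_sim")
}

#' @export
print.family_sim <- function(x, ...) {
  cat(sprintf("<family_sim> %d family genes + %d decoys in %s\n",
              length(x$truth$family_genes), nrow(x$truth$decoys), x$dir))
  invisible(x)
}

# Uniform synonymous back-translation (standard code), stop codon appended.
back_translate <- function(protein) {
  if (!exists("CODON_BY_AA", envir = simkit_cache))
    assign("CODON_BY_AA", local({
      gc <- Biostrings::GENETIC_CODE
      split(names(gc), unname(gc))
    }), envir = simkit_cache)
  tab <- get("CODON_BY_AA", envir = simkit_cache)
  aas <- strsplit(protein, "")[[1]]
  codons <- vapply(aas, function(a) {
    opts <- tab[[a]]
    if (is.null(opts)) "NNN" else opts[sample.int(length(opts), 1)]
  }, "")
  paste0(paste(codons, collapse = ""), "TAA")
}

simkit_cache <- new.env(parent = emptyenv())

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Lay one gene (CDS + planted introns) onto its own contig.
# introns: data.frame(protein_pos, phase) in transcription order.
build_gene_locus <- function(gene_id, cds, introns, strand) {
  offs <- if (nrow(introns)) 3L * (introns$protein_pos - 1L) + introns$phase
          else integer(0)
  stopifnot(!anyDuplicated(offs), all(offs > 0), all(offs < nchar(cds)))
  ilens <- if (length(offs))
    round(exp(stats::runif(length(offs), log(65), log(2258)))) else integer(0)
  # sense gene sequence with introns spliced in
  pieces <- character(0); seg_lens <- integer(0)
  prev <- 0L
  for (j in seq_along(offs)) {
    pieces <- c(pieces, substr(cds, prev + 1L, offs[j]),
                paste0("GT", random_dna(ilens[j] - 4L), "AG"))
    seg_lens <- c(seg_lens, offs[j] - prev)
    prev <- offs[j]
  }
  pieces <- c(pieces, substr(cds, prev + 1L, nchar(cds)))
  seg_lens <- c(seg_lens, nchar(cds) - prev)
  gene_sense <- paste(pieces, collapse = "")

  flank5 <- random_dna(sample(50:150, 1))
  flank3 <- random_dna(sample(50:150, 1))
  contig_name <- paste0("ctg_", gene_id)

  # sense-coordinate CDS segments within the gene
  seg_start <- cumsum(c(1L, utils::head(seg_lens, -1) + ilens))
  seg_end <- seg_start + seg_lens - 1L
  gene_off <- nchar(flank5)

  if (strand == "+") {
    contig_seq <- paste0(flank5, gene_sense, flank3)
    cds_iv <- data.frame(start = gene_off + seg_start, end = gene_off + seg_end)
  } else {
    contig_seq <- paste0(flank5,
                         as.character(Biostrings::reverseComplement(
                           Biostrings::DNAString(gene_sense))), flank3)
    glen <- nchar(gene_sense)
    cds_iv <- data.frame(start = gene_off + glen - seg_end + 1L,
                         end = gene_off + glen - seg_start + 1L)
  }
  prot <- sub("\\*$", "", as.character(
    Biostrings::translate(Biostrings::DNAString(cds), no.init.codon = TRUE)))
  model <- gene_model(gene_id, contig_name, strand,
                      exons = cds_iv, cds = cds_iv,
                      protein = prot, complete = TRUE)
  list(contig_name = contig_name, contig_seq = contig_seq, model = model)
}
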