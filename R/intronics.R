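# Intron architecture: extraction and phases, projection onto the family
# alignment, conserved intron classes, gain/loss inference, census.

#' Extract introns from a gene model
#'
#' One record per gap between consecutive CDS intervals in transcription
#' order.  `cds_offset` is the number of CDS nucleotides preceding the
#' intron; phase is `cds_offset mod 3` (0 = between codons, 1 = after the
#' first base, 2 = after the second); the protein position is the residue
#' encoded by the interrupted (or following) codon,
#' `floor(cds_offset / 3) + 1`.
#'
#' @param model A complete [gene_model()] (CDS length divisible by 3).
#' @return Data frame with columns `gene_id`, `intron_index`,
#'   `cds_offset`, `phase`, `protein_pos`, `length_bp` (empty for
#'   single-exon genes).
#' @export
extract_introns <- function(model) {
  fail_if(!model$complete,
          "gene model '%s' is incomplete (CDS not a multiple of 3)",
          model$gene_id)
  cds <- model$cds
  k <- nrow(cds) - 1L
  if (k < 1)
    return(data.frame(gene_id = character(0), intron_index = integer(0),
                      cds_offset = integer(0), phase = integer(0),
                      protein_pos = integer(0), length_bp = integer(0)))
  seg_len <- cds$end - cds$start + 1L
  offs <- cumsum(seg_len)[seq_len(k)]
  len_bp <- vapply(seq_len(k), function(i) {
    a <- cds[i, ]; b <- cds[i + 1, ]
    if (model$strand == "+") b$start - a$end - 1L else a$start - b$end - 1L
  }, 0L)
  fail_if(any(len_bp < 1), "non-positive intron length in '%s'", model$gene_id)
  data.frame(gene_id = model$gene_id,
             intron_index = seq_len(k),
             cds_offset = offs,
             phase = offs %% 3L,
             protein_pos = offs %/% 3L + 1L,
             length_bp = len_bp,
             stringsAsFactors = FALSE)
}

#' Extract introns from many gene models
#'
#' @param models Named list of gene models; incomplete models are skipped
#'   with a warning.
#' @return Row-bound intron records.
#' @export
extract_introns_all <- function(models) {
  ok <- vapply(models, `[[`, TRUE, "complete")
  if (any(!ok))
    warning(sprintf("%d incomplete model(s) skipped in intron extraction",
                    sum(!ok)), call. = FALSE)
  out <- do.call(rbind, lapply(models[ok], extract_introns))
  rownames(out) <- NULL
  out
}

#' Project intron records onto the family alignment
#'
#' Adds a `column` field: the alignment column of the residue at each
#' record's `protein_pos`, via the alignment's residue-to-column map.
#'
#' @param records Intron records from [extract_introns()].
#' @param aln A [protein_alignment()] containing every record's gene.
#' @return `records` with an integer `column` added.
#' @export
project_to_alignment <- function(records, aln) {
  absent <- setdiff(unique(records$gene_id), names(aln$seqs))
  fail_if(length(absent) > 0, "gene absent from alignment: %s",
          paste(absent, collapse = ", "))
  records$column <- vapply(seq_len(nrow(records)), function(i)
    aln_pos_to_col(aln, records$gene_id[i], records$protein_pos[i]),
    0L)
  records
}

#' Cluster projected introns into conserved intron classes
#'
#' Single-linkage clustering on the 1-D alignment columns with merge
#' radius `window_aa`: introns whose columns chain together within the
#' window form one class, interpreted as one ancestral insertion site.
#' Classes are numbered serially by mean column.  A class is flagged
#' conserved when its members span at least `min_groups` phylogenetic
#' groups or at least `min_members` genes.
#'
#' @param records Projected intron records (with `column`).
#' @param window_aa Merge radius in alignment columns (> 0; default 45).
#' @param group_map Optional named vector gene -> group, used for the
#'   conserved flag.
#' @param min_groups,min_members Conservation thresholds (defaults 2 and
#'   10).
#' @return List with `members` (`records` plus `class_id`) and `classes`
#'   (data frame `class_id`, `mean_column`, `n_introns`, `n_genes`,
#'   `n_groups`, `conserved`).
#' @export
cluster_intron_classes <- function(records, window_aa = 45, group_map = NULL,
                                   min_groups = 2, min_members = 10) {
  fail_if(window_aa <= 0, "window_aa must be positive")
  if (!nrow(records)) {
    return(list(members = cbind(records, class_id = integer(0)),
                classes = data.frame(class_id = integer(0),
                                     mean_column = numeric(0),
                                     n_introns = integer(0),
                                     n_genes = integer(0),
                                     n_groups = integer(0),
                                     conserved = logical(0))))
  }
  ord <- order(records$column)
  cols <- records$column[ord]
  breaks <- c(0, which(diff(cols) > window_aa), length(cols))
  cl_sorted <- rep(seq_len(length(breaks) - 1),
                   times = diff(breaks))
  cl <- integer(nrow(records))
  cl[ord] <- cl_sorted
  means <- tapply(records$column, cl, mean)
  # serial ids by mean column (already ascending by construction)
  records$class_id <- cl
  classes <- data.frame(
    class_id = as.integer(names(means)),
    mean_column = as.numeric(means),
    n_introns = as.integer(table(cl)[names(means)]),
    n_genes = as.integer(tapply(records$gene_id, cl,
                                function(g) length(unique(g)))[names(means)])
  )
  classes <- classes[order(classes$mean_column), ]
  if (!is.null(group_map)) {
    ngr <- tapply(records$gene_id, cl, function(g)
      length(unique(stats::na.omit(group_map[unique(g)]))))
    classes$n_groups <- as.integer(ngr[as.character(classes$class_id)])
  } else classes$n_groups <- NA_integer_
  classes$conserved <- (!is.na(classes$n_groups) &
                          classes$n_groups >= min_groups) |
                       classes$n_genes >= min_members
  rownames(classes) <- NULL
  list(members = records, classes = classes)
}

#' Presence/absence matrix of intron classes across genes
#'
#' @param members Output `members` of [cluster_intron_classes()].
#' @param genes All family gene ids (rows; intronless genes give all-zero
#'   rows).
#' @return Logical matrix genes x classes.
#' @export
presence_matrix <- function(members, genes) {
  cls <- sort(unique(members$class_id))
  m <- matrix(FALSE, length(genes), length(cls),
              dimnames = list(genes, paste0("class", cls, recycle0 = TRUE)))
  for (i in seq_len(nrow(members)))
    m[members$gene_id[i], paste0("class", members$class_id[i])] <- TRUE
  m
}

#' Infer intron gain/loss events on a gene tree
#'
#' Under Dollo parsimony each intron class is gained exactly once, at the
#' most recent common ancestor of the genes possessing it; losses are the
#' minimal set of branches whose removal explains every absent descendant
#' (one post-order pass).  Under Fitch parsimony presence/absence changes
#' freely and a minimum-change scenario is reported (root state preferring
#' absence on ties).
#'
#' @param tree `phylo` tree whose tips are the presence-matrix rows.
#' @param presence Logical/0-1 matrix, rows = tree tips, columns = intron
#'   classes.
#' @param model `"dollo"` or `"fitch"`.
#' @return List with `events` (data frame `class_id`, `node`, `branch`
#'   (tip label or `"node<k>"`), `type` gain/loss), `per_class` (list of
#'   gain node and loss nodes for dollo), `total_events`, `model`.
#' @export
infer_events <- function(tree, presence, model = c("dollo", "fitch")) {
  model <- match.arg(model)
  fail_if(!setequal(rownames(presence), tree$tip.label),
          "presence-matrix rows and tree tips differ")
  presence <- presence[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  branch_name <- function(nd)
    ifelse(nd <= ntip, tree$tip.label[nd], paste0("node", nd))

  # subtree tip counts of possessing leaves, per node, one postorder pass
  events <- list(); per_class <- list()
  for (ci in seq_len(ncol(presence))) {
    have <- presence[, ci]
    cnt <- integer(nnode)
    cnt[seq_len(ntip)] <- as.integer(have)
    sub_n <- integer(nnode)                  # total tips below
    sub_n[seq_len(ntip)] <- 1L
    for (e in ape::postorder(tree)) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      cnt[par] <- cnt[par] + cnt[ch]
      sub_n[par] <- sub_n[par] + sub_n[ch]
    }
    if (model == "dollo") {
      tips_have <- which(have)
      fail_if(length(tips_have) == 0,
              "class %s present in no leaf", colnames(presence)[ci])
      gain <- if (length(tips_have) == 1) unname(tips_have) else
        ape::getMRCA(tree, tree$tip.label[tips_have])
      # losses: maximal empty subtrees strictly inside the gain clade
      inside <- gain_clade_nodes(tree, gain)
      losses <- integer(0)
      for (nd in inside) {
        if (nd == gain) next
        par <- tree$edge[tree$edge[, 2] == nd, 1]
        if (cnt[nd] == 0 && cnt[par] > 0) losses <- c(losses, nd)
      }
      per_class[[ci]] <- list(gain_node = gain, loss_nodes = losses)
      events[[ci]] <- data.frame(
        class_id = ci,
        node = c(gain, losses),
        branch = branch_name(c(gain, losses)),
        type = c("gain", rep("loss", length(losses))),
        stringsAsFactors = FALSE)
    } else {
      ev <- fitch_binary_events(tree, have)
      per_class[[ci]] <- NULL
      events[[ci]] <- if (nrow(ev)) cbind(class_id = ci, ev) else NULL
    }
  }
  ev <- do.call(rbind, events)
  if (is.null(ev))
    ev <- data.frame(class_id = integer(0), node = integer(0),
                     branch = character(0), type = character(0))
  rownames(ev) <- NULL
  list(events = ev, per_class = per_class, total_events = nrow(ev),
       model = model)
}

# all nodes (internal and tips) in the clade rooted at `gain`
gain_clade_nodes <- function(tree, gain) {
  ntip <- length(tree$tip.label)
  out <- gain
  stack <- gain
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > ntip])
  }
  unique(out)
}

# Minimum-change scenario for a binary character: Fitch up-pass sets plus
# a down-pass choosing the parent's state when allowed (root prefers 0).
fitch_binary_events <- function(tree, have) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  # sets coded 1 = {0}, 2 = {1}, 3 = {0,1}
  setv <- integer(nnode)
  setv[seq_len(ntip)] <- ifelse(have, 2L, 1L)
  for (e in ape::postorder(tree)) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (setv[par] == 0L) setv[par] <- setv[ch]
    else {
      inter <- bitwAnd(setv[par], setv[ch])
      setv[par] <- if (inter == 0L) bitwOr(setv[par], setv[ch]) else inter
    }
  }
  state <- integer(nnode)
  state[root] <- if (bitwAnd(setv[root], 1L)) 0L else 1L
  rows <- list()
  for (e in rev(ape::postorder(tree))) {   # preorder: parents first
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    ps_bit <- bitwShiftL(1L, state[par])
    state[ch] <- if (bitwAnd(setv[ch], ps_bit)) state[par]
                 else if (bitwAnd(setv[ch], 1L)) 0L else 1L
    if (state[ch] != state[par])
      rows[[length(rows) + 1]] <- data.frame(
        node = ch,
        branch = if (ch <= ntip) tree$tip.label[ch] else paste0("node", ch),
        type = if (state[ch] == 1L) "gain" else "loss",
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(node = integer(0), branch = character(0),
                      type = character(0)))
  do.call(rbind, rows)
}

#' Intron census over a gene set
#'
#' @param records Intron records (projected or not) whose genes all occur
#'   in `genes`.
#' @param genes Character vector of all family gene ids.
#' @param digits Decimal places for the mean (default 2).
#' @param mode `"round"` (half-up) or `"truncate"` for printed means.
#' @return List: `n_genes`, `genes_by_intron_count` (named vector
#'   `"0"`, `"1"`, `"2+"`), `total_introns`, `mean_per_gene`,
#'   `length_min`/`length_max`/`length_mean` (NA without lengths) and
#'   `phase_hist` (named vector over phases 0/1/2).
#' @export
intron_census <- function(records, genes, digits = 2,
                          mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  extra <- setdiff(unique(records$gene_id), genes)
  fail_if(length(extra) > 0, "records refer to unknown genes: %s",
          paste(extra, collapse = ", "))
  per_gene <- table(factor(records$gene_id, levels = genes))
  n_by <- c("0" = sum(per_gene == 0), "1" = sum(per_gene == 1),
            "2+" = sum(per_gene >= 2))
  total <- nrow(records)
  mean_pg <- if (length(genes)) round_mode(total / length(genes), digits, mode)
             else 0
  lengths_known <- "length_bp" %in% names(records) && nrow(records) > 0
  phase_hist <- table(factor(records$phase, levels = 0:2))
  list(n_genes = length(genes),
       genes_by_intron_count = n_by,
       total_introns = total,
       mean_per_gene = mean_pg,
       length_min = if (lengths_known) min(records$length_bp) else NA,
       length_max = if (lengths_known) max(records$length_bp) else NA,
       length_mean = if (lengths_known)
         round_mode(mean(records$length_bp), digits, mode) else NA,
       phase_hist = stats::setNames(as.integer(phase_hist),
                                    names(phase_hist)))
}
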