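# Intron extraction, phases, projection, classes, events and census.

test_that("phase and protein position follow the codon-boundary rules", {
  # CDS split after nt 3 (phase 0) and after nt 4 (phase 1)
  m0 <- gene_model("g0", "c", "+",
                   exons = data.frame(start = c(1, 104), end = c(3, 109)),
                   cds = data.frame(start = c(1, 104), end = c(3, 109)),
                   protein = "MA")
  r0 <- extract_introns(m0)
  expect_equal(r0$phase, 0L)
  expect_equal(r0$protein_pos, 2L)
  m1 <- gene_model("g1", "c", "+",
                   exons = data.frame(start = c(1, 104), end = c(4, 108)),
                   cds = data.frame(start = c(1, 104), end = c(4, 108)),
                   protein = "MA")
  r1 <- extract_introns(m1)
  expect_equal(r1$phase, 1L)
  expect_equal(r1$protein_pos, 2L)
  expect_equal(r1$cds_offset, 4L)
  expect_equal(r1$length_bp, 99L)
  # single-exon gene: no introns
  m2 <- gene_model("g2", "c", "+", data.frame(start = 1, end = 9),
                   data.frame(start = 1, end = 9), "MA")
  expect_equal(nrow(extract_introns(m2)), 0L)
  # incomplete models are rejected
  m3 <- gene_model("g3", "c", "+", data.frame(start = 1, end = 8),
                   data.frame(start = 1, end = 8), "MA", complete = FALSE)
  expect_error(extract_introns(m3), "incomplete")
})

test_that("projection follows the alignment residue map", {
  aln <- protein_alignment(c(g = "M-AV", h = "MKAV"))
  rec <- data.frame(gene_id = "g", intron_index = 1L, cds_offset = 4L,
                    phase = 1L, protein_pos = 2L, length_bp = 70L)
  expect_equal(project_to_alignment(rec, aln)$column, 3L)
  rec$gene_id <- "zz"
  expect_error(project_to_alignment(rec, aln), "absent")
})

test_that("single-linkage classes split exactly at gaps wider than the window", {
  rec <- function(cols) data.frame(gene_id = paste0("g", seq_along(cols)),
                                   column = cols, phase = 0L)
  one <- cluster_intron_classes(rec(c(100, 100, 100)), 45)
  expect_equal(nrow(one$classes), 1L)
  expect_equal(one$classes$n_introns, 3L)
  two <- cluster_intron_classes(rec(c(100, 300)), 45)
  expect_equal(nrow(two$classes), 2L)
  expect_error(cluster_intron_classes(rec(100), 0), "positive")
})

test_that("clustering equals the optimal 1-D partition on small inputs", {
  set.seed(15)
  for (rep in 1:8) {
    n <- sample(4:12, 1)
    cols <- sort(sample(1:400, n))
    recs <- data.frame(gene_id = paste0("g", seq_len(n)), column = cols,
                       phase = 0L)
    got <- cluster_intron_classes(recs, 45)
    want <- oracle_1d_partition(cols, 45)
    expect_equal(nrow(got$classes), want$n_blocks)
    got_blocks <- split(got$members$column, got$members$class_id)
    expect_equal(unname(lapply(got_blocks, sort)),
                 unname(want$blocks))
  }
})

test_that("conserved flag reflects group breadth or membership size", {
  recs <- data.frame(gene_id = c(paste0("g", 1:3), paste0("h", 1:2)),
                     column = c(100, 101, 102, 300, 301), phase = 0L)
  gm <- c(g1 = "A", g2 = "A", g3 = "A", h1 = "A", h2 = "B")
  cl <- cluster_intron_classes(recs, 45, group_map = gm)
  expect_false(cl$classes$conserved[1])   # one group, few members
  expect_true(cl$classes$conserved[2])    # spans two groups
})

test_that("Dollo places trivial gains on root or terminal branches", {
  tree <- ape::read.tree(text = "((a,b),(c,d));")
  ntip <- 4
  all_present <- matrix(TRUE, 4, 1, dimnames = list(letters[1:4], "class1"))
  ev <- infer_events(tree, all_present, "dollo")
  expect_equal(ev$per_class[[1]]$gain_node, ntip + 1L)
  expect_length(ev$per_class[[1]]$loss_nodes, 0)
  expect_equal(ev$total_events, 1L)
  solo <- matrix(c(TRUE, FALSE, FALSE, FALSE), 4, 1,
                 dimnames = list(letters[1:4], "class1"))
  ev2 <- infer_events(tree, solo, "dollo")
  expect_equal(ev2$per_class[[1]]$gain_node,
               which(tree$tip.label == "a"))
  expect_equal(ev2$total_events, 1L)
  expect_error(infer_events(tree, matrix(TRUE, 1, 1,
                                         dimnames = list("zz", "c1")),
                            "dollo"), "differ")
})

test_that("Dollo losses equal exhaustive single-gain minimization", {
  set.seed(16)
  for (rep in 1:8) {
    ntips <- sample(4:6, 1)
    tree <- ape::rtree(ntips)
    tree$tip.label <- letters[seq_len(ntips)]
    have <- setNames(sample(c(TRUE, FALSE), ntips, replace = TRUE),
                     tree$tip.label)
    if (!any(have)) have[1] <- TRUE
    pres <- matrix(have, ncol = 1, dimnames = list(names(have), "c1"))
    got <- infer_events(tree, pres, "dollo")
    want <- oracle_dollo(tree, have)
    expect_equal(length(got$per_class[[1]]$loss_nodes), want$losses)
    expect_setequal(got$per_class[[1]]$loss_nodes, want$loss_nodes)
  }
})

test_that("Dollo never needs fewer events than unconstrained Fitch", {
  set.seed(17)
  for (rep in 1:10) {
    ntips <- sample(5:9, 1)
    tree <- ape::rtree(ntips)
    pres <- matrix(sample(c(TRUE, FALSE), ntips * 3, replace = TRUE),
                   ntips, 3, dimnames = list(tree$tip.label,
                                             paste0("c", 1:3)))
    pres[1, colSums(pres) == 0] <- TRUE
    dollo <- infer_events(tree, pres, "dollo")
    fitch <- infer_events(tree, pres, "fitch")
    expect_gte(dollo$total_events, fitch$total_events)
  }
})

test_that("the planted gain/loss history is recovered exactly", {
  sim <- ref_sim()
  tr <- sim$truth
  recs <- extract_introns_all(ref_models()[tr$family_genes])
  recs <- project_to_alignment(recs, tr$true_alignment)
  cl <- cluster_intron_classes(recs, 45)
  expect_equal(nrow(cl$classes), ncol(tr$presence))
  pres <- presence_matrix(cl$members, tr$family_genes)
  expect_equal(pres[rownames(tr$presence), ], tr$presence)
  ev <- infer_events(tr$tree, pres, "dollo")
  ih <- tr$intron_history
  for (i in seq_len(nrow(ih))) {
    expect_equal(ev$per_class[[i]]$gain_node, ih$gain_node[i])
    expect_setequal(ev$per_class[[i]]$loss_nodes, ih$loss_nodes[[i]])
  }
  # ancestral classes are the ones whose gain maps to the root
  ntip <- length(tr$tree$tip.label)
  anc <- vapply(ev$per_class, function(x) x$gain_node == ntip + 1L, TRUE)
  expect_equal(which(anc), which(ih$gain_node == ntip + 1L))
})

test_that("window sensitivity: 40 vs 45 residues on the reference family", {
  sim <- ref_sim()
  tr <- sim$truth
  recs <- project_to_alignment(
    extract_introns_all(ref_models()[tr$family_genes]), tr$true_alignment)
  n45 <- nrow(cluster_intron_classes(recs, 45)$classes)
  n40 <- nrow(cluster_intron_classes(recs, 40)$classes)
  expect_gte(n40, n45)   # a tighter window can only split classes
})

test_that("census reproduces direct recounts and handles empties", {
  empty <- intron_census(data.frame(gene_id = character(0),
                                    phase = integer(0)), character(0))
  expect_equal(empty$total_introns, 0L)
  expect_equal(unname(empty$genes_by_intron_count), c(0L, 0L, 0L))
  sim <- ref_sim()
  recs <- extract_introns_all(ref_models()[sim$truth$family_genes])
  cen <- intron_census(recs, sim$truth$family_genes)
  expect_equal(cen$total_introns, nrow(recs))
  expect_equal(sum(cen$phase_hist), cen$total_introns)
  expect_equal(unname(cen$genes_by_intron_count["0"]),
               sum(!sim$truth$family_genes %in% recs$gene_id))
  expect_equal(cen$length_min, min(recs$length_bp))
  expect_error(intron_census(recs, character(0)), "unknown")
})
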