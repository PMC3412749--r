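# Distances, neighbour-joining, bootstrap, parsimony, group assignment.

test_that("p-distances count mismatches over pairwise-complete sites", {
  aln <- protein_alignment(c(a = "AAAA", b = "AAAT", c = "AAAA"))
  d <- pairwise_distances(aln)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))
  # gapped sites excluded pairwise
  aln2 <- protein_alignment(c(a = "A-AA", b = "AAAT", c = "AAAA"))
  expect_equal(pairwise_distances(aln2)["a", "b"], 1 / 3)
  # zero comparable sites is fatal by default
  aln3 <- protein_alignment(c(a = "AA--", b = "--TT", c = "AATT"))
  expect_error(pairwise_distances(aln3), "comparable")
})

test_that("distances match a per-pair recount on random gapped rows", {
  set.seed(12)
  n <- 20; L <- 60
  rows <- vapply(seq_len(n), function(i) {
    ch <- strsplit(random_aa_string(L), "")[[1]]
    ch[runif(L) < 0.15] <- "-"
    paste(ch, collapse = "")
  }, "")
  names(rows) <- paste0("s", seq_len(n))
  aln <- protein_alignment(rows)
  d <- pairwise_distances(aln)
  dd <- pairwise_distances(aln, "dayhoff_corrected")
  m <- lapply(rows, function(r) strsplit(r, "")[[1]])
  for (i in 1:4) for (j in (i + 1):5) {
    a <- m[[i]]; b <- m[[j]]
    ok <- a != "-" & b != "-"
    p <- sum(a[ok] != b[ok]) / sum(ok)
    expect_equal(d[i, j], p)
    arg <- 1 - p - 0.2 * p^2
    expect_equal(dd[i, j], if (arg > 0) -log(arg) else p)
  }
})

test_that("three-taxon NJ reproduces the closed-form pendant lengths", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- build_nj(d)
  pend <- setNames(tree$edge.length[tree$edge[, 2] <= 3],
                   tree$tip.label[tree$edge[tree$edge[, 2] <= 3, 2]])
  expect_equal(pend[["A"]], 0.5)
  expect_equal(pend[["B"]], 1.5)
  expect_equal(pend[["C"]], 2.5)
  expect_error(build_nj(d[1:2, 1:2]), ">= 3")
})

test_that("NJ recovers additive trees exactly, taxon order notwithstanding", {
  set.seed(13)
  for (rep in 1:5) {
    tr <- ape::rtree(6)
    tr$edge.length <- runif(nrow(tr$edge), 0.2, 1)
    d <- ape::cophenetic.phylo(tr)
    nj1 <- build_nj(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), nj1), 0, ignore_attr = TRUE)
    expect_equal(max(abs(ape::cophenetic.phylo(nj1)[rownames(d), colnames(d)]
                         - d)), 0, tolerance = 1e-9)
    perm <- sample(rownames(d))
    nj2 <- build_nj(d[perm, perm])
    expect_equal(ape::dist.topo(nj1, nj2), 0, ignore_attr = TRUE)
  }
})

test_that("a perfectly informative alignment gets support 100", {
  # every column supports the split ab | cd
  rows <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAA",
            c = "TTTTTTTTTT", d = "TTTTTTTTTT")
  bt <- bootstrap_nj(protein_alignment(rows), n_reps = 50, seed = 3)
  supp <- attr(bt, "support")
  expect_equal(max(supp[-1]), 100)
  bt2 <- bootstrap_nj(protein_alignment(rows), n_reps = 50, seed = 3)
  expect_identical(attr(bt2, "support"), supp)
  expect_error(bootstrap_nj(protein_alignment(rows), n_reps = 0), "n_reps")
})

test_that("supports do not depend on leaf input order", {
  sim <- ref_sim()
  aln <- sim$truth$true_alignment
  perm <- protein_alignment(sample(aln$seqs))
  b1 <- bootstrap_nj(aln, n_reps = 40, seed = 5)
  b2 <- bootstrap_nj(perm, n_reps = 40, seed = 5)
  # same bipartitions with the same supports
  key <- function(tr) {
    supp <- attr(tr, "support")
    ntip <- length(tr$tip.label)
    parts <- lapply((ntip + 2):(ntip + tr$Nnode), function(nd)
      paste(sort(ugtfam:::descendant_leaves(tr, nd)), collapse = ","))
    setNames(supp[-1], unlist(parts))
  }
  k1 <- key(b1); k2 <- key(b2)
  shared <- intersect(names(k1), names(k2))
  expect_gt(length(shared), 0)
  expect_equal(k1[shared], k2[shared])
})

test_that("deep simulated clades are recovered with high support", {
  sim <- ref_sim()
  bt <- ref_boot()
  supp <- attr(bt, "support")
  ntip <- length(sim$truth$tree$tip.label)
  kids <- sim$truth$tree$edge[sim$truth$tree$edge[, 1] == ntip + 1, 2]
  for (kk in kids[kids > ntip]) {
    tips <- ape::extract.clade(sim$truth$tree, kk)$tip.label
    expect_true(ape::is.monophyletic(bt, tips))
    expect_gt(supp[ape::getMRCA(bt, tips) - ntip], 85)
  }
})

test_that("parsimony score handles invariant, single-split and gap columns", {
  tree <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(parsimony_score(tree, protein_alignment(
    c(a = "AAA", b = "AAA", c = "AAA", d = "AAA"))), 0L)
  expect_equal(parsimony_score(tree, protein_alignment(
    c(a = "A", b = "A", c = "T", d = "T"))), 1L)
  # gap treated as missing: column still needs only one change
  expect_equal(parsimony_score(tree, protein_alignment(
    c(a = "A", b = "-", c = "T", d = "T"))), 1L)
  expect_error(parsimony_score(tree, protein_alignment(
    c(a = "A", b = "A", c = "T", x = "T"))), "differ")
})

test_that("Fitch equals exhaustive minimization on small trees", {
  set.seed(14)
  for (rep in 1:6) {
    ntips <- sample(4:6, 1)
    tree <- ape::rtree(ntips)
    tree$tip.label <- letters[seq_len(ntips)]
    L <- 8
    rows <- vapply(seq_len(ntips), function(i)
      paste(sample(c("A", "C", "D", "E", "-"), L, replace = TRUE,
                   prob = c(.25, .25, .2, .2, .1)), collapse = ""), "")
    names(rows) <- tree$tip.label
    aln <- protein_alignment(rows)
    got <- parsimony_score(tree, aln)
    m <- as.matrix(aln)
    want <- 0L
    for (col in seq_len(L)) {
      st <- m[, col]
      st[st == "-"] <- NA
      want <- want + oracle_parsimony_column(tree, setNames(st, rownames(m)))
    }
    expect_equal(got, want)
  }
})

test_that("parsimony score agrees with an independent implementation", {
  sim <- ref_sim()
  aln <- sim$truth$true_alignment
  # gap-free columns only, so both tools see identical data
  m <- as.matrix(aln)
  keep <- colSums(m == "-") == 0
  aln2 <- protein_alignment(apply(m[, keep], 1, paste, collapse = ""))
  tree <- ape::unroot(sim$truth$tree)
  got <- parsimony_score(tree, aln2)
  pd <- phangorn::phyDat(as.matrix(aln2), type = "AA")
  expect_equal(got, as.integer(phangorn::parsimony(tree, pd)))
})

test_that("group labels follow the smallest supported reference clade", {
  # z is a distant outlier: the only clades containing it either lack
  # support (40) or span both reference groups
  tree <- ape::read.tree(
    text = "(((r1:1,x:1)95:1,(r2:1,y:1)95:1)40:1,z:6);")
  refs <- data.frame(leaf_id = c("r1", "r2"), group = c("A", "B"))
  got <- assign_groups(tree, refs, support_threshold = 85)
  expect_equal(got[["x"]], "A")
  expect_equal(got[["y"]], "B")
  expect_equal(got[["z"]], "unassigned")
  expect_error(assign_groups(tree, data.frame(leaf_id = "zz", group = "C")),
               "absent")
})

test_that("simulated clade labels are recovered at supported nodes", {
  sim <- ref_sim()
  bt <- ref_boot()
  tr <- sim$truth
  sp <- split(names(tr$groups), tr$groups)
  refs <- data.frame(leaf_id = vapply(sp, `[`, "", 1), group = names(sp))
  got <- assign_groups(bt, refs, support_threshold = 85)
  assigned <- got[got != "unassigned"]
  expect_true(all(assigned == tr$groups[names(assigned)]))
  # clades that are monophyletic with support >= 85 must be fully labelled
  supp <- attr(bt, "support")
  ntip <- length(bt$tip.label)
  for (g in names(sp)) {
    tips <- sp[[g]]
    if (length(tips) < 2) next
    if (ape::is.monophyletic(bt, tips) &&
        !is.na(supp[ape::getMRCA(bt, tips) - ntip]) &&
        supp[ape::getMRCA(bt, tips) - ntip] >= 85)
      expect_true(all(got[tips] == g))
  }
})
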