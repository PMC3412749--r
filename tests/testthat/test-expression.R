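# EST mapping, expression summaries, clustering and delta-CT.

test_that("exact substrings map with identity 1 and random ESTs do not map", {
  set.seed(18)
  cds <- c(gA = paste(sample(c("A", "C", "G", "T"), 900, replace = TRUE),
                      collapse = ""),
           gB = paste(sample(c("A", "C", "G", "T"), 900, replace = TRUE),
                      collapse = ""))
  ests <- data.frame(est_id = c("e1", "e2"),
                     sequence = c(substr(cds[["gA"]], 101, 400),
                                  paste(sample(c("A", "C", "G", "T"), 300,
                                               replace = TRUE),
                                        collapse = "")),
                     tissue = "FL")
  res <- map_ests(ests, cds)
  expect_equal(res$assignments$gene_id[1], "gA")
  expect_equal(res$assignments$identity[1], 1.0)
  expect_equal(res$assignments$matched_length[1], 300L)
  expect_true(is.na(res$assignments$gene_id[2]))
  expect_equal(res$n_unmapped, 1L)
  expect_error(map_ests(ests, cds, k = 5), "k must be")
  expect_error(map_ests(ests, character(0)), "empty")
})

test_that("an EST matching two genes equally is discarded as a tie", {
  set.seed(19)
  shared <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                  collapse = "")
  cds <- c(g1 = paste0(shared,
                       paste(sample(c("A", "C", "G", "T"), 300,
                                    replace = TRUE), collapse = "")),
           g2 = paste0(shared,
                       paste(sample(c("A", "C", "G", "T"), 300,
                                    replace = TRUE), collapse = "")))
  ests <- data.frame(est_id = "e1", sequence = substr(shared, 1, 250),
                     tissue = "FL")
  res <- map_ests(ests, cds)
  expect_equal(res$discarded_ties, 1L)
  expect_true(is.na(res$assignments$gene_id[1]))
  expect_equal(sum(res$counts$values), 0L)
})

test_that("EST accounting always balances and recovery tracks the truth", {
  tr <- ref_sim()$truth
  ests <- simulate_ests(tr, n_ests = 1200, error_rate = 0.01, seed = 21)
  res <- map_ests(ests, tr$cds, tissues = colnames(tr$expression_weights))
  expect_equal(sum(res$counts$values) + res$n_unmapped + res$discarded_ties,
               nrow(ests))
  planted <- rowSums(attr(ests, "sampled_counts"))
  got <- rowSums(res$counts$values)
  n <- nrow(ests)
  p <- planted / n
  bound <- pmax(3 * sqrt(n * p * (1 - p)), 1)
  expect_true(all(abs(got - planted) <= bound))
  expect_setequal(names(got)[got > 0], names(planted)[planted > 0])
})

test_that("summary arithmetic matches hand-checked ratios in both modes", {
  # 85 expressed of 137 genes, 325 ESTs; one group with 91 ESTs over 13
  # expressed members; truncation vs rounding conventions
  expect_equal(ratio_stat(325, 85, percent = FALSE), 3.82)
  expect_equal(ratio_stat(85, 137), 62.04)
  expect_equal(ratio_stat(60, 137, mode = "truncate"), 43.79)
  expect_equal(ratio_stat(60, 137, mode = "round"), 43.80)
  expect_equal(ratio_stat(91, 13, percent = FALSE), 7.00)
  expect_equal(ratio_stat(69, 15, percent = FALSE), 4.60)
  expect_equal(ratio_stat(55, 137, mode = "truncate"), 40.14)
})

test_that("expression_summary recomputes its own percentages", {
  set.seed(20)
  m <- matrix(rpois(40, 2), 10, 4,
              dimnames = list(paste0("g", 1:10), c("FL", "GE", "TC", "ST")))
  m[8:10, ] <- 0L
  tab <- expression_table(m, "est_counts")
  gm <- setNames(rep(c("A", "B"), each = 5), paste0("g", 1:10))
  s <- expression_summary(tab, gm)
  expect_equal(s$n_expressed, 7L)
  expect_equal(s$pct_expressed, round_half_up(100 * 7 / 10))
  expect_equal(s$mean_per_expressed, round_half_up(sum(m) / 7))
  for (i in seq_len(nrow(s$per_group))) {
    g <- s$per_group[i, ]
    expect_equal(g$mean_per_expressed,
                 if (g$n_expressed) round_half_up(g$total_ests / g$n_expressed)
                 else 0)
  }
  expect_equal(sum(s$per_tissue$total_ests), sum(m))
  # empty table
  s0 <- expression_summary(expression_table(
    matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("FL", "TC"))),
    "est_counts"))
  expect_equal(s0$n_expressed, 0L)
  expect_equal(s0$pct_expressed, 0)
})

test_that("correlation clustering handles exact, opposite and flat rows", {
  v <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8),    # r = 1
             g3 = c(4, 3, 2, 1),                        # r = -1 to g1
             g4 = c(5, 5, 5, 5))                        # flat
  colnames(v) <- paste0("t", 1:4)
  tab <- expression_table(v, "log2_intensity")
  res <- cluster_expression(tab)
  expect_equal(res$distance["g1", "g2"], 0)
  expect_equal(res$distance["g1", "g3"], 2)
  expect_equal(res$distance["g4", "g1"], 2)
  expect_equal(res$flagged_constant, "g4")
  # identical rows merge first at height 0
  expect_equal(sort(res$hclust$merge[1, ]), c(-2, -1))
  expect_equal(res$hclust$height[1], 0)
})

test_that("average-linkage merges equal the brute-force oracle on 6 rows", {
  set.seed(22)
  for (rep in 1:4) {
    v <- matrix(rnorm(36), 6, 6,
                dimnames = list(paste0("g", 1:6), paste0("t", 1:6)))
    tab <- expression_table(v, "log2_intensity")
    res <- cluster_expression(tab)
    o <- oracle_average_linkage(res$distance)
    hc <- res$hclust
    members_of <- function(k) {
      rec <- function(x) if (x < 0) -x else unlist(lapply(hc$merge[x, ], rec))
      sort(rec(k))
    }
    for (k in seq_len(nrow(hc$merge))) {
      expect_equal(members_of(k), o[[k]]$members)
      expect_equal(hc$height[k], o[[k]]$height)
    }
  }
})

test_that("canonical leaf order is invariant to row permutation", {
  set.seed(23)
  v <- matrix(rnorm(40), 8, 5,
              dimnames = list(paste0("g", sample(1:8)), paste0("t", 1:5)))
  tab <- expression_table(v, "log2_intensity")
  o1 <- cluster_expression(tab)$order
  perm <- sample(rownames(v))
  o2 <- cluster_expression(expression_table(v[perm, ], "log2_intensity"))$order
  expect_identical(o1, o2)
})

test_that("delta-CT closed forms and guards", {
  base <- expand.grid(bio_rep = 1:3, tech_rep = 1:2)
  ct <- rbind(
    data.frame(gene = "ref", tissue = "FL", base, ct = 20),
    data.frame(gene = "gY", tissue = "FL", base, ct = 20),
    data.frame(gene = "gZ", tissue = "FL", base, ct = 21))
  res <- delta_ct(ct, "ref")
  expect_equal(res$abundance[res$gene == "gY"], 1.0)
  expect_equal(res$se[res$gene == "gY"], 0)
  expect_equal(res$abundance[res$gene == "gZ"], 0.5)
  # missing reference bio_rep is dropped with a warning
  ct2 <- ct[!(ct$gene == "ref" & ct$bio_rep == 3), ]
  w <- capture_warnings(res2 <- delta_ct(ct2, "ref"))
  expect_length(w, 2)                      # one per affected target gene
  expect_match(w, "dropped", all = TRUE)
  expect_equal(unique(res2$n_bio), 2)
  expect_error(delta_ct(ct[ct$gene != "ref", ], "ref"), "absent")
})

test_that("delta-CT recovers simulated abundances within tolerance", {
  tr <- ref_sim()$truth
  n_bio <- 3; n_tech <- 2; sd_ct <- 0.1
  ct <- simulate_qpcr(tr, n_bio = n_bio, n_tech = n_tech, sd_ct = sd_ct,
                      seed = 25)
  res <- delta_ct(ct, "ETIF5A")
  qt <- tr$qpcr_truth
  # tolerance: 3x the true sampling SE implied by the known CT noise
  # (the SE estimated from 3 replicates is itself noisy)
  for (i in seq_len(nrow(res))) {
    tru <- qt[res$gene[i], res$tissue[i]]
    true_se <- log(2) * tru * sd_ct * sqrt(2 / (n_tech * n_bio))
    tol <- 3 * max(res$se[i], true_se)
    expect_lt(abs(res$abundance[i] - tru), tol)
  }
})
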