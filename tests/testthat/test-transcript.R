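test_that("FPKM matches its closed form and an independent per-cell oracle", {
  # count 100, length 1000 b, libsize 1e6 -> FPKM 100
  ex <- fpkm(matrix(100, 1, 1), lengths = 1000, lib_sizes = 1e6)
  expect_equal(unname(ex$fpkm[1, 1]), 100)
  expect_equal(unname(fpkm(matrix(0, 1, 1), 1000, 1e6)$fpkm[1, 1]), 0)

  set.seed(21)
  counts <- matrix(rpois(60, 40), 10, 6)
  lens <- sample(200:3000, 10)
  ex <- fpkm(counts, lens)
  libs <- colSums(counts)
  max_rel <- 0
  for (g in 1:10) for (j in 1:6) {
    oracle <- counts[g, j] * 1e9 / (lens[g] * libs[j])
    if (oracle > 0) {
      max_rel <- max(max_rel, abs(ex$fpkm[g, j] - oracle) / oracle)
    } else {
      expect_identical(unname(ex$fpkm[g, j]), 0)
    }
  }
  expect_lt(max_rel, 1e-12)

  # duplicating reads and libsize jointly leaves FPKM unchanged
  ex2 <- fpkm(2 * counts, lens, lib_sizes = 2 * libs)
  expect_equal(ex2$fpkm, ex$fpkm)

  expect_error(fpkm(counts, lens, lib_sizes = rep(0, 6)), "library size")
  expect_error(fpkm(matrix(-1, 1, 1), 100), "nonnegative")
})

test_that("row-wise Welch t equals stats::t.test gene by gene", {
  set.seed(33)
  x <- matrix(rnorm(25 * 6), 25, 6)
  w <- teaAroma:::.row_welch(x, 1:3, 4:6)
  for (g in 1:25) {
    tt <- t.test(x[g, 1:3], x[g, 4:6])
    expect_equal(w$statistic[g], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(w$p[g], tt$p.value, tolerance = 1e-12)
  }
})

test_that("DEG calling flags planted effects and nothing on flat data", {
  cs <- simulate_counts(seed = 19L)
  ex <- fpkm(cs$counts, cs$lengths)
  deg <- deg_call(ex, cs$condition, "winter", "spring")
  expect_true(all(deg$adj_p >= deg$p_value - 1e-15))
  hit3 <- deg$direction[match(cs$truth$gene_id[cs$truth$log2_fc == 3],
                              deg$gene_id)]
  expect_gt(mean(hit3 == "up"), 0.8)
  dn <- deg$direction[match(cs$truth$gene_id[cs$truth$log2_fc < 0],
                            deg$gene_id)]
  expect_false("up" %in% dn)
  # direction is consistent with sign and thresholds
  up <- deg[deg$direction == "up", ]
  expect_true(all(up$log2_fc >= 1 & up$adj_p <= 0.05))

  # an all-equal matrix yields zero DEGs
  flat <- fpkm(matrix(5L, 100, 6), lengths = rep(1000, 100))
  dflat <- deg_call(flat, rep(c("winter", "spring"), each = 3),
                    "winter", "spring")
  expect_true(all(dflat$direction == "ns"))
  expect_true(all(dflat$p_value == 1))
})

test_that("hypergeometric enrichment equals combinatorial enumeration", {
  # worked instance: universe 10, set 5, draw 5, overlap 5 -> 1/252
  uni <- paste0("g", 1:10)
  res <- hypergeom_enrich(uni[1:5], uni, list(s = uni[1:5]))
  expect_equal(res$p_value, 1 / 252)
  # overlap 0 -> p = 1
  res0 <- hypergeom_enrich(uni[1:5], uni, list(s = uni[6:10]))
  expect_equal(res0$p_value, 1)

  set.seed(55)
  for (i in 1:50) {
    N <- sample(5:30, 1L)
    uni <- paste0("g", seq_len(N))
    K <- sample(1:N, 1L)
    n <- sample(1:N, 1L)
    set <- sample(uni, K)
    degs <- sample(uni, n)
    res <- hypergeom_enrich(degs, uni, list(s = set))
    k <- length(intersect(set, degs))
    expect_equal(res$p_value, hyper_exact_enum(N, K, n, k),
                 tolerance = 1e-12)
    expect_lte(res$overlap, min(res$set_size, res$draw_size))
  }

  expect_error(hypergeom_enrich("a", character(), list()), "empty universe")
  expect_error(hypergeom_enrich("zz", uni, list(s = uni)), "subset")
  # sets empty after intersection are skipped with a note
  res <- hypergeom_enrich(uni[1], uni, list(good = uni[1:3],
                                            gone = c("x", "y")))
  expect_identical(res$set_id, "good")
  expect_identical(attr(res, "skipped"), "gone")
})

test_that("BH adjustment is invariant to input order", {
  set.seed(66)
  p <- runif(500)^2
  adj <- p.adjust(p, method = "BH")
  o <- sample(500)
  adj_perm <- p.adjust(p[o], method = "BH")
  expect_equal(adj_perm, adj[o])
  for (thr in c(0.01, 0.05, 0.2)) {
    expect_identical(which(adj_perm <= thr), which(adj[o] <= thr))
  }
})

test_that("trend concordance compares fold-change signs", {
  expect_false(concordance(c(a = 2), c(a = -1))$genes$concordant)
  res <- concordance(c(a = 1.2, b = -0.8, c = 0.5),
                     c(a = 2.0, b = -0.1, c = -0.4))
  expect_equal(res$n_concordant, 2L)
  expect_equal(res$fraction_concordant, 2 / 3)
  # zero fold changes are excluded, not counted either way
  res0 <- concordance(c(a = 0, b = 1), c(a = 1, b = 2))
  expect_identical(res0$excluded, "a")
  expect_equal(res0$n_compared, 1L)
  expect_error(concordance(c(a = 1), c(b = 1)), "shared")
})

test_that("zero-noise fixture gives full six-gene qPCR concordance", {
  cs <- simulate_counts(seed = 23L, exact = TRUE)
  ex <- fpkm(cs$counts, cs$lengths)
  deg <- deg_call(ex, cs$condition, "winter", "spring")
  planted <- cs$truth[cs$truth$log2_fc != 0, ]
  genes <- c(head(planted$gene_id[planted$log2_fc > 0], 3L),
             head(planted$gene_id[planted$log2_fc < 0], 3L))
  fc <- 2^setNames(planted$log2_fc[match(genes, planted$gene_id)], genes)
  ct <- simulate_ct(fc, reference_gene = "actin", seed = 23L, noise_sd = 0)
  rel <- ddct(ct$ct, "actin", "spring")
  winter <- rel[rel$condition == "winter", ]
  qfc <- setNames(winter$log2_fc, winter$gene_id)
  rfc <- setNames(deg$log2_fc, deg$gene_id)
  res <- concordance(rfc[genes], qfc)
  expect_equal(res$n_concordant, 6L)
  expect_equal(res$fraction_concordant, 1)
})
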