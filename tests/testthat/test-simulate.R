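test_that("GC-MS generator inverts the quantification formula exactly", {
  # one compound, C_true = 500 ng/g, m = 2 g, m_s = 1000 ng, S_s = 1e6:
  # the emitted area must be C * m * S_s / m_s = 1e6
  lib <- compound_library(tiny_library_df())
  groups <- list(G1 = data.frame(compound_id = "linalool",
                                 concentration = 500, cv = 0))
  sim <- simulate_gcms(groups, n_replicates = 2L, seed = 1L, library = lib,
                       spec = quant_spec(2, 1000), is_area = 1e6)
  peak <- sim$peaks[!sim$peaks$is_internal_standard, ]
  expect_equal(unique(peak$peak_area), 1e6)
  prof <- quantify(sim$peaks, sim$spec)
  expect_equal(unique(prof$concentration), 500)
})

test_that("replicate noise follows the planted CV", {
  # CV = 0.1, n = 6: sample CV of recovered concentrations falls in the
  # Monte-Carlo envelope [0.03, 0.25] of the lognormal noise model
  lib <- compound_library(tiny_library_df())
  groups <- list(G1 = data.frame(compound_id = "linalool",
                                 concentration = 500, cv = 0.1))
  sim <- simulate_gcms(groups, n_replicates = 6L, seed = 42L, library = lib)
  prof <- quantify(sim$peaks, sim$spec)
  cv_hat <- sd(prof$concentration) / mean(prof$concentration)
  expect_gte(cv_hat, 0.03)
  expect_lte(cv_hat, 0.25)
})

test_that("a reference RI outside ladder coverage is an error", {
  lib <- compound_library(data.frame(
    compound_id = "x", display_name = "X", reference_ri = 1725,
    odor_threshold = 1, odor_type = "floral", chemical_class = "other"))
  short_ladder <- alkane_ladder(9:15, 4.2 + 2.4 * (0:6))
  groups <- list(G1 = data.frame(compound_id = "x", concentration = 10,
                                 cv = 0))
  expect_error(simulate_gcms(groups, seed = 1L, library = lib,
                             ladder = short_ladder), "outside ladder")
})

test_that("generators are deterministic in the seed", {
  s1 <- simulate_gcms(seed = 5L)
  s2 <- simulate_gcms(seed = 5L)
  expect_identical(as.data.frame(s1$peaks), as.data.frame(s2$peaks))
  c1 <- simulate_counts(seed = 5L)
  c2 <- simulate_counts(seed = 5L)
  expect_identical(c1$counts, c2$counts)
  t1 <- simulate_ct(c(a = 2), seed = 5L)
  t2 <- simulate_ct(c(a = 2), seed = 5L)
  expect_identical(t1$ct$ct, t2$ct$ct)
  expect_false(identical(simulate_gcms(seed = 6L)$peaks$peak_area,
                         s1$peaks$peak_area))
})

test_that("default group specs hit the planted totals and terpene indices", {
  gs <- default_group_specs()
  totals <- vapply(gs, function(d) sum(d$concentration), numeric(1))
  expect_equal(unname(totals[c("SDT", "WDT", "SFL", "WFL")]),
               c(16080, 22930, 1622.20, 1120.32))
  ti <- vapply(gs, function(d) {
    l <- d$concentration[d$compound_id == "linalool"]
    g <- d$concentration[d$compound_id == "geraniol"]
    l / (l + g)
  }, numeric(1))
  expect_equal(unname(ti[c("SDT", "WDT", "SFL", "WFL")]),
               c(0.72, 0.87, 0.31, 0.00), tolerance = 1e-12)
})

test_that("count generator plants effects and validates its inputs", {
  cs <- simulate_counts(n_genes = 200L, n_pathways = 2L,
                        planted_de = data.frame(gene_id = "g0005",
                                                log2_fc = 3,
                                                base_mean = 500),
                        seed = 3L)
  expect_true(all(cs$counts >= 0))
  expect_true(all(cs$counts == round(cs$counts)))
  expect_identical(dim(cs$counts), c(200L, 6L))
  expect_equal(cs$truth$log2_fc[cs$truth$gene_id == "g0005"], 3)
  expect_equal(cs$truth$base_mean[cs$truth$gene_id == "g0005"], 500)
  expect_error(simulate_counts(n_replicates = 1L), "at least 2")
  expect_error(simulate_counts(n_genes = 50L, n_pathways = 1L,
                               pathway_size = 10L,
                               planted_de = data.frame(gene_id = "g9999",
                                                       log2_fc = 2)),
               "not in matrix")
})

test_that("with no planted effects and no overdispersion the condition means agree", {
  cs <- simulate_counts(n_genes = 500L,
                        planted_de = data.frame(gene_id = character(),
                                                log2_fc = numeric()),
                        n_replicates = 50L, seed = 9L, dispersion = 0)
  m_ref <- rowMeans(cs$counts[, cs$condition == "spring"])
  m_test <- rowMeans(cs$counts[, cs$condition == "winter"])
  # Poisson SE of the per-gene mean difference
  se <- sqrt(2 * cs$truth$base_mean / 50)
  expect_gt(mean(abs(m_ref - m_test) < 4 * se), 0.99)
})

test_that("Ct generator encodes fold changes as cycle shifts", {
  sim <- simulate_ct(c(gene_a = 2, gene_b = 1), reference_gene = "actin",
                     seed = 1L, noise_sd = 0)
  tab <- sim$ct
  dct <- function(g, cond) {
    sel <- tab$gene_id == g & tab$condition == cond
    ref <- tab$gene_id == "actin" & tab$condition == cond
    mean(tab$ct[sel]) - mean(tab$ct[ref])
  }
  # true fold change 2 -> ddCt = -1 exactly; fold change 1 -> 0
  expect_equal(dct("gene_a", "winter") - dct("gene_a", "spring"), -1)
  expect_equal(dct("gene_b", "winter") - dct("gene_b", "spring"), 0)
  expect_error(simulate_ct(c(a = 2), reference_gene = ""), "reference")
  expect_error(simulate_ct(c(a = 2, actin = 3)), "fold change 1")
})

test_that("fixtures written to disk are sufficient to rerun every stage", {
  dir <- withr::local_tempdir()
  study <- simulate_study(11L)
  paths <- write_fixtures(study, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "peaks.tsv", "ladder.tsv", "library.tsv", "counts.tsv", "lengths.tsv",
    "sets.tsv", "ct.tsv", "ground_truth_gcms.tsv", "manifest.tsv")))))
  pt <- read_peak_table(file.path(dir, "peaks.tsv"))
  expect_equal(nrow(pt), nrow(study$gcms$peaks))
  truth <- read_tsv_table(file.path(dir, "ground_truth_gcms.tsv"),
                          c("group_label", "compound_id",
                            "true_concentration"))
  expect_equal(sum(truth$true_concentration),
               sum(study$gcms$truth$true_concentration), tolerance = 1e-9)
})
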