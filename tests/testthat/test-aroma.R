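test_that("OAV boundaries, class rule and linearity", {
  lib <- compound_library(tiny_library_df())
  prof <- profile_from_conc(list(G = list(
    linalool = c(0.22, 0.22, 0.22),   # exactly at threshold
    geraniol = c(0, 0, 0),            # absent compound
    indole = c(80, 120, 100))))
  ov <- oav(prof, lib)
  lin <- ov[ov$compound_id == "linalool", ]
  expect_equal(lin$mean_oav, 1)
  expect_identical(lin$contribution, "significant")
  ger <- ov[ov$compound_id == "geraniol", ]
  expect_equal(ger$mean_oav, 0)
  expect_identical(ger$contribution, "minor")
  ind <- ov[ov$compound_id == "indole", ]
  expect_equal(ind$mean_oav, 100 / 40)
  expect_equal(ind$sd_oav, sd(c(80, 120, 100) / 40))
  # linear in concentration: scaling every concentration by k scales OAV by k
  prof_k <- prof
  prof_k$concentration <- prof_k$concentration * 7
  ov_k <- oav(prof_k, lib)
  expect_equal(ov_k$mean_oav, ov$mean_oav * 7)
})

test_that("compounds without thresholds are skipped and listed, never zeroed", {
  lib <- tiny_library_df()
  lib$odor_threshold[lib$compound_id == "geraniol"] <- NA
  lib <- compound_library(lib)
  prof <- profile_from_conc(list(G = list(linalool = c(1, 1),
                                          geraniol = c(5, 5),
                                          mystery = c(9, 9))))
  ov <- oav(prof, lib)
  expect_false("geraniol" %in% ov$compound_id)
  expect_setequal(attr(ov, "skipped"), c("geraniol", "mystery"))
})

test_that("forward OAV reproduces the published key-compound means", {
  # circular consistency check: concentrations back-derived as
  # OAV x threshold, pushed through oav(), must return the printed means
  ref <- key_oav_reference()
  lib <- default_compound_library()
  conc <- list(
    SDT = as.list(setNames(ref$oav_sdt * ref$odor_threshold,
                           ref$compound_id)),
    WDT = as.list(setNames(ref$oav_wdt * ref$odor_threshold,
                           ref$compound_id)))
  ov <- oav(profile_from_conc(conc), lib)
  for (g in c("SDT", "WDT")) {
    got <- ov$mean_oav[ov$group_label == g][
      match(ref$compound_id, ov$compound_id[ov$group_label == g])]
    want <- if (g == "SDT") ref$oav_sdt else ref$oav_wdt
    expect_lt(max(abs(got - want) / want), 1e-6)
  }
  # the two marker compounds swap rank between seasons: ionone dominates
  # muurolene in spring, muurolene dominates ionone in winter
  sdt <- setNames(ref$oav_sdt, ref$compound_id)
  wdt <- setNames(ref$oav_wdt, ref$compound_id)
  expect_gt(sdt[["ionone_tb"]], sdt[["muurolene_a"]])
  expect_gt(wdt[["muurolene_a"]], wdt[["ionone_tb"]])
})

test_that("radar coordinates aggregate and transform per dimension", {
  lib <- compound_library(tiny_library_df())
  # single floral compound with OAV 9 -> floral coordinate log10(10) = 1
  prof <- profile_from_conc(list(G = list(linalool = rep(9 * 0.22, 3))))
  rad <- radar(oav(prof, lib))
  expect_equal(rad$coordinate[rad$odor_type == "floral"], 1)
  # dimensions with no compounds sit at the floor
  expect_equal(rad$coordinate[rad$odor_type == "woody"], 0)
  expect_equal(rad$total_oav[rad$odor_type == "woody"], 0)
  # monotone in any constituent OAV
  prof2 <- profile_from_conc(list(G = list(linalool = rep(9 * 0.22, 3),
                                           indole = rep(400, 3))))
  rad2 <- radar(oav(prof2, lib))
  expect_gt(rad2$coordinate[rad2$odor_type == "floral"],
            rad$coordinate[rad$odor_type == "floral"])
})

test_that("winter dry tea shows the planted woody dominance on the radar", {
  sim <- simulate_gcms(groups = zero_noise_specs(), seed = 8L)
  ov <- oav(quantify(sim$peaks, sim$spec), sim$library)
  rad <- radar(ov)
  woody <- setNames(rad$coordinate[rad$odor_type == "woody"],
                    rad$group_label[rad$odor_type == "woody"])
  expect_gt(woody[["WDT"]], woody[["SDT"]])
})

test_that("terpene index properties and boundaries", {
  expect_equal(terpene_index(5, 5), 0.5)
  expect_equal(terpene_index(87, 13), 0.87)
  expect_equal(terpene_index(0, 10), 0)
  expect_equal(terpene_index(10, 0), 1)
  # scale invariance
  for (k in c(0.1, 3, 1e6)) {
    expect_equal(terpene_index(87 * k, 13 * k), 0.87)
  }
  expect_error(terpene_index(0, 0), "undefined")
  expect_error(terpene_index(-1, 2), "nonnegative")
})

test_that("class totals conserve the grand total", {
  lib <- compound_library(tiny_library_df())
  prof <- profile_from_conc(list(G = list(linalool = c(100, 100),
                                          indole = c(50, 50))))
  ct <- class_totals(prof, lib)
  expect_equal(ct$mean_total[ct$chemical_class == "monoterpene"], 100)
  expect_equal(ct$mean_total[ct$chemical_class == "nitrogen_compound"], 50)
  expect_equal(ct$mean_total[ct$chemical_class == "total"], 150)
  # unclassified compounds fall into "other" with a warning
  prof2 <- profile_from_conc(list(G = list(linalool = c(100, 100),
                                           unknown_x = c(10, 10))))
  expect_warning(ct2 <- class_totals(prof2, lib), "other")
  expect_equal(ct2$mean_total[ct2$chemical_class == "other"], 10)
  expect_equal(ct2$mean_total[ct2$chemical_class == "total"], 110)
})

test_that("zero-noise class totals equal the planted sums", {
  sim <- simulate_gcms(groups = zero_noise_specs(), seed = 4L)
  ct <- class_totals(quantify(sim$peaks, sim$spec), sim$library)
  grand <- ct$mean_total[ct$chemical_class == "total"]
  names(grand) <- ct$group_label[ct$chemical_class == "total"]
  truth_tot <- tapply(sim$truth$true_concentration, sim$truth$group_label,
                      sum)
  expect_equal(unname(grand[names(truth_tot)]), as.numeric(truth_tot),
               tolerance = 1e-9)
  # per-group: class sums re-add to the grand total
  for (g in unique(ct$group_label)) {
    sub <- ct[ct$group_label == g, ]
    expect_equal(sum(sub$mean_total[sub$chemical_class != "total"]),
                 sub$mean_total[sub$chemical_class == "total"],
                 tolerance = 1e-9)
  }
})

test_that("group comparison reports t, exact Mann-Whitney and CV%", {
  res <- compare_groups(c(1, 2, 3, 4, 5, 6),
                        rep(c("A", "B"), each = 3))
  expect_equal(res$u_statistic, 0)
  expect_equal(res$u_p, 0.1)  # 2/20 permutations as extreme
  expect_equal(res$cv_percent[1L], 100 * sd(1:3) / 2)
  expect_equal(res$mean_difference, -3)

  same <- compare_groups(c(5, 5, 5, 5), c("A", "A", "B", "B"))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$t_p, 1)
  expect_true(same$degenerate)

  # equal-variance Student's t agrees with stats::t.test
  set.seed(31)
  a <- rnorm(4); b <- rnorm(5, 1)
  res <- compare_groups(c(a, b), rep(c("A", "B"), c(4, 5)))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$t_statistic, unname(tt$statistic))
  expect_equal(res$t_p, tt$p.value)
})

test_that("Mann-Whitney p equals full permutation enumeration (n <= 6)", {
  set.seed(77)
  for (i in 1:40) {
    n1 <- sample(2:6, 1L)
    n2 <- sample(2:6, 1L)
    # continuous draws: no ties, exact test applies
    a <- round(rnorm(n1), 6)
    b <- round(rnorm(n2, 0.5), 6)
    res <- compare_groups(c(a, b), rep(c("A", "B"), c(n1, n2)))
    expect_equal(res$u_p, mw_exact_enum(a, b), tolerance = 1e-12)
  }
})

test_that("a planted two-fold difference is detected at CV 5% with n = 3", {
  set.seed(13)
  hits <- 0L
  n_seeds <- 200L
  for (i in seq_len(n_seeds)) {
    a <- rnorm(3, 100, 5)
    b <- rnorm(3, 200, 10)
    res <- compare_groups(c(a, b), rep(c("A", "B"), each = 3))
    hits <- hits + (res$t_p < 0.05)
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("PCA of volatiles has orthonormal loadings and ordered variance", {
  set.seed(5)
  mat <- matrix(rnorm(8 * 5), 8, 5,
                dimnames = list(NULL, paste0("c", 1:5)))
  pc <- pca_volatiles(mat)
  expect_equal(t(pc$loadings) %*% pc$loadings,
               diag(ncol(pc$loadings)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(pc$variance_fraction) <= 1e-12))
  expect_equal(sum(pc$variance_fraction), 1)

  # two perfectly correlated compounds collapse onto PC1
  m2 <- cbind(a = 1:6, b = 2 * (1:6))
  expect_equal(pca_volatiles(m2)$variance_fraction[1L], 1)

  # constant columns are dropped with a warning
  m3 <- cbind(mat, const = 1)
  expect_warning(pc3 <- pca_volatiles(m3), "constant")
  expect_identical(pc3$dropped, "const")

  # a planted discriminating compound dominates the separating component
  grp <- rep(c(0, 8), each = 4)
  m4 <- matrix(rnorm(8 * 4, sd = 0.3), 8, 4)
  m4 <- cbind(m4, marker = grp + rnorm(8, sd = 0.3))
  colnames(m4) <- paste0("c", 1:5)
  pc4 <- pca_volatiles(m4, scale. = FALSE)
  expect_identical(names(which.max(abs(pc4$loadings[, 1L]))), "c5")
})
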