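# Seeded synthetic-data generators. Every fixture is emitted together with
# its ground truth, so each downstream stage can be scored exactly:
# zero-noise generation composed with the matching analysis stage is the
# identity on the planted values.
#
# Noise models (the minimal field-standard choices): lognormal multiplicative
# noise on peak areas (detector noise), negative-binomial counts
# (overdispersed sequencing), gaussian noise on the Ct scale.

#' Default C9-C21 alkane calibration ladder
#'
#' Retention times follow a mildly convex trend in carbon number, as under
#' a linear oven ramp; coverage is retention index 900-2100.
#'
#' @return An [alkane_ladder()].
#' @export
default_ladder <- function() {
  n <- 9:21
  alkane_ladder(n, 4.2 + 2.35 * (n - 9) + 0.011 * (n - 9)^2)
}

#' Default compound library for seasonal oolong volatiles
#'
#' Forty-one volatiles spanning the chemical classes of a Dancong oolong
#' profile (mono-/sesquiterpenes, alcohols, ketones, aldehydes, esters,
#' nitrogen compounds, olefins, other). The six key compounds carry
#' published odor thresholds in water (ng/g): (E)-nerolidol 10, (Z)-beta-
#' farnesene 87, indole 40, linalool 0.22, trans-beta-ionone 0.01,
#' alpha-muurolene 0.10. Some compounds deliberately lack a threshold or
#' an odor type: their OAV/radar contribution is undefined, not zero.
#'
#' @return A [compound_library()].
#' @export
default_compound_library <- function() {
  rows <- rbind(
    c("linalool",            "Linalool",                      1099, 0.22,  "floral",  "monoterpene"),
    c("geraniol",            "Geraniol",                      1255, 1.10,  "floral",  "monoterpene"),
    c("nerolidol_E",         "(E)-Nerolidol",                 1564, 10.00, "floral",  "sesquiterpene"),
    c("farnesene_Zb",        "(Z)-beta-Farnesene",            1443, 87.00, "floral",  "sesquiterpene"),
    c("indole",              "Indole",                        1290, 40.00, "floral",  "nitrogen_compound"),
    c("ionone_tb",           "trans-beta-Ionone",             1486, 0.01,  "floral",  "ketone"),
    c("muurolene_a",         "alpha-Muurolene",               1499, 0.10,  "woody",   "sesquiterpene"),
    c("limonene_D",          "D-Limonene",                    1030, 34,    "fruity",  "monoterpene"),
    c("ocimene_allo",        "allo-Ocimene",                  1130, 100,   "green",   "monoterpene"),
    c("cyclocitral_b",       "beta-Cyclocitral",              1219, 3,     "green",   "aldehyde"),
    c("bisabolene_Ea",       "(E)-alpha-Bisabolene",          1540, 80,    "woody",   "sesquiterpene"),
    c("hotrienol",           "Hotrienol",                     1105, 110,   "floral",  "alcohol"),
    c("phenylethanol_2",     "2-Phenylethanol",               1116, 1100,  "floral",  "alcohol"),
    c("benzaldehyde",        "Benzaldehyde",                  962,  350,   "fruity",  "aldehyde"),
    c("nonanal",             "Nonanal",                       1110, 1,     "green",   "aldehyde"),
    c("decanal",             "Decanal",                       1206, 2,     "green",   "aldehyde"),
    c("methyl_salicylate",   "Methyl salicylate",             1192, 40,    "green",   "ester"),
    c("jasmone_Z",           "(Z)-Jasmone",                   1380, 33,    "floral",  "ketone"),
    c("jasmin_lactone",      "Jasmin lactone",                1680, 160,   "floral",  "ester"),
    c("hexenyl_hexanoate_Z3","(Z)-3-Hexenyl hexanoate",       1370, 16,    "green",   "ester"),
    c("caryophyllene_b",     "beta-Caryophyllene",            1419, 64,    "woody",   "sesquiterpene"),
    c("humulene_a",          "alpha-Humulene",                1454, 160,   "woody",   "sesquiterpene"),
    c("cadinene_d",          "delta-Cadinene",                1523, NA,    "woody",   "sesquiterpene"),
    c("ocimene_Eb",          "(E)-beta-Ocimene",              1049, 36,    "green",   "monoterpene"),
    c("myrcene",             "Myrcene",                       991,  14,    "green",   "monoterpene"),
    c("linalool_oxide_cf",   "cis-Linalool oxide (furanoid)", 1074, 320,   "floral",  "alcohol"),
    c("linalool_oxide_tf",   "trans-Linalool oxide (furanoid)",1088,320,   "floral",  "alcohol"),
    c("benzyl_alcohol",      "Benzyl alcohol",                1036, 2546,  "floral",  "alcohol"),
    c("phenylacetaldehyde",  "Phenylacetaldehyde",            1045, 4,     "floral",  "aldehyde"),
    c("methyl_jasmonate",    "Methyl jasmonate",              1650, 70,    "floral",  "ester"),
    c("dimethylpyrazine_25", "2,5-Dimethylpyrazine",          917,  800,   "roasted", "nitrogen_compound"),
    c("acetylpyrrole_2",     "2-Acetylpyrrole",               1064, 170000,"roasted", "nitrogen_compound"),
    c("geranylacetone",      "Geranylacetone",                1434, 60,    "floral",  "ketone"),
    c("ionone_a",            "alpha-Ionone",                  1428, 0.4,   "floral",  "ketone"),
    c("dihydroactinidiolide","Dihydroactinidiolide",          1532, NA,    NA,        "other"),
    c("nerol",               "Nerol",                         1228, 49,    "floral",  "monoterpene"),
    c("safranal",            "Safranal",                      1200, 3,     "woody",   "aldehyde"),
    c("naphthalene",         "Naphthalene",                   1180, 440,   "chemical","other"),
    c("longifolene",         "Longifolene",                   1402, NA,    "woody",   "sesquiterpene"),
    c("cubebene_a",          "alpha-Cubebene",                1351, NA,    "woody",   "sesquiterpene"),
    c("dodecene_1",          "1-Dodecene",                    1240, NA,    "chemical","olefin"))
  df <- data.frame(compound_id = rows[, 1L], display_name = rows[, 2L],
                   reference_ri = as.numeric(rows[, 3L]),
                   odor_threshold = as.numeric(rows[, 4L]),
                   odor_type = rows[, 5L], chemical_class = rows[, 6L],
                   stringsAsFactors = FALSE)
  compound_library(df)
}

# Published reference values the default fixture is anchored to: mean OAVs
# of the six key volatiles in spring vs winter dry tea, and the seasonal
# terpene indices. True concentrations are planted as OAV x threshold so
# the forward pipeline reproduces these numbers.
.KEY_OAV <- data.frame(
  compound_id = c("nerolidol_E", "farnesene_Zb", "indole", "linalool",
                  "ionone_tb", "muurolene_a"),
  SDT = c(219.08, 1.25, 75.51, 3887.77, 48204.00, 439.50),
  WDT = c(427.05, 3.07, 136.34, 4616.14, 25580.00, 33902.70),
  cv  = c(0.161, 0.136, 0.119, 0.170, 0.159, 0.10),
  stringsAsFactors = FALSE)

.TI_TARGET <- c(SDT = 0.72, WDT = 0.87, SFL = 0.31, WFL = 0.00)
.TOTAL_TARGET <- c(SDT = 16080, WDT = 22930, SFL = 1622.20, WFL = 1120.32)

#' Published mean OAVs the default fixture is anchored to
#'
#' The six key volatiles' odor thresholds (ng/g) and mean OAVs in spring
#' (SDT) and winter (WDT) dry tea, with the between-replicate CVs the
#' generator uses for them. Concentrations in the default fixture are
#' planted as OAV x threshold, so the forward pipeline reproduces these
#' values; the same table drives the OAV consistency checks.
#'
#' @return Data frame `compound_id`, `odor_threshold`, `oav_sdt`,
#'   `oav_wdt`, `cv`.
#' @export
key_oav_reference <- function() {
  lib <- default_compound_library()
  data.frame(compound_id = .KEY_OAV$compound_id,
             odor_threshold = lib$odor_threshold[
               match(.KEY_OAV$compound_id, lib$compound_id)],
             oav_sdt = .KEY_OAV$SDT, oav_wdt = .KEY_OAV$WDT,
             cv = .KEY_OAV$cv, stringsAsFactors = FALSE)
}

#' Default per-group true-concentration specs
#'
#' Four groups mirror the seasonal design: spring/winter dry tea (SDT/WDT)
#' and spring/winter fresh leaves (SFL/WFL). The six key compounds are
#' planted at threshold x published OAV for the dry teas; linalool and
#' geraniol are planted so the group terpene indices equal 0.72, 0.87,
#' 0.31 and 0.00; the remaining compounds are apportioned with class-level
#' seasonal contrasts (e.g. ketones/esters richer in SDT, aldehydes and
#' ketones richer in WFL) and rescaled so each group's total volatile
#' concentration equals its published-scale target (16080, 22930, 1622.20
#' and 1120.32 ng/g). Between-replicate CVs come from the key compounds'
#' published mean/SD ratios, 0.10 elsewhere.
#'
#' @param library A [compound_library()]; defaults to
#'   [default_compound_library()].
#' @return Named list (one per group) of data frames with columns
#'   `compound_id`, `concentration` (ng/g), `cv`.
#' @export
default_group_specs <- function(library = default_compound_library()) {
  thr <- library$odor_threshold
  names(thr) <- library$compound_id
  key <- .KEY_OAV
  # key-compound concentrations: dry teas from published OAVs, fresh
  # leaves at leaf-scale values with the published seasonal contrasts
  # (winter leaves richer in alpha-muurolene, cyclocitral and ionone;
  # spring leaves richer in nerolidol, farnesene and indole)
  conc <- list(
    SDT = key$SDT * thr[key$compound_id],
    WDT = key$WDT * thr[key$compound_id],
    SFL = c(180, 25, 95, 40, 6, 1.5),
    WFL = c(60, 8, 30, 0, 12, 9))
  ti <- .TI_TARGET
  lin <- c(SDT = unname(conc$SDT[key$compound_id == "linalool"]),
           SFL = 40, WFL = 0,
           WDT = unname(conc$WDT[key$compound_id == "linalool"]))
  ger <- ifelse(ti > 0, lin[names(ti)] * (1 / ti - 1),
                c(SDT = 0, WDT = 0, SFL = 0, WFL = 55)[names(ti)])
  filler <- setdiff(library$compound_id, c(key$compound_id, "geraniol"))
  fl_class <- library$chemical_class
  names(fl_class) <- library$compound_id
  base_w <- stats::setNames(rep(1, length(filler)), filler)
  # a few dominant background volatiles
  base_w[c("hotrienol", "phenylethanol_2", "benzyl_alcohol",
           "jasmone_Z", "methyl_salicylate")] <- 4
  mult <- list(
    SDT = c(ketone = 1.7, ester = 1.6, other = 1.5, aldehyde = 1.0),
    WDT = c(alcohol = 1.6, nitrogen_compound = 1.4, olefin = 1.7,
            monoterpene = 1.3, sesquiterpene = 1.4),
    SFL = c(monoterpene = 1.6, ester = 1.2),
    WFL = c(ketone = 1.7, aldehyde = 1.7))
  cvs <- stats::setNames(rep(0.10, nrow(library)), library$compound_id)
  cvs[key$compound_id] <- key$cv
  out <- list()
  for (g in names(.TOTAL_TARGET)) {
    w <- base_w
    m <- mult[[g]]
    cls <- fl_class[filler]
    for (cl in names(m)) w[cls == cl] <- w[cls == cl] * m[[cl]]
    key_conc <- stats::setNames(conc[[g]], key$compound_id)
    budget <- .TOTAL_TARGET[[g]] - sum(key_conc) - ger[[g]]
    if (budget <= 0) stop("group total too small for planted key compounds")
    fill_conc <- w / sum(w) * budget
    all_conc <- c(key_conc, geraniol = unname(ger[[g]]), fill_conc)
    df <- data.frame(compound_id = names(all_conc),
                     concentration = unname(all_conc),
                     cv = unname(cvs[names(all_conc)]),
                     stringsAsFactors = FALSE)
    out[[g]] <- df[df$concentration > 0 | df$compound_id %in%
                     c("linalool", "geraniol"), , drop = FALSE]
  }
  out
}

# lognormal multiplier with mean 1 and coefficient of variation cv
.lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate GC-MS peak tables with known ground truth
#'
#' Generates per-replicate peak tables such that the internal-standard
#' quantification formula applied to them recovers the planted
#' concentrations: `S_i = C_true * m * S_s / m_s`, with the
#' internal-standard area `S_s` and mass fixed per replicate, and
#' lognormal multiplicative noise at each compound's stated CV (exact
#' recovery at CV = 0). Retention times are placed by inverting the
#' retention-index interpolation against the ladder, so RI assignment of
#' the emitted peaks is self-consistent. Compounds with zero planted
#' concentration are not detected (no row).
#'
#' @param groups Named list of group specs (`compound_id`, `concentration`,
#'   `cv`); defaults to [default_group_specs()].
#' @param n_replicates Replicate runs per group, >= 2; default 6.
#' @param seed Integer RNG seed.
#' @param library,ladder,spec Library, ladder and [quant_spec()] used.
#' @param is_area Internal-standard peak area per replicate.
#' @param is_id,is_ri Internal-standard id and retention index.
#' @return A list of class `"gcms_simulation"`: `peaks` (one long
#'   [peak_table()]), `ladder`, `library`, `spec`, `truth` (data frame of
#'   planted group/compound concentrations and CVs), `seed`.
#' @export
simulate_gcms <- function(groups = default_group_specs(),
                          n_replicates = 6L, seed = 1L,
                          library = default_compound_library(),
                          ladder = default_ladder(),
                          spec = quant_spec(2, 1000),
                          is_area = 1e6, is_id = "ethyl_decanoate",
                          is_ri = 1396) {
  if (n_replicates < 2L) stop("n_replicates must be >= 2", call. = FALSE)
  set.seed(as.integer(seed))
  ri <- library$reference_ri
  names(ri) <- library$compound_id
  rows <- list()
  truth <- list()
  for (g in names(groups)) {
    gs <- groups[[g]]
    unknown <- setdiff(gs$compound_id, library$compound_id)
    if (length(unknown)) {
      stop("group '", g, "' plants compound(s) not in library: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    # errors immediately if any reference RI is outside ladder coverage
    rt <- rt_from_ri(ri[gs$compound_id], ladder)
    for (r in seq_len(n_replicates)) {
      noise <- vapply(gs$cv, function(cv) .lnorm_noise(1L, cv), numeric(1))
      c_rep <- gs$concentration * noise
      area <- c_rep * spec$sample_mass_g * is_area / spec$is_mass_ng
      keep <- gs$concentration > 0
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste0(g, "_R", r), group_label = g,
        replicate_index = r,
        compound_id = c(gs$compound_id[keep], is_id),
        retention_time = c(rt[keep], rt_from_ri(is_ri, ladder)),
        peak_area = c(area[keep], is_area),
        is_internal_standard = c(rep(FALSE, sum(keep)), TRUE),
        stringsAsFactors = FALSE)
    }
    truth[[g]] <- data.frame(group_label = g, compound_id = gs$compound_id,
                             true_concentration = gs$concentration,
                             cv = gs$cv, stringsAsFactors = FALSE)
  }
  peaks <- peak_table(do.call(rbind, rows))
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(list(peaks = peaks, ladder = ladder, library = library,
                 spec = spec, truth = truth, is_area = is_area,
                 is_id = is_id, seed = as.integer(seed)),
            class = "gcms_simulation")
}

#' Default planted differential-expression spec
#'
#' Effects are concentrated in the first pathways so that enrichment has a
#' planted signal: 20 of pathway 1's and 15 of pathway 2's genes are
#' up-regulated; further up- and down-regulated genes are scattered
#' outside the pathways, with more up than down (mirroring a
#' winter-dominant response). Planted |log2FC| is between 2 and 3.
#'
#' @param n_genes Total genes; default 2000.
#' @param n_pathways,pathway_size Pathway layout (consecutive blocks).
#' @return Data frame `gene_id`, `log2_fc`.
#' @export
default_planted_de <- function(n_genes = 2000L, n_pathways = 8L,
                               pathway_size = 30L) {
  gid <- function(i) sprintf("g%04d", i)
  free_start <- n_pathways * pathway_size + 1L
  up_in_p1 <- 1:20
  up_in_p2 <- (pathway_size + 1L):(pathway_size + 15L)
  up_free <- seq(free_start, length.out = 85L)
  down_free <- seq(free_start + 85L, length.out = 60L)
  data.frame(
    gene_id = gid(c(up_in_p1, up_in_p2, up_free, down_free)),
    log2_fc = c(rep(c(3, 2.5, 2), length.out = 120L),
                rep(c(-3, -2.5, -2), length.out = 60L)),
    stringsAsFactors = FALSE)
}

#' Simulate an RNA-seq count matrix with planted effects
#'
#' Counts are drawn negative-binomially around per-gene means; the test
#' condition's mean is the reference mean times `2^log2_fc` for planted
#' genes. With `exact = TRUE`, counts are the rounded means themselves
#' (deterministic), giving the zero-noise closure used to validate the
#' downstream statistics.
#'
#' @param n_genes Number of genes; default 2000.
#' @param planted_de Data frame `gene_id`, `log2_fc`, and optionally
#'   `base_mean` (to pin a planted gene's reference mean count); default
#'   [default_planted_de()]. Orientation is test (winter) over reference
#'   (spring).
#' @param n_replicates Replicates per condition, >= 2; default 3.
#' @param seed Integer RNG seed.
#' @param dispersion NB dispersion (1/size); 0 gives Poisson counts.
#'   Default 0.01, i.e. a biological coefficient of variation of 0.1,
#'   appropriate for replicates from clonal plants of one cultivar.
#' @param n_pathways,pathway_size Pathway layout, consecutive gene blocks.
#' @param base_mean_log_mean,base_mean_log_sd Lognormal parameters of the
#'   per-gene base mean count.
#' @param exact Emit deterministic rounded means instead of random counts.
#' @param conditions Length-2 labels, reference first; default
#'   `c("spring", "winter")`.
#' @return A list of class `"counts_simulation"`: `counts` (genes x
#'   samples), `lengths`, `condition` (per sample), `pathways` (named list
#'   of gene-id vectors), `truth` (`gene_id`, `length`, `base_mean`,
#'   `log2_fc`), `seed`.
#' @export
simulate_counts <- function(n_genes = 2000L,
                            planted_de = default_planted_de(n_genes,
                                                            n_pathways,
                                                            pathway_size),
                            n_replicates = 3L, seed = 1L,
                            dispersion = 0.01, n_pathways = 8L,
                            pathway_size = 30L,
                            base_mean_log_mean = log(150),
                            base_mean_log_sd = 1,
                            exact = FALSE,
                            conditions = c("spring", "winter")) {
  if (n_replicates < 2L) {
    stop("at least 2 replicates per condition required", call. = FALSE)
  }
  set.seed(as.integer(seed))
  gene_id <- sprintf("g%04d", seq_len(n_genes))
  lengths <- sample(500:4000, n_genes, replace = TRUE)
  base <- stats::rlnorm(n_genes, base_mean_log_mean, base_mean_log_sd)
  lfc <- stats::setNames(rep(0, n_genes), gene_id)
  if (nrow(planted_de)) {
    bad <- setdiff(planted_de$gene_id, gene_id)
    if (length(bad)) stop("planted genes not in matrix: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    lfc[planted_de$gene_id] <- planted_de$log2_fc
    # planted genes get a dependable base mean so the effect is observable
    idx <- match(planted_de$gene_id, gene_id)
    base[idx] <- pmax(base[idx], 100)
    if ("base_mean" %in% names(planted_de)) {
      pin <- !is.na(planted_de$base_mean)
      base[idx[pin]] <- planted_de$base_mean[pin]
    }
  }
  mu_ref <- base
  mu_test <- base * 2^lfc
  draw <- function(mu) {
    if (exact) return(round(mu))
    if (dispersion <= 0) return(stats::rpois(length(mu), mu))
    stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  cols <- c(lapply(seq_len(n_replicates), function(r) draw(mu_ref)),
            lapply(seq_len(n_replicates), function(r) draw(mu_test)))
  counts <- do.call(cbind, cols)
  dimnames(counts) <- list(gene_id,
                           c(paste0(conditions[1L], "_", seq_len(n_replicates)),
                             paste0(conditions[2L], "_", seq_len(n_replicates))))
  condition <- rep(conditions, each = n_replicates)
  pathways <- lapply(seq_len(n_pathways), function(i) {
    gene_id[((i - 1L) * pathway_size + 1L):(i * pathway_size)]
  })
  names(pathways) <- sprintf("pathway_%02d", seq_len(n_pathways))
  truth <- data.frame(gene_id = gene_id, length = lengths,
                      base_mean = base, log2_fc = unname(lfc),
                      stringsAsFactors = FALSE)
  structure(list(counts = counts, lengths = lengths, condition = condition,
                 pathways = pathways, truth = truth,
                 seed = as.integer(seed)),
            class = "counts_simulation")
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Ct values are built so that exact 2^-ddCt recovery holds at zero noise:
#' the reference gene elutes at a fixed Ct in both conditions, each target
#' gene's test-condition Ct is its calibrator Ct minus log2(fold change)
#' (one cycle earlier per doubling), and gaussian noise of standard
#' deviation `noise_sd` cycles is added to every Ct.
#'
#' @param fold_changes Named numeric vector of true fold changes
#'   (test condition over calibrator), one per target gene.
#' @param reference_gene Reference (housekeeping) gene id; must not carry a
#'   fold change other than 1.
#' @param n_replicates Replicates per condition; default 3.
#' @param seed Integer RNG seed.
#' @param noise_sd Gaussian Ct noise, cycles; default 0.2.
#' @param conditions Length-2 labels, calibrator first; default
#'   `c("spring", "winter")`.
#' @return A list of class `"ct_simulation"`: `ct` (a [ct_table()]),
#'   `truth` (`gene_id`, `fold_change`, `log2_fc`), `reference_gene`,
#'   `calibrator`, `seed`.
#' @export
simulate_ct <- function(fold_changes, reference_gene = "actin",
                        n_replicates = 3L, seed = 1L, noise_sd = 0.2,
                        conditions = c("spring", "winter")) {
  if (is.null(reference_gene) || is.na(reference_gene) ||
      !nzchar(reference_gene)) {
    stop("a reference gene is required", call. = FALSE)
  }
  if (is.null(names(fold_changes)) || !length(fold_changes)) {
    stop("fold_changes must be a named vector", call. = FALSE)
  }
  if (reference_gene %in% names(fold_changes) &&
      fold_changes[[reference_gene]] != 1) {
    stop("the reference gene must have fold change 1", call. = FALSE)
  }
  if (any(fold_changes <= 0)) {
    stop("fold changes must be positive", call. = FALSE)
  }
  set.seed(as.integer(seed))
  targets <- setdiff(names(fold_changes), reference_gene)
  base_ct <- stats::setNames(22 + (seq_along(targets) %% 8) * 0.7, targets)
  ref_ct <- 18
  rows <- list()
  for (cond in conditions) {
    shift <- if (cond == conditions[1L]) {
      stats::setNames(rep(0, length(targets)), targets)
    } else {
      -log2(fold_changes[targets])
    }
    for (r in seq_len(n_replicates)) {
      gene <- c(targets, reference_gene)
      ct0 <- c(base_ct[targets] + shift[targets], ref_ct)
      noise <- if (noise_sd == 0) rep(0, length(gene)) else
        stats::rnorm(length(gene), 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene, condition = cond, replicate_index = r,
        ct = unname(ct0) + noise, stringsAsFactors = FALSE)
    }
  }
  tab <- ct_table(do.call(rbind, rows))
  truth <- data.frame(gene_id = targets,
                      fold_change = unname(fold_changes[targets]),
                      log2_fc = unname(log2(fold_changes[targets])),
                      stringsAsFactors = FALSE)
  structure(list(ct = tab, truth = truth, reference_gene = reference_gene,
                 calibrator = conditions[1L], seed = as.integer(seed)),
            class = "ct_simulation")
}

#' Simulate the full default study
#'
#' The default fixture mirrors the study design: four seasonal groups with
#' six GC-MS replicates each (three are used for summary statistics),
#' a 2000-gene count matrix in a 3 vs 3 winter-vs-spring design with eight
#' 30-gene pathways and planted effects, and a six-gene qPCR validation
#' panel whose true fold changes equal the planted RNA-seq effects (three
#' up, three down).
#'
#' @param seed Integer RNG seed; sub-seeds for the three generators are
#'   derived from it.
#' @return A list of class `"study_simulation"`: `gcms`, `counts`, `ct`,
#'   `qpcr_genes`, `seed`.
#' @export
simulate_study <- function(seed = 1L) {
  seed <- as.integer(seed)
  gc <- simulate_gcms(seed = seed)
  cs <- simulate_counts(seed = seed + 1L)
  planted <- cs$truth[cs$truth$log2_fc != 0, ]
  qpcr_genes <- c(head(planted$gene_id[planted$log2_fc > 0], 3L),
                  head(planted$gene_id[planted$log2_fc < 0], 3L))
  fc <- 2^stats::setNames(
    cs$truth$log2_fc[match(qpcr_genes, cs$truth$gene_id)], qpcr_genes)
  ct <- simulate_ct(fc, reference_gene = "actin", seed = seed + 2L)
  structure(list(gcms = gc, counts = cs, ct = ct, qpcr_genes = qpcr_genes,
                 seed = seed),
            class = "study_simulation")
}

#' Write a simulated study's fixtures and ground truth to a directory
#'
#' Emits the pipeline's TSV formats (peaks, ladder, compound library,
#' counts, gene lengths, pathway sets, Ct table), the ground-truth tables,
#' and a manifest recording the seed and generator parameters.
#'
#' @param study A `study_simulation` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixtures <- function(study, dir) {
  stopifnot(inherits(study, "study_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  gc <- study$gcms
  write_tsv_table(as.data.frame(gc$peaks), p("peaks.tsv"))
  write_tsv_table(as.data.frame(gc$ladder), p("ladder.tsv"))
  write_tsv_table(as.data.frame(gc$library), p("library.tsv"))
  write_tsv_table(gc$truth, p("ground_truth_gcms.tsv"))
  cs <- study$counts
  cdf <- data.frame(gene_id = rownames(cs$counts), cs$counts,
                    check.names = FALSE)
  write_tsv_table(cdf, p("counts.tsv"))
  write_tsv_table(data.frame(gene_id = rownames(cs$counts),
                             length = cs$lengths), p("lengths.tsv"))
  sets <- data.frame(set_id = rep(names(cs$pathways),
                                  lengths(cs$pathways)),
                     gene_id = unlist(cs$pathways, use.names = FALSE))
  write_tsv_table(sets, p("sets.tsv"))
  write_tsv_table(cs$truth, p("ground_truth_counts.tsv"))
  write_tsv_table(as.data.frame(study$ct$ct), p("ct.tsv"))
  write_tsv_table(study$ct$truth, p("ground_truth_ct.tsv"))
  manifest <- data.frame(
    key = c("seed", "n_gcms_replicates", "n_count_replicates",
            "n_genes", "sample_mass_g", "is_mass_ng", "is_area",
            "reference_gene", "calibrator"),
    value = c(study$seed, max(gc$peaks$replicate_index),
              sum(cs$condition == cs$condition[1L]), nrow(cs$counts),
              gc$spec$sample_mass_g, gc$spec$is_mass_ng, gc$is_area,
              study$ct$reference_gene, study$ct$calibrator))
  write_tsv_table(manifest, p("manifest.tsv"))
  invisible(vapply(c("peaks.tsv", "ladder.tsv", "library.tsv",
                     "counts.tsv", "lengths.tsv", "sets.tsv", "ct.tsv",
                     "ground_truth_gcms.tsv", "ground_truth_counts.tsv",
                     "ground_truth_ct.tsv", "manifest.tsv"), p, ""))
}
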