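# End-to-end pipeline stages over the TSV formats, shared by the CLI and
# by reproducibility checks. Every stage reads its inputs from and writes
# its outputs to a single run directory.

.log_stage <- function(stage, seed) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", stage,
          "] seed=", seed)
}

.stage_simulate <- function(dir, cfg) {
  study <- simulate_study(cfg$seed)
  write_fixtures(study, dir)
  write_run_config(cfg, file.path(dir, "config.txt"))
  invisible(study)
}

.stage_quantify <- function(dir, cfg) {
  peaks <- read_peak_table(file.path(dir, "peaks.tsv"))
  ladder <- read_alkane_ladder(file.path(dir, "ladder.tsv"))
  lib <- read_compound_library(file.path(dir, "library.tsv"))
  spec <- quant_spec(cfg$sample_mass_g, cfg$is_mass_ng)
  ann <- annotate(peaks, ladder, lib, tolerance = cfg$ri_tolerance)
  write_tsv_table(ann, file.path(dir, "annotation.tsv"))
  prof <- quantify(peaks, spec)
  write_quantified_profile(prof, file.path(dir, "quantified.tsv"))
  invisible(prof)
}

# restrict a profile or peak table to the replicates used for statistics
.first_reps <- function(df, n) df[df$replicate_index <= n, , drop = FALSE]

.stage_score <- function(dir, cfg) {
  prof <- read_quantified_profile(file.path(dir, "quantified.tsv"))
  lib <- read_compound_library(file.path(dir, "library.tsv"))
  n <- as.integer(cfg$stat_replicates)
  prof <- .first_reps(prof, n)
  ov <- oav(prof, lib)
  write_tsv_table(as.data.frame(ov), file.path(dir, "oav.tsv"))
  rad <- radar(ov, offset = cfg$radar_offset)
  write_tsv_table(as.data.frame(rad), file.path(dir, "radar.tsv"))
  ct <- class_totals(prof, lib)
  write_tsv_table(as.data.frame(ct), file.path(dir, "class_totals.tsv"))
  # terpene index per group from summed peak areas of the stat replicates
  peaks <- .first_reps(read_peak_table(file.path(dir, "peaks.tsv")), n)
  groups <- sort(unique(peaks$group_label))
  ti <- vapply(groups, function(g) {
    sel <- peaks$group_label == g
    s_l <- sum(peaks$peak_area[sel & peaks$compound_id == "linalool"])
    s_g <- sum(peaks$peak_area[sel & peaks$compound_id == "geraniol"])
    terpene_index(s_l, s_g)
  }, numeric(1))
  write_tsv_table(data.frame(group_label = groups, terpene_index = ti),
                  file.path(dir, "ti.tsv"))
  invisible(ov)
}

.stage_compare <- function(dir, cfg) {
  prof <- read_quantified_profile(file.path(dir, "quantified.tsv"))
  n <- as.integer(cfg$stat_replicates)
  prof <- .first_reps(prof, n)
  groups <- sort(unique(prof$group_label))
  rows <- list()
  for (pair in utils::combn(groups, 2L, simplify = FALSE)) {
    sub <- prof[prof$group_label %in% pair, , drop = FALSE]
    for (cmp in sort(unique(sub$compound_id))) {
      s <- sub[sub$compound_id == cmp, , drop = FALSE]
      if (!all(table(s$group_label) >= 2L) ||
          length(unique(s$group_label)) != 2L) next
      cg <- compare_groups(s$concentration, s$group_label)
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = cg$groups[1L], group_b = cg$groups[2L],
        compound_id = cmp, mean_a = cg$means[1L], mean_b = cg$means[2L],
        mean_difference = cg$mean_difference,
        cv_percent_a = cg$cv_percent[1L], cv_percent_b = cg$cv_percent[2L],
        t_statistic = cg$t_statistic, t_p = cg$t_p,
        u_statistic = cg$u_statistic, u_p = cg$u_p)
    }
  }
  comp <- do.call(rbind, rows)
  write_tsv_table(comp, file.path(dir, "comparisons.tsv"))
  # PCA across all samples x compounds (replicates as observations)
  wide <- stats::reshape(
    prof[, c("sample_id", "compound_id", "concentration")],
    idvar = "sample_id", timevar = "compound_id", direction = "wide")
  mat <- as.matrix(wide[, -1L, drop = FALSE])
  mat[is.na(mat)] <- 0
  rownames(mat) <- wide$sample_id
  colnames(mat) <- sub("^concentration\\.", "", colnames(mat))
  pc <- suppressWarnings(pca_volatiles(mat))
  sc <- data.frame(sample_id = rownames(pc$scores),
                   pc$scores[, 1:2, drop = FALSE])
  sc$pc1_fraction <- pc$variance_fraction[1L]
  sc$pc2_fraction <- pc$variance_fraction[2L]
  write_tsv_table(sc, file.path(dir, "pca.tsv"))
  invisible(comp)
}

.stage_enrich <- function(dir, cfg) {
  cdf <- read_tsv_table(file.path(dir, "counts.tsv"), "gene_id")
  counts <- as.matrix(cdf[, setdiff(names(cdf), "gene_id"), drop = FALSE])
  rownames(counts) <- cdf$gene_id
  lens <- read_tsv_table(file.path(dir, "lengths.tsv"),
                         c("gene_id", "length"))
  lens <- lens$length[match(cdf$gene_id, lens$gene_id)]
  condition <- sub("_[0-9]+$", "", colnames(counts))
  expr <- fpkm(counts, lens)
  fdf <- data.frame(gene_id = rownames(expr$fpkm), expr$fpkm,
                    check.names = FALSE)
  write_tsv_table(fdf, file.path(dir, "fpkm.tsv"))
  deg <- deg_call(expr, condition, condition_test = "winter",
                  condition_ref = "spring",
                  fc_threshold = cfg$fc_threshold,
                  fdr_threshold = cfg$fdr_threshold)
  write_tsv_table(as.data.frame(deg), file.path(dir, "deg.tsv"))
  sets_df <- read_tsv_table(file.path(dir, "sets.tsv"),
                            c("set_id", "gene_id"))
  sets <- split(sets_df$gene_id, sets_df$set_id)
  enr <- hypergeom_enrich(deg$gene_id[deg$direction != "ns"],
                          deg$gene_id, sets)
  write_tsv_table(as.data.frame(enr), file.path(dir, "enrichment.tsv"))
  invisible(list(deg = deg, enrichment = enr))
}

.stage_qpcr <- function(dir, cfg) {
  ct <- read_ct_table(file.path(dir, "ct.tsv"))
  man <- read_tsv_table(file.path(dir, "manifest.tsv"), c("key", "value"))
  ref <- man$value[man$key == "reference_gene"]
  cal <- man$value[man$key == "calibrator"]
  if (!length(ref)) ref <- "actin"
  if (!length(cal)) cal <- "spring"
  rel <- ddct(ct, reference_gene = ref, calibrator = cal)
  write_tsv_table(as.data.frame(rel), file.path(dir, "relexpr.tsv"))
  invisible(rel)
}

.stage_report <- function(dir, cfg) {
  deg <- read_tsv_table(file.path(dir, "deg.tsv"),
                        c("gene_id", "log2_fc", "direction"))
  rel <- read_tsv_table(file.path(dir, "relexpr.tsv"),
                        c("gene_id", "condition", "log2_fc"))
  enr <- read_tsv_table(file.path(dir, "enrichment.tsv"),
                        c("set_id", "adj_p"))
  tot <- read_tsv_table(file.path(dir, "class_totals.tsv"),
                        c("group_label", "chemical_class", "mean_total"))
  ti <- read_tsv_table(file.path(dir, "ti.tsv"),
                       c("group_label", "terpene_index"))
  rna_fc <- stats::setNames(deg$log2_fc, deg$gene_id)
  winter <- rel[rel$condition == "winter", , drop = FALSE]
  q_fc <- stats::setNames(winter$log2_fc, winter$gene_id)
  conc <- concordance(rna_fc[names(q_fc)], q_fc)
  grand <- tot[tot$chemical_class == "total", , drop = FALSE]
  rows <- rbind(
    data.frame(metric = paste0("total_volatiles_", grand$group_label),
               value = grand$mean_total),
    data.frame(metric = paste0("terpene_index_", ti$group_label),
               value = ti$terpene_index),
    data.frame(metric = c("n_deg", "n_deg_up", "n_deg_down"),
               value = c(sum(deg$direction != "ns"),
                         sum(deg$direction == "up"),
                         sum(deg$direction == "down"))),
    data.frame(metric = "n_enriched_sets_fdr05",
               value = sum(enr$adj_p <= 0.05)),
    data.frame(metric = c("qpcr_concordant", "qpcr_compared"),
               value = c(conc$n_concordant, conc$n_compared)))
  write_tsv_table(rows, file.path(dir, "report.tsv"))
  invisible(rows)
}

#' Run the full pipeline into a directory
#'
#' Simulates the default study at the given seed, then runs
#' quantification, scoring, group comparison, expression/enrichment, qPCR
#' and reporting, writing every intermediate and final table to `dir`.
#' Identical seeds produce byte-identical output tables.
#'
#' @param dir Run directory (created if needed).
#' @param seed Integer RNG seed.
#' @param cfg A `run_config`; defaults to [default_config()].
#' @return `dir`, invisibly.
#' @export
run_pipeline <- function(dir, seed = 1L, cfg = default_config()) {
  cfg$seed <- as.integer(seed)
  for (stage in c("simulate", "quantify", "score", "compare", "enrich",
                  "qpcr", "report")) {
    .log_stage(stage, cfg$seed)
    switch(stage,
           simulate = .stage_simulate(dir, cfg),
           quantify = .stage_quantify(dir, cfg),
           score = .stage_score(dir, cfg),
           compare = .stage_compare(dir, cfg),
           enrich = .stage_enrich(dir, cfg),
           qpcr = .stage_qpcr(dir, cfg),
           report = .stage_report(dir, cfg))
  }
  invisible(dir)
}
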