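# Aroma statistics computed from absolute concentrations: odor activity
# values, odor-dimension radar coordinates, the terpene index,
# chemical-class totals, two-group comparisons and PCA of volatiles.

#' Odor activity values
#'
#' OAV = C_i / T_i: the concentration of a volatile divided by its odor
#' threshold in water. Compounds with OAV >= 1 are classed as making a
#' significant contribution to the perceived aroma; 0 <= OAV < 1 is a
#' minor contribution. OAVs are computed per replicate and then summarised
#' as mean +/- SD across replicates (not the OAV of the mean
#' concentration). Compounds without a library threshold are skipped and
#' listed in the `"skipped"` attribute: their OAV is undefined, not zero.
#'
#' @param profile A `quantified_profile` (see [quantify()]).
#' @param library A [compound_library()].
#' @return A data frame of class `"oav_table"`: one row per (group,
#'   compound) with `group_label`, `compound_id`, `odor_type`, `mean_oav`,
#'   `sd_oav`, `n`, `contribution` (`"significant"` if mean OAV >= 1, else
#'   `"minor"`). Attribute `"replicate"` holds the per-replicate OAVs.
#' @export
oav <- function(profile, library) {
  stopifnot(inherits(profile, "quantified_profile"),
            inherits(library, "compound_library"))
  thr <- library$odor_threshold
  names(thr) <- library$compound_id
  if (any(!is.na(thr) & thr <= 0)) {
    stop("odor thresholds must be positive", call. = FALSE)
  }
  otype <- library$odor_type
  names(otype) <- library$compound_id
  known <- profile$compound_id %in% library$compound_id
  t_i <- thr[profile$compound_id]
  scored <- known & !is.na(t_i)
  skipped <- sort(unique(profile$compound_id[!scored]))
  rep_oav <- profile[scored, c("sample_id", "group_label", "replicate_index",
                               "compound_id")]
  rep_oav$oav <- profile$concentration[scored] / t_i[scored]
  agg <- stats::aggregate(oav ~ group_label + compound_id, data = rep_oav,
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(group_label = agg$group_label,
                    compound_id = agg$compound_id,
                    odor_type = unname(otype[agg$compound_id]),
                    mean_oav = agg$oav[, "mean"],
                    sd_oav = agg$oav[, "sd"],
                    n = as.integer(agg$oav[, "n"]))
  out$contribution <- ifelse(out$mean_oav >= 1, "significant", "minor")
  out <- out[order(out$group_label, out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "replicate") <- rep_oav
  attr(out, "skipped") <- skipped
  class(out) <- c("oav_table", "data.frame")
  out
}

#' Odor-dimension radar coordinates
#'
#' Sums the OAVs of all compounds sharing an odor type and log-transforms
#' the per-dimension totals: coordinate = log10(total + offset). A
#' dimension with no scored compounds has total 0 and, with the default
#' offset 1, coordinate 0 — the offset guards against a log of zero for
#' dimensions (such as roasted) that a season may lack entirely.
#'
#' @param oavs An `oav_table` from [oav()].
#' @param offset Added inside the log; default 1.
#' @param base Log base; default 10, the flavour-literature convention.
#' @return A data frame of class `"radar_profile"`: one row per (group,
#'   odor dimension) with `total_oav` and `coordinate`.
#' @export
radar <- function(oavs, offset = 1, base = 10) {
  stopifnot(inherits(oavs, "oav_table"))
  if (!is.finite(offset) || offset <= 0) stop("offset must be > 0", call. = FALSE)
  typed <- oavs[!is.na(oavs$odor_type), , drop = FALSE]
  groups <- sort(unique(oavs$group_label))
  grid <- expand.grid(group_label = groups, odor_type = .ODOR_TYPES,
                      stringsAsFactors = FALSE)
  tot <- numeric(nrow(grid))
  for (j in seq_len(nrow(grid))) {
    sel <- typed$group_label == grid$group_label[j] &
      typed$odor_type == grid$odor_type[j]
    tot[j] <- sum(typed$mean_oav[sel])
  }
  out <- data.frame(grid, total_oav = tot,
                    coordinate = log(tot + offset, base = base) -
                      log(offset, base = base))
  class(out) <- c("radar_profile", "data.frame")
  out
}

#' Terpene index
#'
#' TI = S_l / (S_l + S_g), with S_l the linalool peak area and S_g the
#' geraniol peak area. TI lies in [0, 1], equals 0 iff linalool is absent
#' and 1 iff geraniol is absent, and is invariant to a joint rescaling of
#' both areas. A high TI reads as a rich, pleasant aroma; a low TI as a
#' strong, sharp one. Computed from peak areas, not concentrations (the
#' internal-standard factors cancel anyway).
#'
#' @param linalool_area Linalool peak area, >= 0.
#' @param geraniol_area Geraniol peak area, >= 0.
#' @return The terpene index, a number in [0, 1].
#' @export
terpene_index <- function(linalool_area, geraniol_area) {
  if (!is.finite(linalool_area) || !is.finite(geraniol_area) ||
      linalool_area < 0 || geraniol_area < 0) {
    stop("peak areas must be nonnegative and finite", call. = FALSE)
  }
  if (linalool_area + geraniol_area == 0) {
    stop("terpene index undefined: both linalool and geraniol areas are zero",
         call. = FALSE)
  }
  linalool_area / (linalool_area + geraniol_area)
}

#' Per-chemical-class concentration totals
#'
#' Sums concentrations within each chemical class per (sample, replicate),
#' then summarises per group as mean +/- SD. Class totals conserve mass:
#' summed over classes they equal the total volatile concentration of the
#' replicate. Compounds missing from the library or unclassified are
#' assigned `"other"` with a warning.
#'
#' @param profile A `quantified_profile`.
#' @param library A [compound_library()].
#' @return A data frame of class `"class_totals"`: per (group, class)
#'   `mean_total`, `sd_total`, `n`, plus a `grand_total` row per group
#'   (class `"total"`). Attribute `"replicate"` holds per-replicate totals.
#' @export
class_totals <- function(profile, library) {
  stopifnot(inherits(profile, "quantified_profile"),
            inherits(library, "compound_library"))
  cls <- library$chemical_class
  names(cls) <- library$compound_id
  cc <- cls[profile$compound_id]
  if (anyNA(cc)) {
    warning(sum(is.na(cc)), " peak(s) without a chemical class assigned to ",
            "'other'", call. = FALSE)
    cc[is.na(cc)] <- "other"
  }
  rep_tot <- stats::aggregate(
    profile$concentration,
    by = list(group_label = profile$group_label,
              sample_id = profile$sample_id,
              replicate_index = profile$replicate_index,
              chemical_class = cc),
    FUN = sum)
  names(rep_tot)[names(rep_tot) == "x"] <- "total"
  grand <- stats::aggregate(
    profile$concentration,
    by = list(group_label = profile$group_label,
              sample_id = profile$sample_id,
              replicate_index = profile$replicate_index),
    FUN = sum)
  grand$chemical_class <- "total"
  names(grand)[names(grand) == "x"] <- "total"
  rep_all <- rbind(rep_tot, grand[, names(rep_tot)])
  agg <- stats::aggregate(total ~ group_label + chemical_class,
                          data = rep_all,
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(group_label = agg$group_label,
                    chemical_class = agg$chemical_class,
                    mean_total = agg$total[, "mean"],
                    sd_total = agg$total[, "sd"],
                    n = as.integer(agg$total[, "n"]))
  out <- out[order(out$group_label, out$chemical_class), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "replicate") <- rep_all
  class(out) <- c("class_totals", "data.frame")
  out
}

#' Two-group comparison of a per-replicate statistic
#'
#' Reports the equal-variance two-sided Student's t-test alongside the
#' two-sided Mann-Whitney U test (exact for group sizes <= 8), plus per-
#' group CV% = 100 * SD / mean. Both tests are reported; neither gates the
#' other. When both groups are constant and identical, p = 1 by convention
#' and the result is flagged degenerate.
#'
#' @param values Numeric vector of per-replicate values.
#' @param groups Vector of group labels, exactly two distinct values.
#' @return A list of class `"group_comparison"`: `groups`, `means`,
#'   `mean_difference` (group1 - group2), `cv_percent`, `t_statistic`,
#'   `t_p`, `u_statistic`, `u_p`, `degenerate`.
#' @export
compare_groups <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("exactly two groups required", call. = FALSE)
  a <- values[g == levels(g)[1L]]
  b <- values[g == levels(g)[2L]]
  if (length(a) < 2L || length(b) < 2L) {
    stop("at least 2 replicates per group required", call. = FALSE)
  }
  cv <- function(v) 100 * stats::sd(v) / mean(v)
  degenerate <- stats::sd(a) == 0 && stats::sd(b) == 0
  if (degenerate) {
    if (mean(a) == mean(b)) {
      tstat <- 0; tp <- 1
    } else {
      tstat <- Inf * sign(mean(a) - mean(b)); tp <- 0
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    tstat <- unname(tt$statistic); tp <- tt$p.value
  }
  exact <- length(a) <= 8L && length(b) <= 8L
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  structure(list(groups = levels(g),
                 means = c(mean(a), mean(b)),
                 mean_difference = mean(a) - mean(b),
                 cv_percent = c(cv(a), cv(b)),
                 t_statistic = tstat, t_p = tp,
                 u_statistic = unname(wt$statistic), u_p = wt$p.value,
                 degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: diff = %.4g, t = %.4g (p = %.4g), U = %g (p = %.4g)\n",
              x$groups[1L], x$groups[2L], x$mean_difference,
              x$t_statistic, x$t_p, x$u_statistic, x$u_p))
  if (x$degenerate) cat("  [degenerate: both groups constant]\n")
  invisible(x)
}

#' PCA of volatile concentrations
#'
#' Principal component analysis of a samples x compounds concentration
#' matrix. Columns are always centred; unit-variance scaling is on by
#' default because volatile concentrations span several orders of
#' magnitude. Constant columns are dropped with a warning (they carry no
#' variance and break scaling).
#'
#' @param mat Numeric matrix, samples in rows, compounds in columns.
#' @param scale. Scale columns to unit variance; default TRUE.
#' @return A list of class `"volatile_pca"`: `scores`, `loadings`
#'   (orthonormal columns), `variance_fraction` (nonincreasing, sums to 1),
#'   `dropped` (names of constant columns removed).
#' @export
pca_volatiles <- function(mat, scale. = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L || ncol(mat) < 2L) {
    stop("need at least 2 samples and 2 compounds", call. = FALSE)
  }
  const <- apply(mat, 2L, function(v) stats::sd(v) == 0)
  dropped <- colnames(mat)[const]
  if (any(const)) {
    warning("dropping ", sum(const), " constant column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
    mat <- mat[, !const, drop = FALSE]
    if (ncol(mat) < 2L) stop("fewer than 2 varying compounds", call. = FALSE)
  }
  pc <- stats::prcomp(mat, center = TRUE, scale. = scale.)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_fraction = vf, dropped = dropped),
            class = "volatile_pca")
}
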