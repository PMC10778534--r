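# Relative expression by the 2^-ddCt method with a named reference gene.

#' Construct and validate a Ct table
#'
#' @param df Data frame with columns `gene_id`, `condition`,
#'   `replicate_index`, `ct` (cycles).
#' @return The validated data frame with class `"ct_table"`.
#' @export
ct_table <- function(df) {
  req <- c("gene_id", "condition", "replicate_index", "ct")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("Ct table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(df$ct))) {
    .located_error("Ct values must be finite", df, which(!is.finite(df$ct)))
  }
  class(df) <- c("ct_table", "data.frame")
  df
}

#' Read a Ct table from TSV
#' @param path Path to a TSV with columns `gene_id`, `condition`,
#'   `replicate_index`, `ct`.
#' @return A `ct_table`.
#' @export
read_ct_table <- function(path) {
  ct_table(read_tsv_table(path, c("gene_id", "condition", "replicate_index",
                                  "ct")))
}

#' Relative expression by 2^-ddCt
#'
#' Livak-style relative quantification: per replicate,
#' dCt = Ct_gene - Ct_reference; then ddCt = dCt - mean dCt of the
#' calibrator condition for that gene, and relative expression = 2^-ddCt.
#' The calibrator condition's mean ddCt is 0 by construction, so its
#' relative expression is centred on 1 (exactly 1 in every replicate at
#' zero noise). Replicates missing a reference-gene Ct are excluded with a
#' warning. Shifting every Ct of a replicate by a constant (a plate
#' offset) leaves all relative expressions unchanged.
#'
#' @param table A [ct_table()].
#' @param reference_gene Gene id used for within-replicate normalisation
#'   (e.g. actin); must be present in every (condition, replicate).
#' @param calibrator Condition id whose mean dCt anchors ddCt (e.g. the
#'   spring season, so fold changes read winter relative to spring).
#' @return A data frame of class `"relative_expression"`: per (gene,
#'   condition) `mean_rel_expr`, `sd_rel_expr`, `n`, `log2_fc` (mean -ddCt,
#'   i.e. the log2 fold change vs the calibrator). Attribute `"replicate"`
#'   holds per-replicate values.
#' @export
ddct <- function(table, reference_gene, calibrator) {
  stopifnot(inherits(table, "ct_table"))
  if (!reference_gene %in% table$gene_id) {
    stop("reference gene '", reference_gene, "' not in Ct table",
         call. = FALSE)
  }
  if (!calibrator %in% table$condition) {
    stop("calibrator condition '", calibrator, "' not in Ct table",
         call. = FALSE)
  }
  ref <- table[table$gene_id == reference_gene, , drop = FALSE]
  ref_ct <- ref$ct
  names(ref_ct) <- paste(ref$condition, ref$replicate_index, sep = "\r")
  tg <- table[table$gene_id != reference_gene, , drop = FALSE]
  key <- paste(tg$condition, tg$replicate_index, sep = "\r")
  have_ref <- key %in% names(ref_ct)
  if (!all(have_ref)) {
    dropped <- unique(gsub("\r", " rep ", key[!have_ref], fixed = TRUE))
    warning("excluding replicate(s) without a reference Ct: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    tg <- tg[have_ref, , drop = FALSE]
    key <- key[have_ref]
  }
  tg$dct <- tg$ct - unname(ref_ct[key])
  cal_mean <- stats::aggregate(
    dct ~ gene_id, data = tg[tg$condition == calibrator, , drop = FALSE],
    FUN = mean)
  cal <- cal_mean$dct
  names(cal) <- cal_mean$gene_id
  if (!all(tg$gene_id %in% names(cal))) {
    stop("gene(s) missing from the calibrator condition: ",
         paste(setdiff(unique(tg$gene_id), names(cal)), collapse = ", "),
         call. = FALSE)
  }
  tg$ddct <- tg$dct - unname(cal[tg$gene_id])
  tg$rel_expr <- 2^(-tg$ddct)
  agg <- stats::aggregate(cbind(rel_expr, ddct) ~ gene_id + condition,
                          data = tg, FUN = mean)
  sds <- stats::aggregate(rel_expr ~ gene_id + condition, data = tg,
                          FUN = stats::sd)
  ns <- stats::aggregate(rel_expr ~ gene_id + condition, data = tg,
                         FUN = length)
  out <- data.frame(gene_id = agg$gene_id, condition = agg$condition,
                    mean_rel_expr = agg$rel_expr, sd_rel_expr = sds$rel_expr,
                    n = as.integer(ns$rel_expr), log2_fc = -agg$ddct)
  out <- out[order(out$gene_id, out$condition), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "replicate") <- tg
  attr(out, "reference_gene") <- reference_gene
  attr(out, "calibrator") <- calibrator
  class(out) <- c("relative_expression", "data.frame")
  out
}
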