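# Desk-scale transcriptome statistics: FPKM expression, differential-
# expression calling on a small two-condition design, hypergeometric
# pathway enrichment and RNA-seq/qPCR trend concordance. The module starts
# at the count matrix; read QC and alignment are upstream of it.

#' FPKM expression matrix
#'
#' FPKM_gj = counts_gj * 1e9 / (length_g * libsize_j): fragments per
#' kilobase of exon model per million mapped fragments. Library sizes
#' default to column sums of the count matrix.
#'
#' @param counts Nonnegative integer matrix, genes x samples.
#' @param lengths Gene lengths in bases, > 0, one per row of `counts`.
#' @param lib_sizes Optional per-sample mapped-fragment totals; defaults to
#'   `colSums(counts)`.
#' @return A list of class `"expression_set"`: `counts`, `lengths`,
#'   `lib_sizes`, `fpkm`.
#' @export
fpkm <- function(counts, lengths, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (length(lengths) != nrow(counts)) {
    stop("one gene length per count row required", call. = FALSE)
  }
  if (any(!is.finite(lengths) | lengths <= 0)) {
    stop("gene lengths must be positive", call. = FALSE)
  }
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (length(lib_sizes) != ncol(counts)) {
    stop("one library size per sample required", call. = FALSE)
  }
  if (any(lib_sizes <= 0)) stop("zero library size", call. = FALSE)
  f <- counts * 1e9 / outer(as.numeric(lengths), as.numeric(lib_sizes))
  dimnames(f) <- dimnames(counts)
  structure(list(counts = counts, lengths = lengths,
                 lib_sizes = lib_sizes, fpkm = f),
            class = "expression_set")
}

# Row-wise Welch t-test on a matrix split into two sample groups.
# Vectorised so thousands of genes over hundreds of simulation seeds stay
# cheap; equality with stats::t.test is asserted in the test suite.
.row_welch <- function(x, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(x[, idx1, drop = FALSE])
  m2 <- rowMeans(x[, idx2, drop = FALSE])
  v1 <- rowSums((x[, idx1, drop = FALSE] - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x[, idx2, drop = FALSE] - m2)^2) / (n2 - 1L)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # zero variance in both groups: identical means -> not significant
  flat <- se2 == 0
  p[flat & (m1 == m2)] <- 1
  p[flat & (m1 != m2)] <- 0
  tstat[flat] <- ifelse(m1[flat] == m2[flat], 0, Inf * sign((m1 - m2)[flat]))
  list(statistic = tstat, p = p, mean1 = m1, mean2 = m2)
}

#' Differential-expression calling
#'
#' Per-gene two-sided Welch t-test on log2(FPKM + 1), Benjamini-Hochberg
#' adjustment across genes, and direction by the sign of the mean log2
#' fold change subject to both thresholds. Fold changes are oriented
#' `condition_test` minus `condition_ref` (winter vs spring in the default
#' fixture), so "up" means higher in the test condition.
#'
#' @param expr An `expression_set` from [fpkm()].
#' @param conditions Vector of condition labels, one per sample column.
#' @param condition_test,condition_ref The two condition labels; fold
#'   changes read test/ref.
#' @param fc_threshold Minimum |log2 fold change|; default 1.
#' @param fdr_threshold BH-adjusted p cutoff; default 0.05.
#' @return A data frame of class `"deg_table"`: per gene `gene_id`,
#'   `log2_fc`, `p_value`, `adj_p`, `direction` in up/down/ns.
#' @export
deg_call <- function(expr, conditions, condition_test, condition_ref,
                     fc_threshold = 1, fdr_threshold = 0.05) {
  stopifnot(inherits(expr, "expression_set"))
  idx1 <- which(conditions == condition_test)
  idx2 <- which(conditions == condition_ref)
  if (length(idx1) < 2L || length(idx2) < 2L) {
    stop("at least 2 replicates per condition required", call. = FALSE)
  }
  lx <- log2(expr$fpkm + 1)
  w <- .row_welch(lx, idx1, idx2)
  lfc <- w$mean1 - w$mean2
  adj <- stats::p.adjust(w$p, method = "BH")
  dir <- rep("ns", length(lfc))
  hit <- adj <= fdr_threshold & abs(lfc) >= fc_threshold
  dir[hit & lfc > 0] <- "up"
  dir[hit & lfc < 0] <- "down"
  gene_id <- rownames(expr$counts)
  if (is.null(gene_id)) gene_id <- paste0("g", seq_along(lfc))
  out <- data.frame(gene_id = gene_id, log2_fc = lfc, p_value = w$p,
                    adj_p = adj, direction = dir)
  rownames(out) <- NULL
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Hypergeometric gene-set enrichment
#'
#' For each gene set, the upper-tail probability that its overlap with the
#' DEG list is at least as large as observed under sampling without
#' replacement: p = P(X >= k), X ~ Hypergeometric(N, K, n) with N the
#' universe size, K the set size within the universe, n the number of
#' DEGs and k the observed overlap. P-values are BH-adjusted across the
#' tested sets. Sets are intersected with the universe first; sets empty
#' after intersection are skipped and listed in the `"skipped"` attribute.
#'
#' @param deg_ids Character vector of differentially expressed gene ids
#'   (must be a subset of `universe_ids`).
#' @param universe_ids Character vector: all genes eligible for selection.
#' @param gene_sets Named list of character vectors.
#' @return A data frame of class `"enrichment_table"`: per set `set_id`,
#'   `set_size` (K), `draw_size` (n), `overlap` (k), `universe` (N),
#'   `p_value`, `adj_p`.
#' @export
hypergeom_enrich <- function(deg_ids, universe_ids, gene_sets) {
  universe_ids <- unique(universe_ids)
  if (!length(universe_ids)) stop("empty universe", call. = FALSE)
  deg_ids <- unique(deg_ids)
  if (!all(deg_ids %in% universe_ids)) {
    stop("deg_ids must be a subset of the universe", call. = FALSE)
  }
  N <- length(universe_ids)
  n <- length(deg_ids)
  sets <- lapply(gene_sets, function(s) intersect(unique(s), universe_ids))
  skipped <- names(sets)[lengths(sets) == 0L]
  sets <- sets[lengths(sets) > 0L]
  K <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(s, deg_ids)), integer(1))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(set_id = names(sets), set_size = K, draw_size = n,
                    overlap = k, universe = N, p_value = p,
                    adj_p = stats::p.adjust(p, method = "BH"))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' RNA-seq vs qPCR trend concordance
#'
#' Compares the sign of the RNA-seq log2 fold change with the sign of the
#' qPCR log2 fold change for shared genes. Genes with a zero fold change
#' on either side carry no direction and are excluded (listed in the
#' `"excluded"` attribute).
#'
#' @param rnaseq_fc Named numeric vector of RNA-seq log2 fold changes.
#' @param qpcr_fc Named numeric vector of qPCR log2 fold changes.
#' @return A list of class `"concordance"`: per-gene data frame `genes`
#'   (`gene_id`, `rnaseq_log2_fc`, `qpcr_log2_fc`, `concordant`),
#'   `n_compared`, `n_concordant`, `fraction_concordant`.
#' @export
concordance <- function(rnaseq_fc, qpcr_fc) {
  shared <- intersect(names(rnaseq_fc), names(qpcr_fc))
  if (!length(shared)) stop("no shared gene identifiers", call. = FALSE)
  r <- rnaseq_fc[shared]
  q <- qpcr_fc[shared]
  zero <- r == 0 | q == 0
  excluded <- shared[zero]
  r <- r[!zero]; q <- q[!zero]
  conc <- sign(r) == sign(q)
  genes <- data.frame(gene_id = names(r), rnaseq_log2_fc = unname(r),
                      qpcr_log2_fc = unname(q), concordant = unname(conc))
  structure(list(genes = genes, n_compared = length(conc),
                 n_concordant = sum(conc),
                 fraction_concordant = if (length(conc)) mean(conc) else NA_real_,
                 excluded = excluded),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat("Trend concordance: ", x$n_concordant, "/", x$n_compared,
      " genes agree in direction\n", sep = "")
  invisible(x)
}
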