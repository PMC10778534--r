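# Retention-index calibration, library annotation and internal-standard
# quantification: the computations that turn an integrated peak table into
# absolute concentrations.

#' Kovats retention index by linear interpolation
#'
#' For a peak eluting at `rt` minutes between the alkanes C(n) and C(n+1),
#'
#'   RI = 100 n + 100 (rt - RT(n)) / (RT(n+1) - RT(n)).
#'
#' No extrapolation is performed: a retention time outside the ladder span
#' is an error, because the ladder was run under the identical temperature
#' programme and an out-of-span peak indicates a calibration problem.
#'
#' @param rt Numeric vector of retention times, minutes.
#' @param ladder An [alkane_ladder()].
#' @return Numeric vector of retention indices.
#' @export
retention_index <- function(rt, ladder) {
  stopifnot(inherits(ladder, "alkane_ladder"))
  rts <- ladder$retention_time
  ns <- ladder$carbon_number
  if (any(!is.finite(rt))) stop("retention times must be finite", call. = FALSE)
  out <- which(rt < rts[1L] | rt > rts[length(rts)])
  if (length(out)) {
    stop("retention time ", format(rt[out[1L]]),
         " min outside ladder span [", format(rts[1L]), ", ",
         format(rts[length(rts)]), "] - no extrapolation", call. = FALSE)
  }
  i <- findInterval(rt, rts, rightmost.closed = TRUE)
  100 * ns[i] + 100 * (rt - rts[i]) / (rts[i + 1L] - rts[i])
}

#' Retention time from a retention index (ladder inversion)
#'
#' Exact inverse of [retention_index()] on the same ladder; used by the
#' synthetic-data generator to place peaks so that RI assignment is
#' self-consistent.
#'
#' @param ri Numeric vector of retention indices.
#' @param ladder An [alkane_ladder()].
#' @return Numeric vector of retention times, minutes.
#' @export
rt_from_ri <- function(ri, ladder) {
  stopifnot(inherits(ladder, "alkane_ladder"))
  ns <- ladder$carbon_number
  lo <- 100 * ns[1L]
  hi <- 100 * ns[length(ns)]
  out <- which(ri < lo | ri > hi)
  if (length(out)) {
    stop("retention index ", format(ri[out[1L]]), " outside ladder coverage [",
         lo, ", ", hi, "]", call. = FALSE)
  }
  i <- pmin(pmax(floor(ri / 100) - ns[1L] + 1L, 1L), length(ns) - 1L)
  frac <- ri / 100 - ns[i]
  ladder$retention_time[i] +
    frac * (ladder$retention_time[i + 1L] - ladder$retention_time[i])
}

#' Annotate peaks against a compound library by retention index
#'
#' Each non-internal-standard peak gets a computed RI and is matched to the
#' library compound with the nearest reference RI, provided the distance is
#' within `tolerance` index units; otherwise it is left unmatched. Exact
#' distance ties are broken toward the lexicographically smaller
#' `compound_id` and flagged ambiguous. (Mass-spectral matching, the other
#' half of routine GC-MS identification, is out of scope here: identity
#' comes from RI alone.)
#'
#' @param peaks A [peak_table()].
#' @param ladder An [alkane_ladder()].
#' @param library A [compound_library()].
#' @param tolerance Maximum |RI - reference RI| for a match, > 0. Default 5,
#'   a conservative capillary-GC convention.
#' @return A data frame with one row per peak: `sample_id`,
#'   `replicate_index`, `peak_compound_id`, `ri`, `bracket_n`,
#'   `matched_compound_id` (NA if unmatched), `match_distance`, `ambiguous`.
#' @export
annotate <- function(peaks, ladder, library, tolerance = 5) {
  stopifnot(inherits(peaks, "peak_table"),
            inherits(library, "compound_library"))
  if (!is.finite(tolerance) || tolerance <= 0) {
    stop("tolerance must be > 0", call. = FALSE)
  }
  p <- peaks[!peaks$is_internal_standard, , drop = FALSE]
  ri <- retention_index(p$retention_time, ladder)
  bracket <- ladder$carbon_number[
    findInterval(p$retention_time, ladder$retention_time,
                 rightmost.closed = TRUE)]
  lib <- library[order(library$compound_id), , drop = FALSE]
  matched <- character(nrow(p))
  dist <- numeric(nrow(p))
  ambig <- logical(nrow(p))
  for (j in seq_len(nrow(p))) {
    d <- abs(ri[j] - lib$reference_ri)
    k <- which.min(d)  # ties resolve to the first = smaller compound_id
    if (d[k] <= tolerance) {
      matched[j] <- lib$compound_id[k]
      dist[j] <- d[k]
      ambig[j] <- sum(d == d[k]) > 1L
    } else {
      matched[j] <- NA_character_
      dist[j] <- NA_real_
    }
  }
  data.frame(sample_id = p$sample_id, replicate_index = p$replicate_index,
             peak_compound_id = p$compound_id, ri = ri, bracket_n = bracket,
             matched_compound_id = matched, match_distance = dist,
             ambiguous = ambig)
}

#' Internal-standard quantification
#'
#' Converts peak areas to absolute concentrations via the spiked internal
#' standard: `C_i = (S_i / S_s) * (m_s / m)`, where `S_i` is the peak area
#' of compound i, `S_s` the peak area of the internal standard in the same
#' (sample, replicate) run, `m_s` the spiked mass in ng and `m` the sample
#' mass in g, giving `C_i` in ng per g of sample. The result is linear in
#' `S_i` and invariant to a joint rescaling of all areas in a run.
#'
#' @param peaks A [peak_table()].
#' @param spec A [quant_spec()].
#' @return A long data frame of class `"quantified_profile"`: one row per
#'   (sample, replicate, compound) with columns `sample_id`, `group_label`,
#'   `replicate_index`, `compound_id`, `concentration` (ng/g), `peak_area`,
#'   `is_area`.
#' @export
quantify <- function(peaks, spec) {
  stopifnot(inherits(peaks, "peak_table"), inherits(spec, "quant_spec"))
  key <- paste(peaks$sample_id, peaks$replicate_index, sep = "\r")
  is_rows <- peaks$is_internal_standard
  ss <- peaks$peak_area[is_rows]
  names(ss) <- key[is_rows]
  if (any(ss <= 0)) {
    bad <- names(ss)[ss <= 0][1L]
    stop("internal-standard area must be > 0 (run ",
         gsub("\r", " rep ", bad, fixed = TRUE), ")", call. = FALSE)
  }
  p <- peaks[!is_rows, , drop = FALSE]
  s_s <- unname(ss[paste(p$sample_id, p$replicate_index, sep = "\r")])
  conc <- (p$peak_area / s_s) * (spec$is_mass_ng / spec$sample_mass_g)
  out <- data.frame(sample_id = p$sample_id, group_label = p$group_label,
                    replicate_index = p$replicate_index,
                    compound_id = p$compound_id, concentration = conc,
                    peak_area = p$peak_area, is_area = s_s)
  class(out) <- c("quantified_profile", "data.frame")
  out
}

#' Read a quantified profile written by [write_quantified_profile()]
#' @param path Path to a long-format TSV.
#' @return A `quantified_profile` data frame.
#' @export
read_quantified_profile <- function(path) {
  df <- read_tsv_table(path, c("sample_id", "group_label", "replicate_index",
                               "compound_id", "concentration"))
  if (any(!is.finite(df$concentration) | df$concentration < 0)) {
    .located_error("concentrations must be nonnegative", df,
                   which(!is.finite(df$concentration) | df$concentration < 0))
  }
  class(df) <- c("quantified_profile", "data.frame")
  df
}

#' Write a quantified profile as long-format TSV
#' @param profile A `quantified_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quantified_profile <- function(profile, path) {
  write_tsv_table(as.data.frame(profile), path)
}
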