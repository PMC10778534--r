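# Delimited-text I/O for every table the pipeline touches.
#
# Dialect: UTF-8, tab-separated, '#'-prefixed comment lines, '.' decimal
# separator. Readers keep the original file line number of every data row so
# validation failures can point at the offending line; absent optional values
# (empty fields) are kept as NA, never coerced to 0.

.ODOR_TYPES <- c("floral", "fruity", "green", "woody", "roasted", "chemical")
.CHEM_CLASSES <- c("monoterpene", "sesquiterpene", "alcohol", "ketone",
                   "aldehyde", "ester", "nitrogen_compound", "olefin", "other")

#' Read a tab-separated table with '#' comments
#'
#' Low-level reader for the package's TSV dialect. Comment lines (leading
#' `#`) and blank lines are skipped; the first remaining line is the header.
#' The returned data frame carries a `"line_numbers"` attribute giving the
#' 1-based file line of each data row, used for located validation errors.
#'
#' @param path Path to a UTF-8, tab-separated text file.
#' @param required_cols Character vector of column names that must be present.
#' @return A `data.frame` with a `"line_numbers"` attribute.
#' @export
read_tsv_table <- function(path, required_cols = character()) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^[[:space:]]*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) < 1L) {
    stop("no header line in ", path, call. = FALSE)
  }
  df <- utils::read.delim(text = paste(lines[keep], collapse = "\n"),
                          sep = "\t", quote = "", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = c("NA", ""))
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  attr(df, "line_numbers") <- if (length(idx) > 1L) idx[-1L] else integer()
  df
}

#' Write a table in the package's TSV dialect
#'
#' @param x A data frame.
#' @param path Output path.
#' @param comments Optional character vector written as leading `#` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path, comments = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(comments)) {
    writeLines(paste0("# ", comments), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

# Stop with a message listing the file line of each offending row.
.located_error <- function(msg, df, rows) {
  ln <- attr(df, "line_numbers")
  where <- if (!is.null(ln) && length(ln) >= max(rows)) {
    paste0("line ", ln[rows])
  } else {
    paste0("row ", rows)
  }
  stop(msg, " (", paste(where, collapse = ", "), ")", call. = FALSE)
}

#' Construct and validate a GC-MS peak table
#'
#' A peak table is the integrated output of one or more GC-MS runs in long
#' format: one row per detected peak, keyed by sample, replicate and
#' compound (or `"unknown"`). Each (sample, replicate) must contain exactly
#' one internal-standard row, the spiked compound whose known mass converts
#' peak-area ratios to absolute concentrations.
#'
#' @param df Data frame with columns `sample_id`, `group_label`,
#'   `replicate_index`, `compound_id`, `retention_time` (minutes),
#'   `peak_area`, `is_internal_standard` (0/1 or logical).
#' @return The validated data frame with class `"peak_table"`.
#' @export
peak_table <- function(df) {
  req <- c("sample_id", "group_label", "replicate_index", "compound_id",
           "retention_time", "peak_area", "is_internal_standard")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("peak table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$replicate_index <- as.integer(df$replicate_index)
  isc <- df$is_internal_standard
  if (!is.logical(isc)) {
    num <- suppressWarnings(as.numeric(isc))
    isc <- ifelse(!is.na(num), num != 0,
                  toupper(trimws(as.character(isc))) %in% c("TRUE", "T", "YES"))
  }
  if (anyNA(isc)) {
    .located_error("is_internal_standard must be 0/1 or TRUE/FALSE",
                   df, which(is.na(isc)))
  }
  df$is_internal_standard <- isc
  bad <- which(!is.finite(df$retention_time) | df$retention_time <= 0)
  if (length(bad)) {
    .located_error("retention times must be strictly positive", df, bad)
  }
  bad <- which(!is.finite(df$peak_area) | df$peak_area < 0)
  if (length(bad)) {
    .located_error("peak areas must be nonnegative", df, bad)
  }
  bad <- which(is.na(df$replicate_index) | df$replicate_index < 1L)
  if (length(bad)) {
    .located_error("replicate_index must be a positive integer", df, bad)
  }
  key <- paste(df$sample_id, df$replicate_index, sep = "\r")
  for (k in unique(key)) {
    sel <- key == k
    n_is <- sum(df$is_internal_standard[sel])
    id <- df$sample_id[sel][1L]
    rep <- df$replicate_index[sel][1L]
    if (n_is == 0L) {
      stop("no internal standard in sample '", id, "' replicate ", rep,
           call. = FALSE)
    }
    if (n_is > 1L) {
      stop("multiple internal-standard rows in sample '", id,
           "' replicate ", rep, call. = FALSE)
    }
    cmpd <- df$compound_id[sel & !df$is_internal_standard]
    cmpd <- cmpd[cmpd != "unknown"]
    if (anyDuplicated(cmpd)) {
      stop("duplicate compound '", cmpd[duplicated(cmpd)][1L],
           "' in sample '", id, "' replicate ", rep, call. = FALSE)
    }
  }
  class(df) <- c("peak_table", "data.frame")
  df
}

#' Read a peak table from TSV
#'
#' @param path Path to a peak-table TSV (see [peak_table()] for columns).
#' @return A validated `peak_table`.
#' @export
read_peak_table <- function(path) {
  df <- read_tsv_table(path, required_cols = c(
    "sample_id", "group_label", "replicate_index", "compound_id",
    "retention_time", "peak_area", "is_internal_standard"))
  peak_table(df)
}

#' Construct and validate an n-alkane calibration ladder
#'
#' Maps alkane carbon number to observed retention time under the run's
#' temperature programme; retention indices are linearly interpolated
#' between consecutive rungs (carbon n maps to index 100n).
#'
#' @param carbon_number Integer vector of consecutive carbon numbers.
#' @param retention_time Numeric vector of retention times (minutes),
#'   strictly increasing with carbon number.
#' @return A data frame of class `"alkane_ladder"`.
#' @export
alkane_ladder <- function(carbon_number, retention_time) {
  n <- as.integer(carbon_number)
  o <- order(n)
  n <- n[o]
  rt <- as.numeric(retention_time)[o]
  if (anyDuplicated(n)) stop("duplicate carbon numbers in ladder", call. = FALSE)
  if (length(n) < 2L) stop("ladder needs at least two alkanes", call. = FALSE)
  if (!all(diff(n) == 1L)) {
    stop("ladder carbon numbers must be consecutive", call. = FALSE)
  }
  if (any(n < 1L)) stop("carbon numbers must be positive", call. = FALSE)
  if (!all(is.finite(rt)) || any(rt <= 0)) {
    stop("ladder retention times must be positive and finite", call. = FALSE)
  }
  if (any(diff(rt) <= 0)) {
    stop("ladder retention times must increase strictly with carbon number",
         call. = FALSE)
  }
  structure(data.frame(carbon_number = n, retention_time = rt),
            class = c("alkane_ladder", "data.frame"))
}

#' Read an alkane ladder from TSV
#' @param path Path to a TSV with columns `carbon_number`, `retention_time`.
#' @return An `alkane_ladder`.
#' @export
read_alkane_ladder <- function(path) {
  df <- read_tsv_table(path, c("carbon_number", "retention_time"))
  alkane_ladder(df$carbon_number, df$retention_time)
}

#' Construct and validate a compound library
#'
#' Per-compound reference data: Kovats retention index, odor threshold in
#' water (ng/g; may be absent), odor type (one of floral/fruity/green/
#' woody/roasted/chemical; may be absent) and chemical class. Absent
#' thresholds and types stay `NA`: an OAV is undefined, not zero, for a
#' compound without a threshold.
#'
#' @param df Data frame with columns `compound_id`, `display_name`,
#'   `reference_ri`, `odor_threshold`, `odor_type`, `chemical_class`.
#' @return The validated data frame with class `"compound_library"`.
#' @export
compound_library <- function(df) {
  req <- c("compound_id", "display_name", "reference_ri", "odor_threshold",
           "odor_type", "chemical_class")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("compound library missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$compound_id)) {
    stop("duplicate compound_id: ",
         df$compound_id[duplicated(df$compound_id)][1L], call. = FALSE)
  }
  df$reference_ri <- as.numeric(df$reference_ri)
  df$odor_threshold <- as.numeric(df$odor_threshold)
  bad <- which(!is.finite(df$reference_ri) | df$reference_ri <= 0)
  if (length(bad)) {
    .located_error("reference_ri must be positive", df, bad)
  }
  bad <- which(!is.na(df$odor_threshold) & df$odor_threshold <= 0)
  if (length(bad)) {
    .located_error("odor_threshold must be positive where present", df, bad)
  }
  bad <- which(!is.na(df$odor_type) & !(df$odor_type %in% .ODOR_TYPES))
  if (length(bad)) {
    .located_error(paste0("odor_type must be one of ",
                          paste(.ODOR_TYPES, collapse = "/")), df, bad)
  }
  bad <- which(!is.na(df$chemical_class) &
                 !(df$chemical_class %in% .CHEM_CLASSES))
  if (length(bad)) {
    .located_error(paste0("chemical_class must be one of ",
                          paste(.CHEM_CLASSES, collapse = "/")), df, bad)
  }
  class(df) <- c("compound_library", "data.frame")
  df
}

#' Read a compound library from TSV
#' @param path Path to a compound-library TSV (see [compound_library()]).
#' @return A `compound_library`.
#' @export
read_compound_library <- function(path) {
  df <- read_tsv_table(path, c("compound_id", "display_name", "reference_ri",
                               "odor_threshold", "odor_type",
                               "chemical_class"))
  compound_library(df)
}

#' Quantification specification
#'
#' The two masses the internal-standard quantification needs: the mass of
#' tea sample in the headspace vial (grams) and the mass of internal
#' standard spiked into it (nanograms). Both are carried in exactly these
#' units; the concentration formula `C_i = (S_i/S_s) * (m_s/m)` then yields
#' ng of compound per g of sample directly.
#'
#' @param sample_mass_g Sample mass, grams, > 0.
#' @param is_mass_ng Internal-standard mass, nanograms, > 0.
#' @return A list of class `"quant_spec"`.
#' @export
quant_spec <- function(sample_mass_g, is_mass_ng) {
  if (!is.finite(sample_mass_g) || sample_mass_g <= 0) {
    stop("sample mass must be > 0 g", call. = FALSE)
  }
  if (!is.finite(is_mass_ng) || is_mass_ng <= 0) {
    stop("internal-standard mass must be > 0 ng", call. = FALSE)
  }
  structure(list(sample_mass_g = sample_mass_g, is_mass_ng = is_mass_ng),
            class = "quant_spec")
}

#' Default run configuration
#'
#' @return A list of class `"run_config"` with fields `ri_tolerance`
#'   (retention-index match tolerance, index units), `fc_threshold`
#'   (absolute log2 fold-change cutoff for DEG calling), `fdr_threshold`
#'   (BH-adjusted p cutoff), `radar_offset` (added inside the radar log),
#'   `sample_mass_g`, `is_mass_ng`, `stat_replicates` (replicates used for
#'   summary statistics) and `seed`.
#' @export
default_config <- function() {
  structure(list(ri_tolerance = 5, fc_threshold = 1, fdr_threshold = 0.05,
                 radar_offset = 1, sample_mass_g = 2, is_mass_ng = 1000,
                 stat_replicates = 3L, seed = 1L),
            class = "run_config")
}

#' Read a flat key=value run configuration
#'
#' Unknown keys are kept; numeric-looking values are converted. Lines
#' starting with `#` are comments.
#'
#' @param path Path to the config file.
#' @return A `run_config` list (defaults overridden by the file).
#' @export
read_run_config <- function(path) {
  cfg <- default_config()
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^[[:space:]]*#", lines) & nzchar(trimws(lines))]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  .validate_config(cfg)
  cfg
}

#' Write a run configuration as flat key=value text
#' @param cfg A `run_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  writeLines(paste0(names(cfg), "=", vapply(cfg, format, "")), path)
  invisible(path)
}

.validate_config <- function(cfg) {
  if (cfg$ri_tolerance <= 0) stop("ri_tolerance must be > 0", call. = FALSE)
  if (cfg$fc_threshold < 0) stop("fc_threshold must be >= 0", call. = FALSE)
  if (cfg$fdr_threshold <= 0 || cfg$fdr_threshold > 1) {
    stop("fdr_threshold must be in (0, 1]", call. = FALSE)
  }
  if (cfg$radar_offset <= 0) stop("radar_offset must be > 0", call. = FALSE)
  invisible(cfg)
}

#' @export
print.peak_table <- function(x, ...) {
  cat("GC-MS peak table: ", nrow(x), " rows, ",
      length(unique(x$sample_id)), " sample(s), ",
      length(unique(paste(x$sample_id, x$replicate_index))),
      " (sample, replicate) run(s)\n", sep = "")
  invisible(x)
}

#' @export
print.compound_library <- function(x, ...) {
  cat("Compound library: ", nrow(x), " compounds (",
      sum(!is.na(x$odor_threshold)), " with odor thresholds)\n", sep = "")
  invisible(x)
}

#' @export
print.alkane_ladder <- function(x, ...) {
  cat("Alkane ladder: C", min(x$carbon_number), "-C", max(x$carbon_number),
      ", RT ", format(min(x$retention_time)), "-",
      format(max(x$retention_time)), " min\n", sep = "")
  invisible(x)
}
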