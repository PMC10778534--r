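# Shared fixture builders. Everything is generated in code; no files.

# minimal 3-compound peak table for one sample/replicate
tiny_peak_df <- function() {
  data.frame(
    sample_id = "S1", group_label = "SDT", replicate_index = 1L,
    compound_id = c("linalool", "geraniol", "indole", "ethyl_decanoate"),
    retention_time = c(9.0, 12.5, 13.3, 15.8),
    peak_area = c(2e6, 1e6, 5e5, 1e6),
    is_internal_standard = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

tiny_library_df <- function() {
  data.frame(
    compound_id = c("linalool", "geraniol", "indole"),
    display_name = c("Linalool", "Geraniol", "Indole"),
    reference_ri = c(1099, 1255, 1290),
    odor_threshold = c(0.22, 1.10, 40),
    odor_type = c("floral", "floral", "floral"),
    chemical_class = c("monoterpene", "monoterpene", "nitrogen_compound"),
    stringsAsFactors = FALSE)
}

# zero-noise variant of the default group specs
zero_noise_specs <- function() {
  lapply(default_group_specs(), function(d) { d$cv <- 0; d })
}

# a quantified profile built directly from per-replicate concentrations:
# conc is a named list group -> named list compound -> numeric replicates
profile_from_conc <- function(conc) {
  rows <- list()
  for (g in names(conc)) {
    for (cmp in names(conc[[g]])) {
      v <- conc[[g]][[cmp]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = paste0(g, "_R", seq_along(v)), group_label = g,
        replicate_index = seq_along(v), compound_id = cmp,
        concentration = v, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("quantified_profile", "data.frame")
  out
}

# exact two-sided Mann-Whitney p-value by full enumeration of all
# assignments of the pooled observations to the two groups
mw_exact_enum <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  obs <- u_of(a, b)
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2L, function(i) u_of(pooled[i], pooled[-i]))
  m <- length(a) * length(b) / 2
  if (obs == m) return(1)
  p <- if (obs < m) 2 * mean(us <= obs) else 2 * mean(us >= obs)
  min(p, 1)
}

# upper-tail hypergeometric p by direct combinatorial enumeration
hyper_exact_enum <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
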